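test_that("prediction follows symplectic Euler and first-order quaternion rules", {
  cfg <- sim_config(dt = 0.01, gravity = c(0, -9.81, 0),
                    collision_enabled = FALSE)
  particles <- list(pos = rbind(c(0, 0, 0), c(1, 2, 3)),
                    vel = matrix(0, 2, 3), inv_mass = c(1, 1))
  orientations <- list(quat = rbind(c(1, 0, 0, 0)),
                       ang_vel = matrix(0, 1, 3), inv_inertia = 1)
  # zero velocity, zero force: positions unchanged
  out <- predict_state(particles, orientations,
                       sim_config(dt = 0.01, gravity = c(0, 0, 0)))
  expect_equal(out$pos, particles$pos)
  # gravity only: velocity gains g dt, position moves g dt^2
  out <- predict_state(particles, orientations, cfg)
  expect_equal(out$vel[, 2], c(-0.0981, -0.0981))
  expect_equal(out$pos[, 2] - particles$pos[, 2], c(-9.81e-4, -9.81e-4))
  # fixed particles never move
  particles$inv_mass <- c(0, 1)
  out <- predict_state(particles, orientations, cfg)
  expect_equal(out$pos[1, ], c(0, 0, 0))
  expect_equal(out$vel[1, ], c(0, 0, 0))
})

test_that("fine-substep quaternion prediction matches closed-form rotation", {
  # omega = (0, 0, pi) for one second rotates the frame ~180 degrees
  n_sub <- 2000
  dt <- 1 / n_sub
  q <- c(1, 0, 0, 0)
  orientations <- list(quat = rbind(q), ang_vel = rbind(c(0, 0, pi)),
                       inv_inertia = 1)
  particles <- list(pos = matrix(0, 1, 3), vel = matrix(0, 1, 3),
                    inv_mass = 1)
  cfg <- sim_config(dt = dt, gravity = c(0, 0, 0))
  for (i in 1:n_sub) {
    out <- predict_state(particles, orientations, cfg)
    orientations$quat <- out$quat
  }
  target <- quat_axis_angle(c(0, 0, 1), pi)
  expect_equal(abs(sum(orientations$quat[1, ] * target)), 1,
               tolerance = 1e-5)
})

test_that("velocity update inverts prediction on constraint-free motion", {
  # pure translation
  out <- update_velocities(matrix(0, 2, 3),
                           rbind(c(0.1, 0, 0), c(0, 0.2, 0)),
                           rbind(c(1, 0, 0, 0)), rbind(c(1, 0, 0, 0)), 0.1)
  expect_equal(out$vel, rbind(c(1, 0, 0), c(0, 2, 0)))
  expect_equal(out$ang_vel, matrix(0, 1, 3))
  # small rotation about e2: omega recovered within small-angle error
  q_new <- quat_axis_angle(c(0, 1, 0), 0.01)
  out <- update_velocities(matrix(0, 1, 3), matrix(0, 1, 3),
                           rbind(c(1, 0, 0, 0)), rbind(q_new), 0.01)
  expect_equal(out$ang_vel[1, ], c(0, 1, 0), tolerance = 1e-4)
  # predict then update round-trips the angular velocity
  om <- c(0.3, -0.2, 0.5)
  orientations <- list(quat = rbind(c(1, 0, 0, 0)), ang_vel = rbind(om),
                       inv_inertia = 1)
  particles <- list(pos = matrix(0, 1, 3), vel = matrix(0, 1, 3),
                    inv_mass = 1)
  pred <- predict_state(particles, orientations, sim_config(dt = 0.005))
  out <- update_velocities(particles$pos, pred$pos, orientations$quat,
                           pred$quat, 0.005)
  expect_equal(out$ang_vel[1, ], om, tolerance = 1e-4)
})

test_that("damping removes the stated per-second velocity fraction", {
  v <- rbind(c(1, 2, 3))
  om <- rbind(c(4, 5, 6))
  expect_equal(apply_damping(v, om, 0, 0, 0.5), list(vel = v, ang_vel = om))
  expect_equal(apply_damping(v, om, 0.5, 0, 1)$vel, v / 2)
  expect_equal(apply_damping(v, om, 0, 0.75, 0.5)$ang_vel, om * 0.25^0.5)
})

test_that("a free particle chain falls ballistically", {
  # an unconstrained horizontal free rod falls rigidly; symplectic Euler
  # gives exactly y(t) = -g dt^2 (1 + 2 + ... + n) per step
  wd <- straight_rod_world(4, 0.004)
  n <- 60
  dt <- wd$config$dt
  for (i in 1:n) wd <- sim_step(wd)
  expected_y <- -9.81 * dt^2 * sum(1:n)
  expect_equal(wd$particles$pos[, 2], rep(expected_y, 5), tolerance = 1e-9)
})

test_that("a 2-particle rod pinned at one end settles hanging vertical", {
  rod <- build_rod(cbind(c(0, 0.01), 0, 0), d_v = 0.5, d_a = 0.5)
  wd <- make_world(rod, config = sim_config(collision_enabled = FALSE))
  wd <- pin_particle(wd, 1)
  for (i in 1:600) wd <- sim_step(wd)
  expect_equal(wd$particles$pos[2, ], c(0, -0.01, 0), tolerance = 1e-4)
})

test_that("identical configurations give bit-identical trajectories", {
  run <- function() {
    pts <- make_spiral_centerline(0.05, 20, 0.004, 0.02)
    rod <- build_rod(pts, d_v = 0.1, d_a = 0.1)
    wd <- make_world(rod, config = sim_config())
    wd <- pin_particle(wd, 1)
    for (i in 1:120) wd <- sim_step(wd)
    wd$particles$pos
  }
  expect_identical(run(), run())
})

test_that("internal constraint projection conserves linear momentum", {
  # free bent rod, no gravity, no damping: the center of mass must not move
  set.seed(31)
  phi <- pi / 2
  g <- seq(0, phi, length.out = 13)
  pts <- cbind(0.05 * sin(g), 0.05 * (1 - cos(g)), 0)
  pts <- pts * (0.02 / polyline_length(pts))
  rod <- build_rod(pts)
  rod$particles$pos <- rod$particles$pos +
    matrix(rnorm(39, sd = 1e-4), 13, 3)  # perturb off the rest state
  wd <- make_world(rod, config = sim_config(gravity = c(0, 0, 0),
                                            collision_enabled = FALSE))
  com0 <- colMeans(wd$particles$pos)
  for (i in 1:50) {
    wd <- sim_step(wd)
    expect_lt(max(abs(colMeans(wd$particles$pos) - com0)), 1e-10)
  }
})

test_that("quaternions stay unit after every step", {
  pts <- make_spiral_centerline(0.05, 20, 0.004, 0.02)
  rod <- build_rod(pts, d_v = 0.1, d_a = 0.1)
  wd <- make_world(rod, config = sim_config())
  wd <- pin_particle(wd, 1)
  for (i in 1:120) {
    wd <- sim_step(wd)
    expect_lt(max(abs(sqrt(rowSums(wd$orientations$quat^2)) - 1)), 1e-9)
  }
})

test_that("full damping freezes all velocities after one unit-dt step", {
  rod <- build_rod(cbind(c(0, 0.01, 0.02), 0, 0), d_v = 1, d_a = 1)
  wd <- make_world(rod, config = sim_config(dt = 1, iterations = 2,
                                            collision_enabled = FALSE))
  wd$particles$vel <- matrix(rnorm(9), 3, 3)
  wd <- sim_step(wd)
  expect_equal(max(abs(wd$particles$vel)), 0)
  expect_equal(max(abs(wd$orientations$ang_vel)), 0)
})

test_that("constraint residuals are non-increasing in the iteration count", {
  # static perturbed rod, no gravity: more Gauss-Seidel iterations leave a
  # smaller (never larger) stretch residual
  set.seed(32)
  base <- straight_rod_world(12, 0.015)
  base$particles$pos <- base$particles$pos +
    matrix(rnorm(39, sd = 5e-4), 13, 3)
  res <- vapply(c(1L, 2L, 4L, 8L, 16L), function(k) {
    wd <- base
    wd$config <- sim_config(iterations = k, use_ddc = FALSE,
                            gravity = c(0, 0, 0), collision_enabled = FALSE)
    wd <- sim_step(wd)
    wd$report$residual_stretch
  }, 0)
  expect_true(all(diff(res) <= 1e-12))
})

test_that("held particles never move through any scene forces", {
  pts <- make_spiral_centerline(0.06, 24, 0.004, 0.02)
  rod <- build_rod(pts, d_v = 0.1, d_a = 0.1)
  wd <- make_world(rod, config = sim_config())
  wd <- pin_particle(wd, 1)
  wd <- pin_particle(wd, 12)
  p1 <- wd$particles$pos[1, ]
  p12 <- wd$particles$pos[12, ]
  for (i in 1:200) {
    wd <- sim_step(wd)
    expect_identical(wd$particles$pos[1, ], p1)
    expect_identical(wd$particles$pos[12, ], p12)
  }
})

test_that("the compiled stepper agrees with the explicit projection pieces", {
  # constraint-free world: one step equals predict -> update -> damp
  rod <- build_rod(cbind(c(0, 0.01), 0, 0), d_v = 0.3, d_a = 0.2)
  wd <- make_world(rod, config = sim_config(iterations = 1,
                                            collision_enabled = FALSE))
  wd$particles$vel <- rbind(c(0.1, 0, 0), c(0.1, 0, 0))  # rigid motion
  pred <- predict_state(wd$particles, wd$orientations, wd$config)
  upd <- update_velocities(wd$particles$pos, pred$pos, wd$orientations$quat,
                           pred$quat, wd$config$dt)
  damped <- apply_damping(upd$vel, upd$ang_vel, 0.3, 0.2, wd$config$dt)
  stepped <- sim_step(wd)
  expect_equal(stepped$particles$pos, pred$pos, tolerance = 1e-12)
  expect_equal(stepped$particles$vel, damped$vel, tolerance = 1e-12)
})
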