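test_that("sphere-sphere time of impact matches analytic and scanned values", {
  # head-on: centers touch at distance 1 halfway through the step
  expect_equal(sphere_sphere_toi(c(2, 0, 0), c(0, 0, 0), c(0, 0, 0),
                                 c(0, 0, 0), 0.5, 0.5), 0.5)
  # distant parallel paths never collide
  expect_true(is.na(sphere_sphere_toi(c(0, 3, 0), c(1, 3, 0), c(0, 0, 0),
                                      c(1, 0, 0), 0.5, 0.5)))
  # already overlapping reports impact at the start of the step
  expect_equal(sphere_sphere_toi(c(0.1, 0, 0), c(5, 0, 0), c(0, 0, 0),
                                 c(0, 0, 0), 0.5, 0.5), 0)
  # random pairs against the dense time-scanning + bisection oracle
  set.seed(51)
  n_hit <- 0
  for (rep in 1:1000) {
    xa <- rnorm(3); xb <- rnorm(3)
    xap <- xa + rnorm(3); xbp <- xb + rnorm(3)
    ra <- runif(1, 0.1, 0.8); rb <- runif(1, 0.1, 0.8)
    got <- sphere_sphere_toi(xa, xap, xb, xbp, ra, rb)
    want <- oracle_toi(xa, xap, xb, xbp, ra, rb)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      n_hit <- n_hit + 1
      expect_equal(got, want, tolerance = 1e-4)
    }
  }
  expect_gt(n_hit, 100)  # the sample exercises real collisions
})

test_that("swept bounding boxes contain the moving sphere", {
  # stationary sphere: cube of half-width r
  box <- swept_aabb(c(1, 2, 3), c(1, 2, 3), 0.5)
  expect_equal(box[1, ], c(0.5, 1.5, 2.5))
  expect_equal(box[2, ], c(1.5, 2.5, 3.5))
  # straight motion along +x
  box <- swept_aabb(c(0, 0, 0), c(1, 0, 0), 0.1)
  expect_equal(box[2, ] - box[1, ], c(1.2, 0.2, 0.2))
  # sampled swept-sphere surface points all lie inside the box
  set.seed(52)
  for (rep in 1:20) {
    x <- rnorm(3); xp <- x + rnorm(3); r <- runif(1, 0.05, 0.5)
    box <- swept_aabb(x, xp, r)
    t <- runif(500)
    u <- matrix(rnorm(1500), 500, 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- (1 - t) %o% x + t %o% xp + r * u
    expect_true(all(sweep(pts, 2, box[1, ], ">=") &
                      sweep(pts, 2, box[2, ], "<=")))
  }
})

random_collision_world <- function(n_rods = 12) {
  rods <- lapply(seq_len(n_rods), function(i) {
    o <- runif(3, -0.05, 0.05)
    build_rod(rbind(o, o + c(0, 0, 2e-3), o + c(0, 0, 4e-3)), radius = 1e-3)
  })
  wd <- make_world(rods, config = sim_config(cell_size = 4e-3))
  wd$particles$pos <- matrix(runif(3 * nrow(wd$particles$pos), -0.02, 0.02),
                             ncol = 3)
  wd$particles$vel <- matrix(rnorm(3 * nrow(wd$particles$pos), sd = 0.05),
                             ncol = 3)
  wd
}

test_that("broad phase returns a deduplicated superset of AABB overlaps", {
  set.seed(53)
  for (rep in 1:20) {
    wd <- random_collision_world()
    pred <- wd$particles$pos + wd$config$dt * wd$particles$vel
    pairs <- broad_phase(wd, pred)
    # deduplicated and ordered
    expect_false(any(duplicated(paste(pairs[, 1], pairs[, 2]))))
    if (nrow(pairs) > 0) expect_true(all(pairs[, 1] < pairs[, 2]))
    # brute-force reference: all overlapping swept AABBs, same exclusions
    tp <- threadsim:::particle_topology(wd)
    n <- nrow(wd$particles$pos)
    key <- paste(pairs[, 1], pairs[, 2])
    for (i in 1:(n - 1)) {
      bi <- swept_aabb(wd$particles$pos[i, ], pred[i, ], 1e-3)
      for (j in (i + 1):n) {
        if (tp$rod_id[i] == tp$rod_id[j] &&
            abs(tp$chain_pos[i] - tp$chain_pos[j]) <= 2) next
        bj <- swept_aabb(wd$particles$pos[j, ], pred[j, ], 1e-3)
        if (all(bi[1, ] <= bj[2, ]) && all(bj[1, ] <= bi[2, ])) {
          expect_true(paste(i, j) %in% key)
        }
      }
    }
  }
})

test_that("spheres in distant cells are never candidate pairs", {
  r1 <- build_rod(rbind(c(0, 0, 0), c(0, 0, 2e-3), c(0, 0, 4e-3)),
                  radius = 1e-3)
  r2 <- build_rod(rbind(c(1, 0, 0), c(1, 0, 2e-3), c(1, 0, 4e-3)),
                  radius = 1e-3)
  wd <- make_world(list(r1, r2), config = sim_config(cell_size = 4e-3))
  expect_equal(nrow(broad_phase(wd)), 0L)
})

test_that("a head-on pair ends the step separated at the contact distance", {
  # two short rods shot at each other; after the step no penetration
  r1 <- build_rod(rbind(c(-6e-3, 0, -1e-3), c(-6e-3, 0, 1e-3)),
                  radius = 1e-3)
  r2 <- build_rod(rbind(c(6e-3, 0, -1e-3), c(6e-3, 0, 1e-3)),
                  radius = 1e-3)
  wd <- make_world(list(r1, r2),
                   config = sim_config(gravity = c(0, 0, 0),
                                       friction_k = 0))
  wd$particles$vel[1:2, 1] <- 1
  wd$particles$vel[3:4, 1] <- -1
  for (i in 1:20) wd <- sim_step(wd, report_min_separation = TRUE)
  expect_gte(wd$report$min_separation, 2e-3 - 1e-6)
})

test_that("friction strength zero reproduces a frictionless run exactly", {
  run <- function(k) {
    rod <- build_rod(rbind(c(0, 1.1e-3, 0), c(2e-3, 1.1e-3, 0)),
                     radius = 1e-3)
    plane <- collider_plane(c(0, 1, 0), 0, friction = k)
    tilt <- 20 * pi / 180
    wd <- make_world(rod, colliders = list(plane),
                     config = sim_config(dt = 1 / 600,
                                         gravity = 9.81 * c(sin(tilt),
                                                            -cos(tilt), 0),
                                         friction_k = k))
    for (i in 1:300) wd <- sim_step(wd)
    wd$particles$pos
  }
  base <- run(0)
  # k = 0 leaves sliding unrestricted: the rod slides down-slope
  expect_gt(mean(base[, 1]), 1e-3)
  expect_identical(run(0), base)
})

test_that("tangential slip is non-increasing in the friction strength", {
  # few iterations so the per-step friction correction is partial and the
  # strength actually grades the slip
  slip <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(k) {
    rod <- build_rod(rbind(c(0, 1.1e-3, 0), c(2e-3, 1.1e-3, 0)),
                     radius = 1e-3)
    plane <- collider_plane(c(0, 1, 0), 0, friction = k)
    tilt <- 20 * pi / 180
    wd <- make_world(rod, colliders = list(plane),
                     config = sim_config(dt = 1 / 600, iterations = 2L,
                                         gravity = 9.81 * c(sin(tilt),
                                                            -cos(tilt), 0),
                                         friction_k = k))
    x0 <- mean(wd$particles$pos[, 1])
    for (i in 1:300) wd <- sim_step(wd)
    mean(wd$particles$pos[, 1]) - x0
  }, 0)
  expect_true(all(diff(slip) <= 1e-6))
  expect_lt(slip[5], slip[1])  # full strength visibly reduces the slide
})

test_that("full-strength friction pins a resting contact in place", {
  # rod resting on a level plane with no tangential force: no drift at all
  rod <- build_rod(rbind(c(0, 1e-3, 0), c(2e-3, 1e-3, 0)), radius = 1e-3)
  plane <- collider_plane(c(0, 1, 0), 0, friction = 1)
  wd <- make_world(rod, colliders = list(plane),
                   config = sim_config(dt = 1 / 600, friction_k = 1))
  p0 <- wd$particles$pos
  for (i in 1:300) wd <- sim_step(wd)
  expect_lt(max(abs(wd$particles$pos[, c(1, 3)] - p0[, c(1, 3)])), 1e-6)
})
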