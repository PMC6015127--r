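test_that("shear-stretch constraint matches its analytic and oracle values", {
  q_id <- c(1, 0, 0, 0)
  # rest state
  expect_equal(shear_stretch_constraint(c(0, 0, 0), c(0, 0, 1), q_id, 1),
               c(0, 0, 0))
  # pure 2x stretch along the director
  expect_equal(shear_stretch_constraint(c(0, 0, 0), c(0, 0, 2), q_id, 1),
               c(0, 0, 1))
  # rotated frame against an axis-angle rotation-matrix oracle
  set.seed(21)
  for (i in 1:20) {
    ax <- rnorm(3); ang <- runif(1, -pi, pi)
    q <- quat_axis_angle(ax, ang)
    l <- runif(1, 0.5, 2)
    p1 <- rnorm(3); p2 <- rnorm(3)
    expected <- (p2 - p1) / l -
      as.numeric(oracle_axis_angle_mat(ax, ang) %*% c(0, 0, 1))
    expect_equal(shear_stretch_constraint(p1, p2, q, l), expected,
                 tolerance = 1e-12)
  }
  expect_error(shear_stretch_constraint(c(0, 0, 0), c(0, 0, 1),
                                        c(2, 0, 0, 0), 1),
               "invalid orientation")
})

test_that("bend-twist constraint measures the discrete Darboux mismatch", {
  q_id <- c(1, 0, 0, 0)
  expect_equal(bend_twist_constraint(q_id, q_id, q_id, q_id), c(0, 0, 0))
  # relative rotation pi/2 about e3 against the quaternion-product oracle
  u <- quat_axis_angle(c(0, 0, 1), pi / 2)
  expect_equal(bend_twist_constraint(q_id, u, q_id, q_id),
               c(0, 0, sin(pi / 4)), tolerance = 1e-12)
  # invariance under a common rigid rotation of current AND rest pairs
  set.seed(22)
  for (i in 1:25) {
    q0 <- random_unit_quat(); u0 <- random_unit_quat()
    g <- random_unit_quat()
    expect_equal(bend_twist_constraint(quat_multiply(g, q0),
                                       quat_multiply(g, u0), q0, u0),
                 bend_twist_constraint(q0, u0, q0, u0), tolerance = 1e-10)
  }
  expect_error(bend_twist_constraint(c(0.5, 0, 0, 0), q_id, q_id, q_id),
               "invalid orientation")
})

test_that("analytic Jacobians agree with central finite differences", {
  set.seed(23)
  for (i in 1:100) {
    q <- random_unit_quat(); u <- random_unit_quat()
    l <- runif(1, 0.5, 2)
    p1 <- rnorm(3); p2 <- p1 + quat_rotate(q, c(0, 0, 1)) * l + rnorm(3) * 0.1
    ev <- constraint_jacobian(list(type = "shear_stretch", p1 = p1, p2 = p2,
                                   q = q, l = l))
    Jfd <- oracle_fd(function(x) {
      (p2 - x) / l - quat_rotate(q, c(0, 0, 1))
    }, p1)
    expect_equal(unname(ev$jacobian$p1), Jfd, tolerance = 1e-5)
    # quaternion block: differentiate the raw-component sandwich product
    Jfd_q <- oracle_fd(function(x) {
      rr <- quat_multiply(quat_multiply(x, c(0, c(0, 0, 1))),
                          quat_conjugate(x))
      (p2 - p1) / l - rr[2:4]
    }, q)
    expect_equal(unname(ev$jacobian$q), Jfd_q, tolerance = 1e-5)

    evb <- constraint_jacobian(list(type = "bend_twist", q = q, u = u,
                                    q0 = q, u0 = u))
    Jb_q <- oracle_fd(function(x) quat_multiply(quat_conjugate(x), u)[2:4], q)
    Jb_u <- oracle_fd(function(x) quat_multiply(quat_conjugate(q), x)[2:4], u)
    expect_equal(unname(evb$jacobian$q), Jb_q, tolerance = 1e-5)
    expect_equal(unname(evb$jacobian$u), Jb_u, tolerance = 1e-5)
  }
})

test_that("distance constraint gradient is the unit separation direction", {
  set.seed(24)
  for (i in 1:20) {
    p1 <- rnorm(3); p2 <- rnorm(3)
    n <- (p1 - p2) / sqrt(sum((p1 - p2)^2))
    ev <- constraint_jacobian(list(type = "distance", p1 = p1, p2 = p2,
                                   d = 0.5))
    expect_equal(as.numeric(ev$jacobian$p1), n, tolerance = 1e-12)
    expect_equal(as.numeric(ev$jacobian$p2), -n, tolerance = 1e-12)
  }
  expect_error(constraint_jacobian(list(type = "distance", p1 = c(1, 1, 1),
                                        p2 = c(1, 1, 1), d = 1)),
               "degenerate geometry")
})

test_that("friction constraint value follows the cross-product formula", {
  n <- c(0, 1, 0)
  # offset parallel to the normal: no friction violation
  expect_equal(friction_constraint(c(0, 1, 0), c(0, 0, 0), n, 1), 0)
  # perpendicular offset at full strength
  expect_equal(friction_constraint(c(1, 0, 0), c(0, 0, 0), n, 1), 1,
               tolerance = 1e-12)
  # 45-degree offset at half strength
  expect_equal(friction_constraint(c(1, 1, 0) / sqrt(2), c(0, 0, 0), n, 0.5),
               0.5 * sin(pi / 4), tolerance = 1e-12)
  expect_error(friction_constraint(c(0, 0, 0), c(0, 0, 0), n, 1),
               "degenerate geometry")
  # finite-difference gradient is antisymmetric between the two points
  set.seed(25)
  for (i in 1:10) {
    p1 <- rnorm(3); p2 <- rnorm(3)
    ev <- constraint_jacobian(list(type = "friction", p1 = p1, p2 = p2,
                                   normal = n, k = 0.7))
    expect_equal(unname(ev$jacobian$p1), -unname(ev$jacobian$p2),
                 tolerance = 1e-8)
  }
})

test_that("contact constraint measures the signed gap along the normal", {
  n <- c(1, 0, 0)
  expect_equal(contact_constraint(c(0.5, 0, 0), c(0, 0, 0), n, 0.5), 0)
  expect_equal(contact_constraint(c(0.25, 0, 0), c(0, 0, 0), n, 0.5), -0.25)
})

test_that("Gauss-Seidel projection reproduces the classic closed forms", {
  # symmetric split of a stretched pair
  st <- list(pos = rbind(c(0, 0, 0), c(1.2, 0, 0)), inv_mass = c(1, 1))
  out <- project_constraints(st, list(list(type = "distance", i1 = 1,
                                           i2 = 2, d = 1)))
  expect_equal(out$pos[1, ], c(0.1, 0, 0), tolerance = 1e-12)
  expect_equal(out$pos[2, ], c(1.1, 0, 0), tolerance = 1e-12)
  # a fixed endpoint absorbs nothing; the free one takes the whole move
  st$inv_mass <- c(0, 1)
  out <- project_constraints(st, list(list(type = "distance", i1 = 1,
                                           i2 = 2, d = 1)))
  expect_equal(out$pos[1, ], c(0, 0, 0))
  expect_equal(out$pos[2, ], c(1, 0, 0), tolerance = 1e-12)
  # singular local system (both ends fixed) is skipped, not fatal
  st$inv_mass <- c(0, 0)
  out <- project_constraints(st, list(list(type = "distance", i1 = 1,
                                           i2 = 2, d = 1)))
  expect_equal(out$pos, st$pos)
  # random 5-particle chain, one pass, against an independent straight-line
  # implementation of the mass-weighted corrections
  set.seed(26)
  for (rep in 1:20) {
    p <- random_chain(5, d = 1)
    w <- runif(5, 0.2, 2)
    if (rep %% 3 == 0) w[1] <- 0
    cons <- lapply(1:4, function(i) list(type = "distance", i1 = i,
                                         i2 = i + 1, d = 1))
    got <- project_constraints(list(pos = p, inv_mass = w), cons)$pos
    expect_equal(got, oracle_gs_distance(p, w, 1), tolerance = 1e-12)
  }
  # projecting a penetrating contact pair separates it symmetrically
  st <- list(pos = rbind(c(0.2, 0, 0), c(0, 0, 0)), inv_mass = c(1, 1))
  out <- project_constraints(st, list(list(type = "contact", i1 = 1, i2 = 2,
                                           normal = c(1, 0, 0), d = 1)))
  expect_equal(contact_constraint(out$pos[1, ], out$pos[2, ], c(1, 0, 0), 1),
               0, tolerance = 1e-10)
  expect_equal(out$pos[1, 1] - 0.2, -(out$pos[2, 1] - 0), tolerance = 1e-10)
  # a satisfied contact (inequality) is left alone
  st <- list(pos = rbind(c(2, 0, 0), c(0, 0, 0)), inv_mass = c(1, 1))
  out <- project_constraints(st, list(list(type = "contact", i1 = 1, i2 = 2,
                                           normal = c(1, 0, 0), d = 1)))
  expect_equal(out$pos, st$pos)
})
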