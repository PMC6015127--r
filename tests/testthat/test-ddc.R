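test_that("distance constraint values are the pairwise length errors", {
  p <- cbind(0, 0, seq(0, 1, by = 0.1))
  expect_equal(distance_constraint_values(p, 0.1), rep(0, 10),
               tolerance = 1e-15)
  p2 <- p
  p2[11, 3] <- p2[11, 3] + 0.1  # last segment stretched to 2d
  expect_equal(distance_constraint_values(p2, 0.1), c(rep(0, 9), 0.1),
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:10) {
    ch <- random_chain(8, 0.05)
    lens <- sqrt(rowSums((ch[-1, ] - ch[-8, ])^2))
    expect_equal(distance_constraint_values(ch, 0.05), lens - 0.05,
                 tolerance = 1e-12)
  }
  expect_error(distance_constraint_values(rbind(c(0, 0, 0), c(0, 0, 0)), 1),
               "degenerate geometry")
})

test_that("the assembled system reproduces the printed band pattern", {
  # straight chain with the first particle held: diagonal magnitudes
  # [1, 2, 2, ...], off-diagonal magnitudes 1 (parallel directions)
  p <- cbind(0, 0, seq(0, 0.5, by = 0.1))
  w <- c(0, 1, 1, 1, 1, 1)
  sys <- assemble_tridiagonal(p, w, 0.1)
  expect_equal(abs(sys$diag), c(1, 2, 2, 2, 2))
  expect_equal(abs(sys$super), rep(1, 4), tolerance = 1e-12)
  expect_equal(abs(sys$sub), rep(1, 4), tolerance = 1e-12)
  # right-angle chain: orthogonal directions decouple the system
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  sys <- assemble_tridiagonal(p, c(1, 1, 1), 1)
  expect_equal(sys$super, 0, tolerance = 1e-14)
})

test_that("assembled bands equal the dense Gram matrix on random chains", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    p <- random_chain(n, 0.1)
    w <- runif(n, 0.2, 2)
    if (rep %% 4 == 0) w[1] <- 0
    if (rep %% 5 == 0) w[sample(2:(n - 1), 1)] <- 0
    dense <- oracle_dense_ddc(p, w, 0.1)
    sys <- assemble_tridiagonal(p, w, 0.1)
    k <- n - 1
    expect_equal(sys$diag, unname(diag(dense$A)), tolerance = 1e-12)
    if (k > 1) {
      expect_equal(sys$super, unname(dense$A[cbind(1:(k - 1), 2:k)]),
                   tolerance = 1e-12)
      expect_equal(sys$sub, unname(dense$A[cbind(2:k, 1:(k - 1))]),
                   tolerance = 1e-12)
    }
    expect_equal(sys$rhs, -dense$C, tolerance = 1e-12)
    # the dense Gram matrix is exactly tridiagonal: nothing off the bands
    off <- dense$A
    off[abs(row(off) - col(off)) <= 1] <- 0
    expect_equal(max(abs(off)), 0)
  }
})

test_that("the Thomas algorithm solves tridiagonal systems exactly", {
  # identity system
  out <- thomas_solve(list(sub = c(0, 0), diag = c(1, 1, 1),
                           super = c(0, 0), rhs = c(2, 3, 4)))
  expect_equal(out, c(2, 3, 4))
  # fixed 3x3 against a dense solve
  A <- matrix(c(-2, 1, 0, 1, -2, 1, 0, 1, -2), 3, 3, byrow = TRUE)
  rhs <- c(1, 0, 1)
  out <- thomas_solve(list(sub = c(1, 1), diag = c(-2, -2, -2),
                           super = c(1, 1), rhs = rhs))
  expect_equal(out, as.numeric(solve(A, rhs)), tolerance = 1e-12)
  # 200 random diagonally dominant systems against dense solves
  set.seed(43)
  for (rep in 1:200) {
    k <- sample(2:30, 1)
    sub <- runif(k - 1, -1, 1)
    super <- runif(k - 1, -1, 1)
    dg <- abs(c(0, sub)) + abs(c(super, 0)) + runif(k, 0.5, 2)
    rhs <- rnorm(k)
    A <- diag(dg)
    A[cbind(2:k, 1:(k - 1))] <- sub
    A[cbind(1:(k - 1), 2:k)] <- super
    out <- thomas_solve(list(sub = sub, diag = dg, super = super,
                             rhs = rhs))
    expect_lt(max(abs(out - solve(A, rhs))), 1e-10)
  }
  expect_error(thomas_solve(list(sub = 0, diag = c(0, 1), super = 0,
                                 rhs = c(1, 1))), "singular")
})

test_that("one direct correction matches the dense mass-weighted update", {
  set.seed(44)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    p <- random_chain(n, 0.1)
    w <- rep(1, n)
    if (rep %% 2 == 0) w[1] <- 0
    dense <- oracle_dense_ddc(p, w, 0.1)
    lam <- solve(dense$A, -dense$C)
    expected <- p + matrix(dense$W %*% t(dense$G) %*% lam, n, 3,
                           byrow = TRUE)
    got <- apply_ddc(p, w, 0.1)
    # apply_ddc line-searches the Newton step; for these mild chains the
    # full step must be taken and match the dense update exactly
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("direct correction restores a stretched chain and respects holds", {
  # chain already at rest lengths: no correction at all
  p <- cbind(0, 0, seq(0, 0.4, by = 0.1))
  expect_equal(apply_ddc(p, rep(1, 5), 0.1), p)
  # 3-particle chain, first fixed, 10% uniform stretch: one call cuts the
  # worst violation by at least 5x; iterating restores rest lengths
  p <- cbind(0, 0, c(0, 0.11, 0.22))
  w <- c(0, 1, 1)
  e0 <- max(abs(distance_constraint_values(p, 0.1)))
  p1 <- apply_ddc(p, w, 0.1)
  expect_lt(max(abs(distance_constraint_values(p1, 0.1))), e0 / 5)
  for (i in 1:50) p1 <- apply_ddc(p1, w, 0.1)
  expect_lt(max(abs(distance_constraint_values(p1, 0.1))) / 0.1, 1e-8)
  expect_equal(p1[1, ], p[1, ])  # the held particle never moved
})

test_that("repeated corrections converge on randomly perturbed chains", {
  set.seed(45)
  for (rep in 1:15) {
    n <- sample(5:20, 1)
    d <- 0.05
    base <- cbind(0, 0, seq(0, by = d, length.out = n))
    p <- base + matrix(runif(3 * n, -0.2 * d, 0.2 * d), n, 3)
    w <- rep(1, n)
    if (rep %% 2 == 0) w[1] <- 0
    errs <- numeric(50)
    for (i in 1:50) {
      p <- apply_ddc(p, w, d)
      errs[i] <- max(abs(distance_constraint_values(p, d))) / d
    }
    expect_lt(errs[50], 1e-8)
    expect_true(all(diff(errs[errs > 1e-12]) <= 1e-9))
  }
})

test_that("an interior held particle splits the chain into independent halves", {
  set.seed(46)
  d <- 0.1
  base <- cbind(0, 0, seq(0, by = d, length.out = 9))
  w <- rep(1, 9)
  w[5] <- 0  # gripped by the instrument
  # perturb only the right half; the left half must not move at all
  p <- base
  p[6:9, ] <- p[6:9, ] + matrix(runif(12, -0.015, 0.015), 4, 3)
  out <- apply_ddc(p, w, d)
  expect_identical(out[1:5, ], p[1:5, ])
  expect_false(identical(out[6:9, ], p[6:9, ]))
  # and symmetrically
  p <- base
  p[1:4, ] <- p[1:4, ] + matrix(runif(12, -0.015, 0.015), 4, 3)
  out <- apply_ddc(p, w, d)
  expect_identical(out[5:9, ], p[5:9, ])
})

test_that("an all-held chain is a no-op and w1 = 0 never moves", {
  p <- random_chain(5, 0.1)
  expect_equal(apply_ddc(p, rep(0, 5), 0.1), p)
  set.seed(47)
  for (rep in 1:10) {
    p <- random_chain(6, 0.1)
    w <- c(0, runif(5, 0.1, 2))
    out <- apply_ddc(p, w, 0.1)
    expect_identical(out[1, ], p[1, ])
  }
})
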