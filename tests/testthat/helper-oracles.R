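# Independent oracles used across the tests. Everything here is written
# against the mathematical definitions directly (rotation matrices, dense
# linear algebra, time scanning), never by calling the implementation paths
# it checks.

# rotation matrix from a unit quaternion (scalar-first), textbook form
oracle_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# axis-angle rotation matrix (Rodrigues formula)
oracle_axis_angle_mat <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_unit_quat <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

# dense Gauss-Newton projection step for the chained distance constraints:
# grad(C) W grad(C)^T lambda = -C built as full matrices
oracle_dense_ddc <- function(p, w, d) {
  n <- nrow(p)
  k <- n - 1
  G <- matrix(0, k, 3 * n)
  C <- numeric(k)
  for (i in 1:k) {
    diff <- p[i, ] - p[i + 1, ]
    len <- sqrt(sum(diff^2))
    nn <- diff / len
    C[i] <- len - d
    G[i, (3 * i - 2):(3 * i)] <- nn
    G[i, (3 * i + 1):(3 * i + 3)] <- -nn
  }
  W <- diag(rep(w, each = 3))
  A <- G %*% W %*% t(G)
  list(A = A, C = C, G = G, W = W)
}

# random mildly-kinked chain with given segment scale
random_chain <- function(n, d = 0.1, stretch = c(0.8, 1.2)) {
  p <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    dir <- dir + rnorm(3) * 0.4
    dir <- dir / sqrt(sum(dir^2))
    p[i, ] <- p[i - 1, ] + dir * d * runif(1, stretch[1], stretch[2])
  }
  p
}

# earliest contact time by dense scanning plus bisection refinement
oracle_toi <- function(xa, xap, xb, xbp, ra, rb, n_scan = 2000) {
  gap <- function(t) {
    pa <- xa + t * (xap - xa)
    pb <- xb + t * (xbp - xb)
    sqrt(sum((pa - pb)^2)) - (ra + rb)
  }
  ts <- seq(0, 1, length.out = n_scan + 1)
  gs <- vapply(ts, gap, 0)
  if (gs[1] <= 0) return(0)
  hit <- which(gs <= 0)[1]
  if (is.na(hit)) return(NA_real_)
  lo <- ts[hit - 1]; hi <- ts[hit]
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (gap(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# central finite differences of a scalar- or vector-valued function
oracle_fd <- function(f, x, h = 1e-6) {
  m <- length(f(x))
  J <- matrix(0, m, length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# straight-line re-implementation of one Gauss-Seidel pass of pairwise
# distance projections over a chain (classic PBD closed form)
oracle_gs_distance <- function(pos, w, d) {
  n <- nrow(pos)
  for (i in 1:(n - 1)) {
    wsum <- w[i] + w[i + 1]
    if (wsum <= 0) next
    diff <- pos[i, ] - pos[i + 1, ]
    len <- sqrt(sum(diff^2))
    corr <- (len - d) / (len * wsum)
    pos[i, ] <- pos[i, ] - w[i] * corr * diff
    pos[i + 1, ] <- pos[i + 1, ] + w[i + 1] * corr * diff
  }
  pos
}

# a small straight rod world used by several solver tests
straight_rod_world <- function(n_el = 10, L = 0.0125, ...,
                               config = sim_config(collision_enabled = FALSE)) {
  z <- seq(0, L, length.out = n_el + 1)
  rod <- build_rod(cbind(z, 0, 0), ...)
  make_world(rod, config = config)
}
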