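# Discretization of a centerline into connected rod elements, plus the
# simulation configuration object. All quantities are SI (meters, kg,
# seconds); scene files may declare `units: cm` and are converted on load.

#' Simulation configuration
#'
#' Settings of the PBD solver loop. Damping and stiffness live on the rod
#' (they are material properties); everything about the loop itself lives
#' here.
#'
#' @param dt time step in seconds. Default 1/60 s, the interactive rendering
#'   rate the simulator targets.
#' @param iterations Gauss-Seidel iterations per step (>= 1).
#' @param use_ddc enable the direct distance constraint: a tridiagonal solve
#'   of all chained segment-length constraints, run at the end of every
#'   projection iteration.
#' @param gravity external acceleration, m/s^2.
#' @param friction_k friction strength in `[0, 1]` for thread-thread
#'   contacts; 0 is frictionless, 1 blocks tangential motion at the contact.
#' @param cell_size spatial-hash cell edge length in meters; `NULL` picks
#'   twice the sphere diameter of the first rod.
#' @param collision_enabled run continuous collision detection each step.
#' @param seed integer seed stored with the configuration (the solver itself
#'   is deterministic; the seed governs randomized scene generation).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt = 1 / 60, iterations = 10L, use_ddc = TRUE,
                       gravity = c(0, -9.81, 0), friction_k = 0.5,
                       cell_size = NULL, collision_enabled = TRUE,
                       seed = 1L) {
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0)
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1L)
  stopifnot(length(gravity) == 3, is.numeric(gravity))
  stopifnot(friction_k >= 0, friction_k <= 1)
  if (!is.null(cell_size)) stopifnot(cell_size > 0)
  cfg <- list(dt = dt, iterations = iterations, use_ddc = isTRUE(use_ddc),
              gravity = as.numeric(gravity), friction_k = friction_k,
              cell_size = cell_size,
              collision_enabled = isTRUE(collision_enabled),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  dt: %.6g s, iterations: %d, DDC: %s\n",
              x$dt, x$iterations, x$use_ddc))
  cat(sprintf("  gravity: (%g, %g, %g) m/s^2\n",
              x$gravity[1], x$gravity[2], x$gravity[3]))
  cat(sprintf("  collisions: %s, friction k: %g, cell size: %s\n",
              x$collision_enabled, x$friction_k,
              if (is.null(x$cell_size)) "auto" else format(x$cell_size)))
  invisible(x)
}

#' Helical centerline with uniform spacing
#'
#' Points on a helix about the +z axis, spaced so that every polyline
#' segment has the same length and the total polyline length equals
#' `total_length` (to 1e-6 relative). `helix_radius = 0` degenerates to a
#' straight line along +z.
#'
#' @param total_length desired polyline length in meters (> 0).
#' @param n_elements number of segments (>= 2); returns `n_elements + 1`
#'   points.
#' @param helix_radius radius of the helix in meters (>= 0).
#' @param pitch axial advance per full turn in meters (>= 0).
#' @return an `(n_elements + 1) x 3` matrix of points.
#' @export
make_spiral_centerline <- function(total_length, n_elements,
                                   helix_radius = 0.005, pitch = 0.02) {
  stopifnot(total_length > 0, n_elements >= 2)
  n <- as.integer(n_elements)
  R <- helix_radius
  b <- pitch / (2 * pi)  # axial advance per radian
  if (R <= 0 && pitch <= 0)
    stop("degenerate geometry: helix_radius and pitch are both zero")
  if (R <= 0) {
    z <- seq(0, total_length, length.out = n + 1)
    return(cbind(0, 0, z))
  }
  # chord length of one segment spanning dth radians:
  #   c(dth)^2 = (2 R sin(dth/2))^2 + (b dth)^2; solve n * c(dth) = L
  chord <- function(dth) sqrt((2 * R * sin(dth / 2))^2 + (b * dth)^2)
  f <- function(dth) n * chord(dth) - total_length
  if (b <= 0) {
    # pure circle: a segment chord can be at most the diameter
    if (2 * R * n < total_length)
      stop("degenerate geometry: requested length cannot fit on this helix")
    upper <- pi
  } else {
    upper <- total_length / (n * b)
  }
  dth <- uniroot(f, c(1e-12, upper), tol = 1e-15)$root
  th <- dth * (0:n)
  cbind(R * cos(th), R * sin(th), b * th)
}

#' Discretize a centerline into a rod
#'
#' Builds the discrete Cosserat rod: one element per consecutive point pair,
#' each carrying a unit quaternion material frame whose third director
#' `d3 = R(q) e3` points along the segment. Rest quaternions are the
#' shortest-arc rotation from `e3 = (0, 0, 1)` onto each segment direction,
#' so the rest configuration is twist-free; rest bend-twist terms (the
#' discrete Darboux products of adjacent frames) are precomputed from them.
#' All velocities start at zero.
#'
#' Segment lengths must be uniform within 1%: the discretization assumes
#' fixed-length rod elements (this is also what makes the per-node collision
#' spheres "closely arranged" and the distance-constraint system
#' tridiagonal).
#'
#' @param centerline `(n+1) x 3` matrix of ordered points (n >= 1 segments;
#'   for a rod, n >= 2 points).
#' @param radius collision/rendering radius in meters. Default `d / 2`, i.e.
#'   the element rest length equals the thread thickness.
#' @param K_b,K_t bend and twist stiffness in `(0, 1]` (PBD per-iteration
#'   correction scale).
#' @param d_v,d_a linear and angular damping factors in `[0, 1]`
#'   (fraction of velocity removed per second).
#' @param mass particle mass in kg (> 0); uniform.
#' @param inv_inertia scalar inverse moment of inertia per element
#'   (isotropic), in solver units. Default `1 / (mass * d^2)`, the scaling
#'   of a rod element's moment of inertia about its center.
#' @param frame_coupling factor in `(0, 1]` scaling the frame's effective
#'   inverse inertia inside the shear-stretch projection only. At 1 the
#'   frames are re-aligned to the centerline so aggressively that bending
#'   stress can no longer move positions (the Gauss-Seidel fixed point
#'   pins the frames to the segments); a small value lets frames track the
#'   centerline over a few steps while remaining governed by the
#'   bend-twist constraints, which is what gives the rod usable bending
#'   elasticity at fine discretizations.
#' @return an object of class `thread_rod` bundling the rod parameters with
#'   its particle state (positions, velocities, inverse masses) and
#'   orientation state (quaternions, angular velocities, inverse inertias).
#' @export
build_rod <- function(centerline, radius = NULL, K_b = 0.05, K_t = 0.25,
                      d_v = 0, d_a = 0, mass = 1, inv_inertia = NULL,
                      frame_coupling = 0.05) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2)
    stop("invalid topology: a rod needs at least 2 centerline points")
  stopifnot(ncol(centerline) == 3)
  stopifnot(K_b > 0, K_b <= 1, K_t > 0, K_t <= 1)
  stopifnot(d_v >= 0, d_v <= 1, d_a >= 0, d_a <= 1, mass > 0)
  n <- nrow(centerline) - 1L
  seg <- centerline[-1, , drop = FALSE] - centerline[-(n + 1), , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  if (any(lens < 1e-12))
    stop("degenerate geometry: zero-length segment in centerline")
  d <- mean(lens)
  if (max(abs(lens - d)) / d > 0.01)
    stop("discretization error: segment lengths non-uniform beyond 1%")
  if (is.null(radius)) radius <- d / 2
  stopifnot(radius > 0)
  if (is.null(inv_inertia)) inv_inertia <- 1 / (mass * d^2)
  stopifnot(inv_inertia >= 0, frame_coupling > 0, frame_coupling <= 1)
  dirs <- seg / lens
  rest_quat <- t(apply(dirs, 1, function(u) quat_from_vectors(c(0, 0, 1), u)))
  # rest Darboux product conj(q_e) q_{e+1} for adjacent element pairs
  rest_pair <- matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)
  if (n >= 2) {
    for (e in seq_len(n - 1)) {
      rest_pair[e, ] <- quat_multiply(quat_conjugate(rest_quat[e, ]),
                                      rest_quat[e + 1, ])
    }
  }
  rod <- list(
    n_particles = n + 1L, n_elements = n,
    d = d, radius = radius, K_b = K_b, K_t = K_t, d_v = d_v, d_a = d_a,
    frame_coupling = frame_coupling,
    rest_quat = rest_quat, rest_pair = rest_pair,
    particles = list(
      pos = centerline,
      vel = matrix(0, n + 1L, 3),
      inv_mass = rep(1 / mass, n + 1L)),
    orientations = list(
      quat = rest_quat,
      ang_vel = matrix(0, n, 3),
      inv_inertia = rep(inv_inertia, n)))
  class(rod) <- "thread_rod"
  rod
}

#' @export
print.thread_rod <- function(x, ...) {
  cat("<thread_rod>\n")
  cat(sprintf("  %d elements (%d particles), rest length d = %.4g m, radius = %.4g m\n",
              x$n_elements, x$n_particles, x$d, x$radius))
  cat(sprintf("  total length %.4g m; K_b = %g, K_t = %g, d_v = %g, d_a = %g\n",
              x$d * x$n_elements, x$K_b, x$K_t, x$d_v, x$d_a))
  invisible(x)
}

#' Polyline length of a position matrix
#' @param pos `n x 3` matrix of chain positions.
#' @return total length of the polyline through the rows.
#' @export
polyline_length <- function(pos) {
  seg <- pos[-1, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE]
  sum(sqrt(rowSums(seg^2)))
}
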