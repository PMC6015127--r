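# Scripted validation scenes: inextensibility sweeps, twist winding,
# dissipation, knot tying, thread-cylinder binding. Every scene is
# deterministic given its configuration; "frame" means one solver step at
# dt (there is no separate render clock).

#' Length elongation of a rod
#'
#' `100 * (current polyline length - rest length) / rest length`.
#'
#' @param rod a `thread_rod` (supplies the rest length `d * n_elements`).
#' @param positions `n x 3` positions of the rod's particles; defaults to
#'   the rod's own current positions.
#' @return elongation percentage (0 at rest, 100 at uniform 2x stretch).
#' @export
elongation_metric <- function(rod, positions = NULL) {
  stopifnot(inherits(rod, "thread_rod"))
  if (is.null(positions)) positions <- rod$particles$pos
  rest <- rod$d * rod$n_elements
  100 * (polyline_length(positions) - rest) / rest
}

#' Elongation of a rod inside a world
#' @param world a `thread_world`.
#' @param rod rod index within the world.
#' @return elongation percentage of that rod's current centerline.
#' @export
world_elongation <- function(world, rod = 1L) {
  i0 <- world$rods$first_particle[rod]
  n <- world$rods$n_particles[rod]
  pos <- world$particles$pos[i0:(i0 + n - 1L), , drop = FALSE]
  rest <- world$rods$d[rod] * (n - 1L)
  100 * (polyline_length(pos) - rest) / rest
}

new_result <- function(scene, series, summary, config, seed = NA_integer_,
                       trajectory = NULL, world = NULL) {
  out <- list(scene = scene, series = series, summary = summary,
              config = config, seed = seed, trajectory = trajectory,
              world = world)
  class(out) <- "thread_result"
  out
}

#' @export
print.thread_result <- function(x, ...) {
  cat(sprintf("<thread_result: %s>\n", x$scene))
  cat(sprintf("  %d recorded frames\n", nrow(x$series)))
  for (nm in names(x$summary)) {
    v <- x$summary[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                if (is.numeric(v)) format(signif(v, 6)) else format(v)))
  }
  invisible(x)
}

#' @export
plot.thread_result <- function(x, metric = NULL, ...) {
  cols <- setdiff(names(x$series), c("frame", "time"))
  if (is.null(metric)) metric <- cols[1]
  plot(x$series$frame, x$series[[metric]], type = "l",
       xlab = "frame", ylab = metric, main = x$scene, ...)
  invisible(x)
}

record_trajectory <- function(store) {
  if (!store) return(NULL)
  function(world, frame) world$particles$pos
}

#' Hanging spiral inextensibility scene
#'
#' A 120-element, 15 cm thread with a helical rest shape is pinned at one
#' end and dropped under gravity. Elongation is recorded every frame; with
#' the direct distance constraint the thread stays within a few percent of
#' its rest length at any iteration count, without it the elongation is
#' large at low iteration counts and decreases as iterations grow.
#'
#' @param iterations Gauss-Seidel iterations per step (the reference sweep
#'   uses 5, 10, 20, 40).
#' @param use_ddc enable the direct distance constraint.
#' @param duration simulated seconds (default 10).
#' @param n_elements,total_length rod discretization (defaults 120, 0.15 m).
#' @param helix_radius,pitch spiral rest-shape parameters (defaults 5 mm
#'   radius, 2 cm pitch: about four turns over 15 cm).
#' @param dt time step (default 1/60 s).
#' @param store_trajectory keep per-frame positions in the result.
#' @return a `thread_result`; `summary$max_elongation_pct` is the maximum
#'   over all recorded frames.
#' @export
hanging_spiral_experiment <- function(iterations = 10L, use_ddc = TRUE,
                                      duration = 10, n_elements = 120L,
                                      total_length = 0.15,
                                      helix_radius = 0.005, pitch = 0.02,
                                      dt = 1 / 60,
                                      store_trajectory = FALSE) {
  pts <- make_spiral_centerline(total_length, n_elements, helix_radius,
                                pitch)
  # helix axis +z -> hang along -y (rotate -90 degrees about x)
  pts <- cbind(pts[, 1], -pts[, 3], pts[, 2])
  rod <- build_rod(pts, K_b = 0.05, K_t = 0.25, d_v = 0.1, d_a = 0.1)
  cfg <- sim_config(dt = dt, iterations = iterations, use_ddc = use_ddc,
                    collision_enabled = TRUE, friction_k = 0.5)
  world <- make_world(rod, config = cfg)
  world <- pin_particle(world, 1L)
  n_steps <- round(duration / dt)
  traj <- if (store_trajectory) vector("list", n_steps) else NULL
  elong <- numeric(n_steps)
  for (f in seq_len(n_steps)) {
    world <- sim_step(world)
    elong[f] <- world_elongation(world)
    if (store_trajectory) traj[[f]] <- world$particles$pos
  }
  series <- data.frame(frame = seq_len(n_steps),
                       time = seq_len(n_steps) * dt,
                       elongation_pct = elong)
  new_result("hanging_spiral", series,
             summary = list(max_elongation_pct = max(elong),
                            final_elongation_pct = elong[n_steps],
                            iterations = iterations, use_ddc = use_ddc),
             config = cfg, trajectory = traj, world = world)
}

#' Iteration-count elongation sweep
#'
#' Runs [hanging_spiral_experiment()] over iteration counts with and/or
#' without the direct distance constraint and tabulates the maximum
#' elongation of each run.
#'
#' @param iteration_counts integer vector (default `c(5, 10, 20, 40)`).
#' @param ddc logical vector of DDC settings to cross with the counts.
#' @param ... passed to [hanging_spiral_experiment()].
#' @return data.frame with columns `iterations`, `use_ddc`,
#'   `max_elongation_pct`, `final_elongation_pct`.
#' @export
elongation_sweep <- function(iteration_counts = c(5L, 10L, 20L, 40L),
                             ddc = c(TRUE, FALSE), ...) {
  rows <- list()
  for (use_ddc in ddc) {
    for (it in iteration_counts) {
      res <- hanging_spiral_experiment(iterations = it, use_ddc = use_ddc,
                                       ...)
      rows[[length(rows) + 1]] <- data.frame(
        iterations = it, use_ddc = use_ddc,
        max_elongation_pct = res$summary$max_elongation_pct,
        final_elongation_pct = res$summary$final_elongation_pct)
    }
  }
  do.call(rbind, rows)
}

#' Compression-release dissipation scene
#'
#' A 49-element, 2 cm thread with no gravity or friction: the left end is
#' clamped (position and frame), the right end is gripped and pushed 1 cm
#' inward over two seconds, quasi-statically compressing and buckling the
#' thread, and then released. For 500 frames after release the summed
#' distance of all particles to their pre-compression positions is
#' recorded. With zero angular damping the thread keeps oscillating and
#' the metric never settles; larger damping factors settle it faster.
#'
#' The initial centerline carries a small multi-harmonic transverse seed
#' (a generic imperfection, a fraction of the thread radius) so that the
#' inextensible compression buckles deterministically into a mix of modes;
#' the compression phase runs with heavy damping so the released state is
#' at rest and the recorded motion is purely the elastic recovery.
#'
#' @param d_a angular velocity damping factor in `[0, 1]` during the
#'   recorded phase.
#' @param n_frames frames recorded after release (default 500).
#' @param d_v linear damping factor during the recorded phase (default 0:
#'   the scene isolates the angular channel).
#' @param dt time step (default 1/60 s).
#' @return a `thread_result`; the series column `settle_distance_m` is the
#'   metric, and the summary reports its initial value, the first frame at
#'   which it falls below half that value (`NA` if never), and the minimum
#'   fraction of the initial value reached.
#' @export
compression_release_experiment <- function(d_a, n_frames = 500L, d_v = 0,
                                           dt = 1 / 60) {
  n_el <- 49L
  L <- 0.02
  z <- seq(0, L, length.out = n_el + 1)
  s <- seq(0, 1, length.out = n_el + 1)
  pts <- cbind(z, 0, 0)
  rod <- build_rod(pts, K_b = 0.5, K_t = 0.5, d_v = 0.9, d_a = 0.9)
  # generic transverse imperfection so the inextensible compression
  # buckles deterministically into several modes
  rod$particles$pos[, 2] <- rod$particles$pos[, 2] +
    2e-4 * (sin(pi * s) + 0.6 * sin(2 * pi * s))
  rod$particles$pos[, 3] <- rod$particles$pos[, 3] +
    1.5e-4 * (sin(3 * pi * s) - 0.4 * sin(pi * s))
  init_pos <- rod$particles$pos
  cfg <- sim_config(dt = dt, iterations = 10L, use_ddc = TRUE,
                    gravity = c(0, 0, 0), collision_enabled = FALSE)
  world <- make_world(rod, config = cfg)
  world <- pin_particle(world, 1L)
  world <- hold_element(world, 1L)
  right <- n_el + 1L
  world <- pin_particle(world, right)
  world <- hold_element(world, n_el)
  # compression phase: right end moves 1 cm inward over two seconds
  compress_frames <- round(2 / dt)
  x0 <- init_pos[right, 1]
  for (f in seq_len(compress_frames)) {
    world$particles$pos[right, 1] <- x0 - 0.01 * f / compress_frames
    world <- sim_step(world)
  }
  world$rods$d_v <- d_v
  world$rods$d_a <- d_a
  world <- pin_particle(world, right, pinned = FALSE)
  world <- hold_element(world, n_el, held = FALSE)
  metric <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    world <- sim_step(world)
    dp <- world$particles$pos - init_pos
    metric[f] <- sum(sqrt(rowSums(dp^2)))
  }
  half_frame <- which(metric < metric[1] / 2)[1]
  series <- data.frame(frame = seq_len(n_frames),
                       time = seq_len(n_frames) * dt,
                       settle_distance_m = metric)
  new_result("compression_release", series,
             summary = list(initial_distance_m = metric[1],
                            half_settle_frame = half_frame,
                            min_fraction = min(metric) / metric[1],
                            d_a = d_a),
             config = cfg, world = world)
}

# circular arc in the xz... xy-plane sagging in -y, chord along +x,
# uniform chords by uniform angle sampling
arc_centerline <- function(chord, length, n) {
  stopifnot(chord < length)
  f <- function(phi) 2 * sin(phi / 2) / phi - chord / length
  phi <- uniroot(f, c(1e-6, 2 * pi - 1e-6), tol = 1e-14)$root
  rho <- length / phi
  h <- rho * cos(phi / 2)
  gamma <- seq(-phi / 2, phi / 2, length.out = n + 1)
  cbind(chord / 2 + rho * sin(gamma), h - rho * cos(gamma), 0)
}

winding_count_from_z <- function(z, threshold) {
  s <- sign(z[abs(z) > threshold])
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Twist winding scene
#'
#' A slack thread (40 elements, 15 cm, ends clamped 12 cm apart along the
#' x axis with a gentle sag and a small out-of-plane imperfection) whose
#' right end material frame is rotated about the world x axis. With twist
#' stiffness the accumulated twist couples into bending and the thread
#' loops out of its initial plane (twist converting to writhe); reducing
#' the bend stiffness at fixed twist stiffness reduces the winding. The
#' scene runs without gravity: axial tension from the hanging weight
#' suppresses the writhe instability at these stiffness scales.
#'
#' @param K_b,K_t bend and twist stiffness in `[0, 1]` (`K_t = 0` disables
#'   the twist coupling).
#' @param total_rotation end rotation in radians (default `10 * pi`).
#' @param ramp_duration seconds over which the rotation ramps (default 6).
#' @param settle_duration seconds simulated after the ramp (default 4).
#' @param dt time step (default 1/60 s).
#' @return a `thread_result` with summary `winding_count` (sign changes of
#'   the out-of-plane deflection along the centerline) and
#'   `max_out_of_plane_m`.
#' @export
twist_winding_experiment <- function(K_b = 0.8, K_t = 0.8,
                                     total_rotation = 10 * pi,
                                     ramp_duration = 6, settle_duration = 4,
                                     dt = 1 / 60) {
  n_el <- 40L
  L <- 0.15
  pts <- arc_centerline(0.8 * L, L, n_el)
  s <- seq(0, 1, length.out = n_el + 1)
  pts[, 3] <- pts[, 3] + 1e-3 * sin(2 * pi * s)  # out-of-plane seed
  Kb_eff <- max(K_b, 1e-9)  # build_rod wants positive; 0 means "off"
  Kt_eff <- max(K_t, 1e-9)
  rod <- build_rod(pts, K_b = Kb_eff, K_t = Kt_eff, d_v = 0.1, d_a = 0.1)
  rod$K_t <- K_t
  rod$K_b <- K_b
  cfg <- sim_config(dt = dt, iterations = 10L, use_ddc = TRUE,
                    gravity = c(0, 0, 0),
                    collision_enabled = TRUE, friction_k = 0.5)
  world <- make_world(rod, config = cfg)
  world <- pin_particle(world, 1L)
  world <- pin_particle(world, n_el + 1L)
  world <- hold_element(world, 1L)
  world <- hold_element(world, n_el)
  q_end0 <- world$orientations$quat[n_el, ]
  ramp_frames <- round(ramp_duration / dt)
  settle_frames <- round(settle_duration / dt)
  n_steps <- ramp_frames + settle_frames
  maxz <- numeric(n_steps)
  for (f in seq_len(n_steps)) {
    theta <- total_rotation * min(f / ramp_frames, 1)
    world$orientations$quat[n_el, ] <-
      quat_multiply(quat_axis_angle(c(1, 0, 0), theta), q_end0)
    world <- sim_step(world)
    maxz[f] <- max(abs(world$particles$pos[, 3]))
  }
  z <- world$particles$pos[, 3]
  series <- data.frame(frame = seq_len(n_steps),
                       time = seq_len(n_steps) * dt,
                       max_out_of_plane_m = maxz)
  new_result("twist_winding", series,
             summary = list(
               winding_count = winding_count_from_z(z, rod$radius / 2),
               max_out_of_plane_m = max(maxz),
               final_out_of_plane_m = max(abs(z)),
               K_b = K_b, K_t = K_t),
             config = cfg, world = world)
}

# resample a (densely sampled) polyline to n uniform chord-length segments
resample_centerline <- function(raw, n) {
  seg <- sqrt(rowSums((raw[-1, , drop = FALSE] -
                         raw[-nrow(raw), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  tgt <- seq(0, cs[length(cs)], length.out = n + 1)
  cbind(approx(cs, raw[, 1], xout = tgt)$y,
        approx(cs, raw[, 2], xout = tgt)$y,
        approx(cs, raw[, 3], xout = tgt)$y)
}

# open overhand-knot space curve (trefoil segment), resampled to uniform
# arc length
trefoil_centerline <- function(total_length, n) {
  t <- seq(0.25, 2 * pi - 0.25, length.out = 4000)
  raw <- cbind(sin(t) + 2 * sin(2 * t),
               cos(t) - 2 * cos(2 * t),
               -sin(3 * t))
  seg <- sqrt(rowSums((raw[-1, ] - raw[-nrow(raw), ])^2))
  raw <- raw * (total_length / sum(seg))
  resample_centerline(raw, n)
}

#' Knot tightening scene
#'
#' A thread laid out as a loose overhand knot (an open trefoil curve) has
#' both ends pulled apart by a scripted end-effector path, tightening the
#' knot against its self-contacts. Continuous collision detection must keep
#' the thread from tunneling through itself: the minimum center distance
#' between non-neighboring spheres never drops below one thread diameter
#' (up to the contact tolerance), and the tightened knot persists.
#'
#' @param script optional end waypoint script: a data.frame with columns
#'   `time`, `particle` (1 or the last particle index), `x`, `y`, `z`,
#'   linearly interpolated. Defaults to the shipped pull-apart path
#'   (`extdata/knot_pull_script.csv`, scaled to the scene).
#' @param n_elements rod discretization (default 100).
#' @param total_length thread length in meters (default 0.15).
#' @param duration simulated seconds (default 4).
#' @param friction_k thread-thread friction strength (default 0.5).
#' @param dt time step (default 1/300 s; the contact scenes run finer than
#'   the free-space scenes so position-level contacts resolve gracefully at
#'   millimeter geometry).
#' @return a `thread_result` with summary `min_separation_m`,
#'   `final_elongation_pct` and the thread `diameter_m`.
#' @export
knot_experiment <- function(script = NULL, n_elements = 100L,
                            total_length = 0.15, duration = 4,
                            friction_k = 0.5, dt = 1 / 300) {
  pts <- trefoil_centerline(total_length, n_elements)
  rod <- build_rod(pts, K_b = 0.05, K_t = 0.25, d_v = 0.2, d_a = 0.2)
  cfg <- sim_config(dt = dt, iterations = 10L, use_ddc = TRUE,
                    gravity = c(0, 0, 0), collision_enabled = TRUE,
                    friction_k = friction_k)
  world <- make_world(rod, config = cfg)
  last <- n_elements + 1L
  world <- pin_particle(world, 1L)
  world <- pin_particle(world, last)
  if (is.null(script)) {
    path <- system.file("extdata", "knot_pull_script.csv",
                        package = "threadsim")
    script <- read.csv(path)
    # shipped script is in scene units: offsets relative to each end's
    # start, along the end-to-end axis
    u <- pts[last, ] - pts[1, ]
    u <- u / sqrt(sum(u^2))
    s1 <- script[script$particle == 1, ]
    s2 <- script[script$particle == 2, ]
    script <- rbind(
      data.frame(time = s1$time, particle = 1L,
                 x = pts[1, 1] - u[1] * s1$pull,
                 y = pts[1, 2] - u[2] * s1$pull,
                 z = pts[1, 3] - u[3] * s1$pull),
      data.frame(time = s2$time, particle = last,
                 x = pts[last, 1] + u[1] * s2$pull,
                 y = pts[last, 2] + u[2] * s2$pull,
                 z = pts[last, 3] + u[3] * s2$pull))
  }
  n_steps <- round(duration / dt)
  minsep <- numeric(n_steps)
  elong <- numeric(n_steps)
  for (f in seq_len(n_steps)) {
    t_now <- f * dt
    for (p in unique(script$particle)) {
      sp <- script[script$particle == p, ]
      world$particles$pos[p, ] <- c(
        approx(sp$time, sp$x, xout = t_now, rule = 2)$y,
        approx(sp$time, sp$y, xout = t_now, rule = 2)$y,
        approx(sp$time, sp$z, xout = t_now, rule = 2)$y)
    }
    world <- sim_step(world, report_min_separation = TRUE)
    minsep[f] <- world$report$min_separation
    elong[f] <- world_elongation(world)
  }
  series <- data.frame(frame = seq_len(n_steps),
                       time = seq_len(n_steps) * dt,
                       min_separation_m = minsep,
                       elongation_pct = elong)
  new_result("knot_tightening", series,
             summary = list(min_separation_m = min(minsep),
                            final_elongation_pct = elong[n_steps],
                            diameter_m = 2 * rod$radius),
             config = cfg, world = world)
}

#' Thread tied around a cylinder (friction binding scene)
#'
#' A single throw around a static rigid cylinder: the thread wraps the
#' (horizontal) cylinder two and a half turns, with both free ends hanging
#' down so their weight tensions the wrap against the surface (a capstan
#' configuration). Gravity is tilted fifteen degrees toward the cylinder
#' axis, so an axial force component constantly drives the wrap along the
#' cylinder. After a two-second settling phase the axial drift of the
#' thread is recorded for `duration` seconds. With friction strength 1 the
#' wrap shows no relative slip (axial drift well below one thread
#' diameter); with friction 0 it slides off freely.
#'
#' The scene runs at a finer time step than the free-space scenes: with a
#' millimeter-scale thread, a single 1/60 s gravity step moves a resting
#' particle farther than the thread radius, which no position-level
#' friction constraint can survive.
#'
#' @param friction friction strength `[0, 1]` of the cylinder contacts.
#' @param duration measured simulated seconds after settling (default 5).
#' @param dt time step (default 1/600 s).
#' @param settle settling seconds before measurement starts (default 2).
#' @return a `thread_result` with summary `axial_drift_m` (mean axial
#'   displacement magnitude over the measured window) and `diameter_m`.
#' @export
cylinder_wrap_experiment <- function(friction = 1, duration = 5,
                                     dt = 1 / 600, settle = 2) {
  Rc <- 0.005
  L <- 0.15
  n_el <- 80L
  d <- L / n_el
  r <- d / 2
  turns <- 2.5
  Rw <- Rc + r
  warc <- turns * 2 * pi * Rw
  a <- 0.0022 * turns  # axial advance across the wrap: keeps coils apart
  t1 <- (L - warc) / 2
  s <- seq(0, L, length.out = 4001)
  raw <- t(vapply(s, function(si) {
    if (si <= t1) {
      c(-a / 2, -(t1 - si), Rw)                      # entry tail, hanging
    } else if (si <= t1 + warc) {
      phi <- pi / 2 - turns * 2 * pi * (si - t1) / warc
      c(-a / 2 + a * (si - t1) / warc, Rw * cos(phi), Rw * sin(phi))
    } else {
      c(a / 2, -(si - t1 - warc), -Rw)               # exit tail
    }
  }, numeric(3)))
  pts <- resample_centerline(raw, n_el)
  rod <- build_rod(pts, K_b = 0.5, K_t = 0.5, d_v = 0.2, d_a = 0.2)
  cyl <- collider_cylinder(c(0, 0, 0), c(1, 0, 0), Rc, friction = friction)
  tilt <- 15 * pi / 180
  cfg <- sim_config(dt = dt, iterations = 10L, use_ddc = TRUE,
                    gravity = 9.81 * c(sin(tilt), -cos(tilt), 0),
                    collision_enabled = TRUE, friction_k = friction)
  world <- make_world(rod, colliders = list(cyl), config = cfg)
  for (f in seq_len(round(settle / dt))) world <- sim_step(world)
  x0 <- mean(world$particles$pos[, 1])
  n_steps <- round(duration / dt)
  drift <- numeric(n_steps)
  for (f in seq_len(n_steps)) {
    world <- sim_step(world)
    drift[f] <- abs(mean(world$particles$pos[, 1]) - x0)
  }
  series <- data.frame(frame = seq_len(n_steps),
                       time = seq_len(n_steps) * dt,
                       axial_drift_m = drift)
  new_result("cylinder_wrap", series,
             summary = list(axial_drift_m = drift[n_steps],
                            max_drift_m = max(drift),
                            diameter_m = 2 * rod$radius,
                            friction = friction),
             config = cfg, world = world)
}
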