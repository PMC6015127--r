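# Assembling rods and static colliders into a simulation world, and
# stepping it. A world concatenates all rod particle/orientation arrays;
# rod descriptors keep the index ranges so the compiled stepper and the
# collision filter know the chain topology.

#' Assemble a simulation world
#'
#' @param rods a `thread_rod` or a list of them (see [build_rod()]).
#' @param colliders optional list of static rigid colliders, each created by
#'   [collider_plane()], [collider_sphere()] or [collider_cylinder()].
#' @param config a [sim_config()].
#' @return an object of class `thread_world`.
#' @export
make_world <- function(rods, colliders = list(), config = sim_config()) {
  if (inherits(rods, "thread_rod")) rods <- list(rods)
  stopifnot(length(rods) >= 1, all(vapply(rods, inherits, TRUE, "thread_rod")))
  stopifnot(inherits(config, "sim_config"))
  pos <- do.call(rbind, lapply(rods, function(r) r$particles$pos))
  vel <- do.call(rbind, lapply(rods, function(r) r$particles$vel))
  w <- unlist(lapply(rods, function(r) r$particles$inv_mass))
  quat <- do.call(rbind, lapply(rods, function(r) r$orientations$quat))
  ang_vel <- do.call(rbind, lapply(rods, function(r) r$orientations$ang_vel))
  wq <- unlist(lapply(rods, function(r) r$orientations$inv_inertia))
  rest_pair <- do.call(rbind, lapply(rods, function(r) r$rest_pair))
  np <- vapply(rods, function(r) r$n_particles, 1L)
  ne <- vapply(rods, function(r) r$n_elements, 1L)
  desc <- list(
    first_particle = cumsum(c(1L, np))[seq_along(rods)],
    n_particles = np,
    first_element = cumsum(c(1L, ne))[seq_along(rods)],
    d = vapply(rods, function(r) r$d, 1),
    radius = vapply(rods, function(r) r$radius, 1),
    K_b = vapply(rods, function(r) r$K_b, 1),
    K_t = vapply(rods, function(r) r$K_t, 1),
    d_v = vapply(rods, function(r) r$d_v, 1),
    d_a = vapply(rods, function(r) r$d_a, 1),
    frame_coupling = vapply(rods, function(r) r$frame_coupling, 1))
  w_obj <- list(
    particles = list(pos = pos, vel = vel, inv_mass = w),
    orientations = list(quat = quat, ang_vel = ang_vel, inv_inertia = wq),
    rods = desc,
    rest_pair = rest_pair,
    colliders = colliders,
    config = config,
    time = 0)
  class(w_obj) <- "thread_world"
  w_obj
}

#' @export
print.thread_world <- function(x, ...) {
  cat("<thread_world>\n")
  cat(sprintf("  %d rod(s), %d particles, %d elements, %d collider(s)\n",
              length(x$rods$n_particles), nrow(x$particles$pos),
              nrow(x$orientations$quat), length(x$colliders)))
  cat(sprintf("  simulated time: %.4g s\n", x$time))
  invisible(x)
}

#' Static plane collider
#' @param normal outward unit normal of the plane (normalized internally).
#' @param offset plane offset: the surface is `normal . x == offset`.
#' @param friction friction strength `[0, 1]` for contacts with this plane.
#' @return a collider description.
#' @export
collider_plane <- function(normal, offset, friction = 0.5) {
  normal <- normal / sqrt(sum(normal^2))
  list(type = "plane", normal = normal, offset = offset, friction = friction)
}

#' Static sphere collider
#' @param center sphere center (length-3).
#' @param radius sphere radius (> 0).
#' @param friction friction strength `[0, 1]`.
#' @return a collider description.
#' @export
collider_sphere <- function(center, radius, friction = 0.5) {
  stopifnot(radius > 0)
  list(type = "sphere", center = center, radius = radius, friction = friction)
}

#' Static cylinder collider (infinite axis)
#' @param point a point on the cylinder axis.
#' @param axis axis direction (normalized internally).
#' @param radius cylinder radius (> 0).
#' @param friction friction strength `[0, 1]`.
#' @return a collider description.
#' @export
collider_cylinder <- function(point, axis, radius, friction = 0.5) {
  stopifnot(radius > 0)
  axis <- axis / sqrt(sum(axis^2))
  list(type = "cylinder", point = point, axis = axis, radius = radius,
       friction = friction)
}

collider_matrix <- function(colliders) {
  if (length(colliders) == 0)
    return(list(mat = matrix(0, 0, 8), k = numeric(0)))
  rows <- lapply(colliders, function(cl) {
    switch(cl$type,
      plane = c(0, cl$normal, cl$offset, 0, 0, 0),
      sphere = c(1, cl$center, 0, 0, 0, cl$radius),
      cylinder = c(2, cl$point, cl$axis, cl$radius),
      stop("unknown collider type: ", cl$type))
  })
  list(mat = do.call(rbind, rows),
       k = vapply(colliders, function(cl) cl$friction, 1))
}

#' Pin or release a particle
#'
#' A pinned particle has inverse mass 0 and never moves during prediction or
#' projection; scripted boundary motion moves pinned particles directly.
#'
#' @param world a `thread_world`.
#' @param index particle index (1-based, into the concatenated world arrays).
#' @param pinned `TRUE` to pin, `FALSE` to release (restores inverse mass 1).
#' @return the modified world.
#' @export
pin_particle <- function(world, index, pinned = TRUE) {
  world$particles$inv_mass[index] <- if (pinned) 0 else 1
  if (pinned) world$particles$vel[index, ] <- 0
  world
}

#' Hold or release an element orientation
#' @param world a `thread_world`.
#' @param index element index (1-based).
#' @param held `TRUE` sets the inverse inertia to 0 (frame never rotates
#'   during projection), `FALSE` restores 1.
#' @return the modified world.
#' @export
hold_element <- function(world, index, held = TRUE) {
  world$orientations$inv_inertia[index] <- if (held) 0 else 1
  if (held) world$orientations$ang_vel[index, ] <- 0
  world
}

step_cfg <- function(world, report_min_separation = FALSE) {
  cfg <- world$config
  cell <- cfg$cell_size
  if (is.null(cell)) cell <- 4 * world$rods$radius[1]
  list(dt = cfg$dt, iterations = cfg$iterations, use_ddc = cfg$use_ddc,
       gravity = cfg$gravity, friction_k = cfg$friction_k, cell_size = cell,
       collision_enabled = cfg$collision_enabled,
       report_min_separation = report_min_separation)
}

#' Advance the world by one time step
#'
#' One full PBD step: symplectic-Euler prediction of positions and
#' first-order quaternion prediction; continuous collision detection from
#' the current to the predicted state; `iterations` Gauss-Seidel sweeps
#' projecting shear-stretch, bend-twist, contact and friction constraints,
#' with the direct distance constraint solved last in every sweep when
#' enabled; velocity update from the corrected state; and per-second
#' velocity damping. Deterministic for identical inputs.
#'
#' @param world a `thread_world`.
#' @param report_min_separation also compute the minimum center distance
#'   between non-neighboring collision spheres (O(n^2); used by the contact
#'   scenes).
#' @return the advanced world; the step diagnostics are attached as
#'   `world$report` (constraint residual maxima, active contact count,
#'   minimum separation if requested).
#' @export
sim_step <- function(world, report_min_separation = FALSE) {
  cm <- collider_matrix(world$colliders)
  res <- cpp_step(
    world$particles$pos, world$particles$vel, world$particles$inv_mass,
    world$orientations$quat, world$orientations$ang_vel,
    world$orientations$inv_inertia,
    as.integer(world$rods$first_particle - 1L),
    as.integer(world$rods$n_particles),
    as.integer(world$rods$first_element - 1L),
    world$rods$d, world$rods$radius, world$rods$K_b, world$rods$K_t,
    world$rods$d_v, world$rods$d_a, world$rods$frame_coupling,
    world$rest_pair, cm$mat, cm$k,
    step_cfg(world, report_min_separation))
  world$particles$pos <- res$pos
  world$particles$vel <- res$vel
  world$orientations$quat <- res$quat
  world$orientations$ang_vel <- res$angvel
  world$time <- world$time + world$config$dt
  world$report <- res$report
  world
}

#' Run the world for many steps
#'
#' @param world a `thread_world`.
#' @param n_steps number of steps to take.
#' @param callback optional `function(world, frame)` run after every step;
#'   if it returns a `thread_world` the run continues from it (this is how
#'   scripted boundary motions are injected).
#' @param record optional `function(world, frame)` whose (scalar or vector)
#'   value is collected per frame.
#' @param report_min_separation passed to [sim_step()].
#' @return list with `world` (final state) and `recorded` (list of per-frame
#'   values, `NULL` if `record` was not given).
#' @export
sim_run <- function(world, n_steps, callback = NULL, record = NULL,
                    report_min_separation = FALSE) {
  recorded <- if (is.null(record)) NULL else vector("list", n_steps)
  for (f in seq_len(n_steps)) {
    if (!is.null(callback)) {
      out <- callback(world, f)
      if (inherits(out, "thread_world")) world <- out
    }
    world <- sim_step(world, report_min_separation)
    if (!is.null(record)) recorded[[f]] <- record(world, f)
  }
  list(world = world, recorded = recorded)
}

#' Rod membership vectors of the world particles
#' @param world a `thread_world`.
#' @return list with integer vectors `rod_id` and `chain_pos` (1-based
#'   position along the owning rod) for every particle.
#' @keywords internal
particle_topology <- function(world) {
  nr <- length(world$rods$n_particles)
  rod_id <- integer(0)
  chain_pos <- integer(0)
  for (rd in seq_len(nr)) {
    rod_id <- c(rod_id, rep(rd, world$rods$n_particles[rd]))
    chain_pos <- c(chain_pos, seq_len(world$rods$n_particles[rd]))
  }
  list(rod_id = rod_id, chain_pos = chain_pos)
}

#' Minimum separation between non-neighboring collision spheres
#' @param world a `thread_world`.
#' @return minimum center distance over all particle pairs, excluding pairs
#'   on the same rod within two chain positions of each other.
#' @export
min_separation <- function(world) {
  tp <- particle_topology(world)
  cpp_min_separation(world$particles$pos, as.integer(tp$rod_id - 1L),
                     as.integer(tp$chain_pos - 1L))
}
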