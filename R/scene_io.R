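# Scene configuration files (YAML), trajectory/metric CSV output, and
# centerline OBJ export. Scene files are validated strictly: unknown keys
# are rejected by name so typos fail loudly instead of being ignored.

scene_schema <- list(
  top = c("schema_version", "units", "seed", "sim", "rods", "colliders",
          "output", "run"),
  sim = c("dt", "iterations", "use_ddc", "gravity", "friction_k",
          "cell_size", "collision_enabled"),
  rod = c("type", "total_length", "n_elements", "radius", "helix_radius",
          "pitch", "origin", "K_b", "K_t", "d_v", "d_a", "mass", "pin",
          "points"),
  collider = c("type", "normal", "offset", "center", "point", "axis",
               "radius", "friction"),
  output = c("trajectory", "metrics", "obj"),
  run = c("duration"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0)
    stop(sprintf("scene schema violation in '%s': unknown key '%s'",
                 where, bad[1]))
  invisible(x)
}

#' Load a scene configuration file
#'
#' Reads and validates a YAML scene description. Lengths may be given in
#' centimeters by declaring `units: cm`; everything is converted to meters
#' on load. Unknown keys anywhere in the file are rejected with an error
#' naming the offending key; physical parameters are range-checked.
#'
#' @param path path to a YAML scene file.
#' @return a validated `scene_config` list with fields `schema_version`,
#'   `seed`, `sim` (a [sim_config()]), `rods`, `colliders`, `output`,
#'   `run`.
#' @export
load_scene <- function(path) {
  if (!file.exists(path)) stop("scene file not found: ", path)
  raw <- yaml::read_yaml(path)
  check_keys(raw, scene_schema$top, "scene")
  unit <- if (is.null(raw$units)) "m" else raw$units
  if (!unit %in% c("m", "cm")) stop("scene schema violation: units must be 'm' or 'cm'")
  s <- if (unit == "cm") 0.01 else 1
  simr <- if (is.null(raw$sim)) list() else raw$sim
  check_keys(simr, scene_schema$sim, "sim")
  cfg <- sim_config(
    dt = simr$dt %||% (1 / 60),
    iterations = simr$iterations %||% 10L,
    use_ddc = simr$use_ddc %||% TRUE,
    gravity = unlist(simr$gravity %||% c(0, -9.81, 0)),
    friction_k = simr$friction_k %||% 0.5,
    cell_size = if (is.null(simr$cell_size)) NULL else simr$cell_size * s,
    collision_enabled = simr$collision_enabled %||% TRUE,
    seed = raw$seed %||% 1L)
  rods <- lapply(seq_along(raw$rods %||% list()), function(i) {
    rd <- raw$rods[[i]]
    check_keys(rd, scene_schema$rod, sprintf("rods[%d]", i))
    if (!is.null(rd$radius) && rd$radius <= 0)
      stop("scene schema violation: 'radius' must be positive")
    if (!is.null(rd$total_length) && rd$total_length <= 0)
      stop("scene schema violation: 'total_length' must be positive")
    for (f in c("total_length", "radius", "helix_radius", "pitch"))
      if (!is.null(rd[[f]])) rd[[f]] <- rd[[f]] * s
    if (!is.null(rd$origin)) rd$origin <- unlist(rd$origin) * s
    if (!is.null(rd$points))
      rd$points <- matrix(unlist(rd$points), ncol = 3, byrow = TRUE) * s
    rd$type <- rd$type %||% "straight"
    rd
  })
  colliders <- lapply(seq_along(raw$colliders %||% list()), function(i) {
    cl <- raw$colliders[[i]]
    check_keys(cl, scene_schema$collider, sprintf("colliders[%d]", i))
    if (!is.null(cl$radius) && cl$radius <= 0)
      stop("scene schema violation: 'radius' must be positive")
    for (f in c("offset", "radius")) if (!is.null(cl[[f]])) cl[[f]] <- cl[[f]] * s
    for (f in c("center", "point")) if (!is.null(cl[[f]])) cl[[f]] <- unlist(cl[[f]]) * s
    if (!is.null(cl$normal)) cl$normal <- unlist(cl$normal)
    if (!is.null(cl$axis)) cl$axis <- unlist(cl$axis)
    cl
  })
  if (!is.null(raw$output)) check_keys(raw$output, scene_schema$output, "output")
  if (!is.null(raw$run)) check_keys(raw$run, scene_schema$run, "run")
  out <- list(schema_version = raw$schema_version %||% 1L,
              seed = as.integer(raw$seed %||% 1L),
              sim = cfg, rods = rods, colliders = colliders,
              output = raw$output %||% list(),
              run = list(duration = (raw$run %||% list())$duration %||% 1))
  class(out) <- "scene_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a scene configuration file
#'
#' Inverse of [load_scene()]: writes a YAML file (in meters) that loads
#' back to an identical `scene_config`.
#'
#' @param scene a `scene_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene_config"))
  cfg <- scene$sim
  out <- list(
    schema_version = scene$schema_version,
    units = "m",
    seed = scene$seed,
    sim = list(dt = cfg$dt, iterations = cfg$iterations,
               use_ddc = cfg$use_ddc, gravity = cfg$gravity,
               friction_k = cfg$friction_k,
               collision_enabled = cfg$collision_enabled),
    rods = scene$rods,
    colliders = scene$colliders,
    output = scene$output,
    run = scene$run)
  if (!is.null(cfg$cell_size)) out$sim$cell_size <- cfg$cell_size
  if (length(out$colliders) == 0) out$colliders <- NULL
  if (length(out$output) == 0) out$output <- NULL
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Instantiate a world from a scene configuration
#'
#' @param scene a `scene_config` from [load_scene()].
#' @return a `thread_world`.
#' @export
world_from_scene <- function(scene) {
  stopifnot(inherits(scene, "scene_config"))
  rods <- lapply(scene$rods, function(rd) {
    pts <- switch(rd$type,
      straight = {
        z <- seq(0, rd$total_length, length.out = rd$n_elements + 1)
        cbind(0, 0, z)
      },
      spiral = make_spiral_centerline(rd$total_length, rd$n_elements,
                                      rd$helix_radius %||% 0.005,
                                      rd$pitch %||% 0.02),
      points = rd$points,
      stop("scene schema violation: unknown rod type '", rd$type, "'"))
    if (!is.null(rd$origin))
      pts <- sweep(pts, 2, rd$origin, "+")
    build_rod(pts, radius = rd$radius,
              K_b = rd$K_b %||% 0.05, K_t = rd$K_t %||% 0.25,
              d_v = rd$d_v %||% 0, d_a = rd$d_a %||% 0,
              mass = rd$mass %||% 1)
  })
  colliders <- lapply(scene$colliders, function(cl) {
    switch(cl$type,
      plane = collider_plane(cl$normal, cl$offset, cl$friction %||% 0.5),
      sphere = collider_sphere(cl$center, cl$radius, cl$friction %||% 0.5),
      cylinder = collider_cylinder(cl$point, cl$axis, cl$radius,
                                   cl$friction %||% 0.5),
      stop("scene schema violation: unknown collider type '", cl$type, "'"))
  })
  world <- make_world(rods, colliders = colliders, config = scene$sim)
  offset <- 0L
  for (i in seq_along(scene$rods)) {
    for (p in scene$rods[[i]]$pin %||% integer(0))
      world <- pin_particle(world, offset + as.integer(p))
    offset <- offset + world$rods$n_particles[i]
  }
  world
}

#' Write trajectory and metrics tables
#'
#' Trajectory: one row per frame per particle with columns `frame`,
#' `particle`, `x_m`, `y_m`, `z_m`. Metrics: one row per frame with the
#' result's metric columns (units in the header names). Both are plain CSV
#' with a header row, written deterministically.
#'
#' @param result a `thread_result` holding a trajectory (run the scene with
#'   `store_trajectory = TRUE` or record positions through [sim_run()]).
#' @param path trajectory CSV path.
#' @param metrics_path metrics CSV path; default replaces the extension of
#'   `path` with `_metrics.csv`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(result, path,
                             metrics_path = sub("(\\.[^.]*)?$",
                                                "_metrics.csv", path)) {
  stopifnot(inherits(result, "thread_result"))
  if (is.null(result$trajectory))
    stop("result holds no trajectory; rerun with store_trajectory = TRUE")
  frames <- length(result$trajectory)
  n <- nrow(result$trajectory[[1]])
  tab <- data.frame(
    frame = rep(seq_len(frames), each = n),
    particle = rep(seq_len(n), times = frames),
    x_m = unlist(lapply(result$trajectory, function(p) p[, 1])),
    y_m = unlist(lapply(result$trajectory, function(p) p[, 2])),
    z_m = unlist(lapply(result$trajectory, function(p) p[, 3])))
  write.csv(format(tab, digits = 17, scientific = NA, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  write.csv(format(result$series, digits = 17, scientific = NA, trim = TRUE),
            metrics_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV back into position matrices
#'
#' @param path a trajectory file written by [write_trajectory()].
#' @return list of `n x 3` position matrices, one per frame.
#' @export
read_trajectory <- function(path) {
  tab <- read.csv(path)
  lapply(split(tab, tab$frame),
         function(fr) unname(cbind(fr$x_m, fr$y_m, fr$z_m)))
}

#' Export a centerline as a Wavefront OBJ polyline
#'
#' Writes one `v` record per point and a single `l` record chaining them.
#'
#' @param positions `n x 3` matrix (n >= 2).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_centerline_obj <- function(positions, path) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) >= 2, ncol(positions) == 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g",
                     positions[, 1], positions[, 2], positions[, 3]), con)
  writeLines(paste("l", paste(seq_len(nrow(positions)), collapse = " ")),
             con)
  invisible(path)
}
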