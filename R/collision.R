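# Continuous collision detection: sphere-sphere time of impact (narrow
# phase), swept AABBs (middle phase), spatial hashing (wide phase). The
# thread is a chain of spheres of radius r spaced one diameter apart, so
# sphere-sphere TOI is a single quadratic; adjacent and next-adjacent
# spheres on the same rod permanently overlap by construction and are
# excluded.

#' Sphere-sphere time of impact
#'
#' Earliest `t` in `[0, 1]` at which the two moving spheres, each traveling
#' linearly from its current to its predicted position, first touch
#' (`|center_a(t) - center_b(t)| = r_a + r_b`). Returns 0 if they already
#' overlap at `t = 0`, and `NA` if they never touch within the step.
#'
#' @param x_a,x_a_pred current and predicted centers of sphere a.
#' @param x_b,x_b_pred current and predicted centers of sphere b.
#' @param r_a,r_b sphere radii (> 0).
#' @return scalar TOI in `[0, 1]`, or `NA` on miss.
#' @export
sphere_sphere_toi <- function(x_a, x_a_pred, x_b, x_b_pred, r_a, r_b) {
  stopifnot(r_a > 0, r_b > 0)
  t <- cpp_sphere_toi(as.numeric(x_a), as.numeric(x_a_pred),
                      as.numeric(x_b), as.numeric(x_b_pred), r_a, r_b)
  if (t < 0) NA_real_ else t
}

#' Swept axis-aligned bounding box
#'
#' The AABB of a sphere moving linearly from `x` to `x_pred`: min/max over
#' both endpoints, expanded by the radius in all axes. Contains the swept
#' sphere entirely.
#'
#' @param x,x_pred current and predicted sphere centers.
#' @param r sphere radius (> 0).
#' @return a `2 x 3` matrix; first row the box minimum, second the maximum.
#' @export
swept_aabb <- function(x, x_pred, r) {
  stopifnot(r > 0)
  rbind(pmin(x, x_pred) - r, pmax(x, x_pred) + r)
}

#' Broad-phase candidate pairs via spatial hashing
#'
#' Hashes every particle's swept AABB into grid cells and reports each pair
#' sharing a cell whose swept AABBs actually overlap: a superset of all
#' truly colliding pairs. Self-pairs and same-rod neighbors within two
#' chain positions are excluded; output is deduplicated and sorted.
#'
#' @param world a `thread_world`.
#' @param predicted optional `n x 3` matrix of predicted positions
#'   (defaults to one gravity-free Euler prediction from the current
#'   velocities).
#' @param cell_size spatial-hash cell edge; defaults to the world
#'   configuration (or twice the sphere diameter).
#' @return integer matrix with columns `i`, `j` (1-based particle indices,
#'   `i < j`).
#' @export
broad_phase <- function(world, predicted = NULL, cell_size = NULL) {
  tp <- particle_topology(world)
  pos <- world$particles$pos
  if (is.null(predicted))
    predicted <- pos + world$config$dt * world$particles$vel
  if (is.null(cell_size)) {
    cell_size <- world$config$cell_size
    if (is.null(cell_size)) cell_size <- 4 * world$rods$radius[1]
  }
  radius <- world$rods$radius[tp$rod_id]
  cpp_broad_phase(pos, predicted, radius, cell_size,
                  as.integer(tp$rod_id - 1L), as.integer(tp$chain_pos - 1L))
}
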