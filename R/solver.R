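# The pieces of one PBD step, exposed individually. sim_step() runs the
# same sequence fused in compiled code; these functions define the contract
# (and are cross-checked against the fused path in the tests).

#' Predict positions and orientations
#'
#' Symplectic explicit Euler: velocities absorb external forces first, then
#' positions advance with the new velocity (`v <- v + dt W F_ext`,
#' `x <- x + dt v`). Quaternions advance by the first-order rule
#' `q <- normalize(q + dt/2 (0, omega) q)`. Fixed variables (zero inverse
#' mass / inertia) are left unchanged. External torque is zero for thread.
#'
#' @param particles list with `pos`, `vel`, `inv_mass`.
#' @param orientations list with `quat`, `ang_vel`, `inv_inertia`.
#' @param config a [sim_config()] (supplies `dt` and `gravity`).
#' @return list with predicted `pos`, `vel` (post-force), `quat`.
#' @export
predict_state <- function(particles, orientations, config) {
  dt <- config$dt
  free <- particles$inv_mass > 0
  vel <- particles$vel
  vel[free, ] <- vel[free, , drop = FALSE] +
    dt * matrix(config$gravity, sum(free), 3, byrow = TRUE)
  pos <- particles$pos
  pos[free, ] <- pos[free, , drop = FALSE] + dt * vel[free, , drop = FALSE]
  quat <- orientations$quat
  for (j in seq_len(nrow(quat))) {
    if (orientations$inv_inertia[j] <= 0) next
    om <- orientations$ang_vel[j, ]
    dq <- 0.5 * dt * quat_multiply(c(0, om), quat[j, ])
    quat[j, ] <- quat_normalize(quat[j, ] + dq)
  }
  list(pos = pos, vel = vel, quat = quat)
}

#' Velocities from corrected states
#'
#' `v = (x_new - x_old) / dt`; angular velocity from the relative
#' quaternion in the small-angle form
#' `omega = 2 Im(q_new conj(q_old)) / dt` (sign-consistent with
#' [predict_state()], so prediction followed by update is idempotent on
#' constraint-free motion).
#'
#' @param pos_old,pos_new `n x 3` positions before and after the step.
#' @param quat_old,quat_new `k x 4` quaternions before and after.
#' @param dt time step in seconds (> 0).
#' @return list with `vel` (`n x 3`) and `ang_vel` (`k x 3`).
#' @export
update_velocities <- function(pos_old, pos_new, quat_old, quat_new, dt) {
  stopifnot(dt > 0)
  vel <- (pos_new - pos_old) / dt
  k <- nrow(quat_old)
  ang_vel <- matrix(0, k, 3)
  for (j in seq_len(k)) {
    rel <- quat_multiply(quat_new[j, ], quat_conjugate(quat_old[j, ]))
    s <- if (rel[1] < 0) -1 else 1
    ang_vel[j, ] <- s * 2 * rel[2:4] / dt
  }
  list(vel = vel, ang_vel = ang_vel)
}

#' Time-step-independent velocity damping
#'
#' `v <- (1 - d_v)^dt v` and `omega <- (1 - d_a)^dt omega`: the damping
#' factors are the fraction of the corresponding velocity removed per
#' second, so behavior does not depend on the time step.
#'
#' @param vel `n x 3` linear velocities.
#' @param ang_vel `k x 3` angular velocities.
#' @param d_v,d_a damping factors in `[0, 1]`.
#' @param dt time step in seconds.
#' @return list with damped `vel` and `ang_vel`.
#' @export
apply_damping <- function(vel, ang_vel, d_v, d_a, dt) {
  stopifnot(d_v >= 0, d_v <= 1, d_a >= 0, d_a <= 1)
  list(vel = (1 - d_v)^dt * vel, ang_vel = (1 - d_a)^dt * ang_vel)
}
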