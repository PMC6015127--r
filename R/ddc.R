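# Direct distance constraint: all chained segment-length constraints of a
# rod solved simultaneously as one tridiagonal linear system per iteration.
# This is what makes the thread inextensible at any iteration count, where
# Gauss-Seidel distance projection alone leaves visible elongation.

#' Chained distance constraint values
#'
#' `C_i = |p_i - p_{i+1}| - d` for every consecutive particle pair.
#'
#' @param positions `n x 3` matrix of chain positions (n >= 2).
#' @param d rest segment length (> 0).
#' @return numeric vector of length `n - 1`.
#' @export
distance_constraint_values <- function(positions, d) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) >= 2, d > 0)
  seg <- positions[-1, , drop = FALSE] -
    positions[-nrow(positions), , drop = FALSE]
  if (any(rowSums(seg^2) < 1e-30))
    stop("degenerate geometry: coincident consecutive particles")
  cpp_distance_values(positions, d)
}

#' Assemble the tridiagonal distance-constraint system
#'
#' Bands of `grad(C) W grad(C)^T` for the chained distance constraints,
#' with right-hand side `-C`. With segment directions
#' `n_i = (p_i - p_{i+1}) / |p_i - p_{i+1}|`, row `i` couples only
#' `lambda_{i-1}, lambda_i, lambda_{i+1}`: the diagonal is
#' `w_i + w_{i+1}` and the off-diagonals are `-w (n_i . n_{i+1})` dot
#' products, so the system is exactly tridiagonal. A held particle
#' (`w = 0`) zeroes every coupling through it, which is how a thread
#' gripped by an instrument splits into independently solved sub-chains.
#'
#' @param positions `n x 3` chain positions.
#' @param inv_mass length-n nonnegative inverse masses.
#' @param d rest segment length.
#' @return list of class `tridiagonal_system` with `sub`, `diag`, `super`,
#'   `rhs`.
#' @export
assemble_tridiagonal <- function(positions, inv_mass, d) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) >= 2, length(inv_mass) == nrow(positions),
            all(inv_mass >= 0), d > 0)
  out <- cpp_assemble_tridiag(positions, as.numeric(inv_mass), d)
  class(out) <- "tridiagonal_system"
  out
}

#' Thomas algorithm for tridiagonal systems
#'
#' O(k) forward elimination and back substitution. Errors on a vanishing
#' pivot (magnitude below 1e-12 during the sweep).
#'
#' @param system a `tridiagonal_system` (see [assemble_tridiagonal()]), or
#'   any list with `sub`, `diag`, `super`, `rhs`.
#' @return the solution vector `lambda`.
#' @export
thomas_solve <- function(system) {
  k <- length(system$diag)
  stopifnot(k >= 1, length(system$rhs) == k,
            length(system$sub) == max(k - 1, 0),
            length(system$super) == max(k - 1, 0))
  cpp_thomas(as.numeric(system$sub), as.numeric(system$diag),
             as.numeric(system$super), as.numeric(system$rhs))
}

#' One direct inextensibility correction
#'
#' Performs a single linearized solve of the chained distance constraints
#' (assemble, Thomas solve, apply `dp_i = w_i (n_i lambda_i -
#' n_{i-1} lambda_{i-1})`) and returns the corrected positions. Held
#' particles (`w = 0`) never move, and corrections never cross a held
#' particle. One call per solver iteration is how the stepper uses it;
#' repeated calls converge to exact segment lengths.
#'
#' @param positions `n x 3` chain positions.
#' @param inv_mass length-n nonnegative inverse masses (0 marks held
#'   particles).
#' @param d rest segment length.
#' @return corrected `n x 3` position matrix.
#' @export
apply_ddc <- function(positions, inv_mass, d) {
  positions <- as.matrix(positions)
  stopifnot(length(inv_mass) == nrow(positions), d > 0)
  if (all(inv_mass == 0)) return(positions)  # nothing can move: no-op
  cpp_apply_ddc(positions, as.numeric(inv_mass), d)
}
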