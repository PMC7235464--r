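#' Spiking nonlinearity
#'
#' The spike current is a hard threshold on the membrane potential:
#' `I_psi` amperes strictly above 0 V, zero at or below the threshold.
#' The threshold itself is non-spiking.
#'
#' @param v membrane potential(s), scalar or vector (V).
#' @param I_psi spike current amplitude (A).
#' @return spike current, same shape as `v` (A).
#' @examples
#' psi_current(c(-0.3, 0, 0.5), I_psi = 1)  # 0 0 1
#' @export
psi_current <- function(v, I_psi) {
  ifelse(v > 0, I_psi, 0)
}

#' Spiking barrier energy
#'
#' The penalty term of the network energy functional,
#' `sum_i integral_{-inf}^{v_i} Psi(v) dv = I_psi * sum_i max(v_i, 0)`:
#' zero below threshold, a linear ramp above it. Models power dissipated by
#' spiking activity; its gradient discontinuity at 0 V is what turns the
#' bound-constrained quadratic program into a spiking limit cycle.
#'
#' @param v membrane potential(s) (V); a vector is summed over the population.
#' @param I_psi spike current amplitude (A).
#' @return total barrier power (W).
#' @examples
#' barrier_energy(c(0.5, -0.1), I_psi = 2)  # 1
#' @export
barrier_energy <- function(v, I_psi) {
  I_psi * sum(pmax(v, 0))
}

#' Network energy functional
#'
#' `H(v) = 1/2 v' Q v - b' v + I_psi * sum_i max(v_i, 0)`, the extrinsic
#' power supplied to the network: coupling dissipation, stimulus power, and
#' spiking dissipation. Its constrained minimum over `|v_i| <= v_c` is the
#' steady-state attractor of the dynamics.
#'
#' @param v membrane potential vector (V).
#' @param config a [gt_network()].
#' @param b stimulus current vector (A); scalar is broadcast.
#' @return scalar energy (W).
#' @export
network_energy <- function(v, config, b = 0) {
  M <- config$M
  if (length(v) != M) stop("v must have length M")
  if (length(b) == 1L) b <- rep(b, M)
  if (length(b) != M) stop("b must have length M")
  qv <- drop(config$Q %*% v)
  0.5 * sum(v * qv) - sum(b * v) + barrier_energy(v, config$I_psi)
}

#' Gradient of the network energy
#'
#' `dH/dv_i = sum_j Q_ij v_j - b_i + Psi(v_i)`, a per-neuron current.
#'
#' @inheritParams network_energy
#' @return length-M gradient vector (A).
#' @export
energy_gradient <- function(v, config, b = 0) {
  M <- config$M
  if (length(v) != M) stop("v must have length M")
  if (length(b) == 1L) b <- rep(b, M)
  if (length(b) != M) stop("b must have length M")
  drop(config$Q %*% v) - b + psi_current(v, config$I_psi)
}

# Raw multiplicative map given a precomputed gradient; lambda-dominance must
# hold (checked by callers so the offending step can be reported).
.gt_map <- function(v, g, v_c, lam) {
  v_c * (-g * v_c + lam * v) / (-g * v + lam * v_c)
}

#' One Growth Transform update
#'
#' The multiplicative fixed-point map
#' `v <- v_c * (-g * v_c + lam * v) / (-g * v + lam * v_c)` with
#' `g = dH/dv`. Under the dominance condition `lam > |g_i|` the update keeps
#' every `|v_i| <= v_c` and decreases `H` wherever the gradient is
#' continuous. States with zero gradient, and the boundary states
#' `v = +/- v_c`, are algebraic fixed points.
#'
#' @param v membrane potential vector with `|v_i| <= v_c`.
#' @param config a [gt_network()].
#' @param b stimulus current vector (A).
#' @param lam optional override of the GT current parameter; defaults to the
#'   configured or automatic value.
#' @return updated potential vector.
#' @export
gt_update <- function(v, config, b = 0, lam = NULL) {
  if (is.null(lam)) lam <- .resolve_lambda(config, b)
  g <- energy_gradient(v, config, b)
  if (max(abs(g)) >= lam) {
    stop(sprintf(
      "lambda-dominance violated: lambda = %g but max|dH/dv| = %g",
      lam, max(abs(g))
    ))
  }
  .gt_map(v, g, config$v_c, lam)
}

#' Composite spike signal
#'
#' `s_i = v_i + C * Psi(v_i)`: the sub-threshold membrane trajectory with a
#' spike of height `C * I_psi` volts superimposed on every supra-threshold
#' step. For an uncoupled neuron with `C = 1/Q0` the long-run mean of `s`
#' encodes the stimulus as `C * b`.
#'
#' @param v membrane potential vector (V).
#' @param config a [gt_network()].
#' @return composite signal vector (V).
#' @export
composite_spike <- function(v, config) {
  v + config$C * psi_current(v, config$I_psi)
}

#' Remap synaptic weights to coupling space
#'
#' Converts a standard synaptic weight matrix `W` and external input `y`
#' into the coupling matrix and effective stimulus of the energy functional:
#' `Q = -(1 - gamma) * W^-1` and `b = -W^-1 y`, where `gamma` is the leak
#' factor. A Moore-Penrose pseudo-inverse (singular values below
#' `tol * sigma_max` dropped) is used when `W` is singular.
#'
#' @param W square synaptic weight matrix.
#' @param gamma leak factor in `[0, 1]`.
#' @param y external input vector (defaults to zeros).
#' @param tol relative pseudo-inverse tolerance.
#' @return list with elements `Q` (matrix) and `b` (vector).
#' @examples
#' remap_weights(-2 * diag(2), gamma = 0, y = c(1, 1))
#' @export
remap_weights <- function(W, gamma = 0, y = NULL, tol = 1e-10) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (is.null(y)) y <- rep(0, nrow(W))
  if (length(y) != nrow(W)) stop("y must have length nrow(W)")
  Winv <- .pinv(W, tol)
  list(Q = -(1 - gamma) * Winv, b = drop(-Winv %*% y))
}

# SVD pseudo-inverse; exact inverse falls out when W is well-conditioned.
.pinv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}
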