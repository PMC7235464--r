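#' Network configuration for a Growth Transform population
#'
#' Bundles the static parameters of a population of `M` Growth Transform (GT)
#' neurons: the trans-conductance coupling matrix `Q` (Ohm^-1), the membrane
#' potential bound `v_c` (V), the GT normalization current `lambda` (A), the
#' spike current amplitude `I_psi` (A) and the trans-impedance `C` (Ohm) that
#' converts the spike current into the spike height of the composite signal.
#'
#' All quantities follow the model's unit convention (V, A, Ohm, W) but are
#' stored as plain magnitudes. The membrane potentials are normalized so that
#' `v_c = 1` and the spiking threshold sits at 0.
#'
#' `lambda` must dominate the energy gradient, `lambda > |dH/dv_i|`, at every
#' visited state; this is what keeps the multiplicative update bounded and
#' monotone. When `lam = NULL` (the default) a safe static bound
#' `safety * (||Q||_inf * v_c + max|b| + I_psi)` is computed at run time from
#' the stimulus actually supplied to the run functions. A user-supplied
#' `lam` is still checked against the realized gradient at every step.
#'
#' @param Q square numeric coupling matrix (M x M), in Ohm^-1.
#' @param v_c positive membrane potential bound (V). Default 1.
#' @param lam GT current parameter (A), or `NULL` for automatic selection.
#' @param I_psi non-negative spike current amplitude (A). Default 1.
#' @param C positive trans-impedance (Ohm). Defaults to `1/Q[1,1]` for a
#'   diagonal (uncoupled) `Q` with a positive diagonal -- the choice under
#'   which the mean composite signal encodes `C * b` exactly -- and 1
#'   otherwise.
#' @param lam_safety multiplier used by the automatic `lambda` bound.
#' @return An object of class `gt_network`.
#' @examples
#' net <- gt_network(Q = diag(1), I_psi = 1)
#' net$C  # 1/Q0 for an uncoupled network
#' @export
gt_network <- function(Q, v_c = 1, lam = NULL, I_psi = 1, C = NULL,
                       lam_safety = 1.2) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) {
    stop("Q must be a square matrix")
  }
  if (!all(is.finite(Q))) stop("Q must have finite entries")
  if (!is.numeric(v_c) || length(v_c) != 1L || v_c <= 0) {
    stop("v_c must be a positive scalar")
  }
  if (!is.numeric(I_psi) || length(I_psi) != 1L || I_psi < 0) {
    stop("I_psi must be a non-negative scalar")
  }
  if (!is.null(lam) && (!is.numeric(lam) || length(lam) != 1L || lam <= 0)) {
    stop("lam must be a positive scalar or NULL")
  }
  M <- nrow(Q)
  if (is.null(C)) {
    uncoupled <- M == 1L ||
      (all(Q[row(Q) != col(Q)] == 0) && all(diag(Q) > 0))
    C <- if (uncoupled && all(diag(Q) > 0)) 1 / Q[1, 1] else 1
  }
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop("C must be a positive scalar")
  }
  structure(
    list(Q = Q, v_c = v_c, lam = lam, I_psi = I_psi, C = C, M = M,
         lam_safety = lam_safety),
    class = "gt_network"
  )
}

#' @export
print.gt_network <- function(x, ...) {
  cat("<gt_network>", x$M, "neurons\n")
  cat("  v_c =", x$v_c, " I_psi =", x$I_psi, " C =", x$C,
      " lambda =", if (is.null(x$lam)) "auto" else x$lam, "\n")
  od <- x$Q[row(x$Q) != col(x$Q)]
  cat("  Q: diag in [", min(diag(x$Q)), ",", max(diag(x$Q)), "],",
      if (length(od) && any(od != 0)) "coupled" else "uncoupled", "\n")
  invisible(x)
}

#' Automatic lambda bound
#'
#' Static upper bound on `|dH/dv_i| = |sum_j Q_ij v_j - b_i + Psi(v_i)|`
#' over the reachable set `|v| <= v_c`:
#' `||Q||_inf * v_c + max|b| + I_psi`, scaled by a safety factor.
#'
#' @param config a [gt_network()].
#' @param b stimulus vector, matrix, or maximum absolute stimulus value.
#' @return positive scalar usable as `lambda`.
#' @export
gt_lambda_auto <- function(config, b = 0) {
  bmax <- max(abs(b))
  config$lam_safety *
    (norm(config$Q, type = "I") * config$v_c + bmax + config$I_psi)
}

# Resolve the lambda actually used by a run: user value or automatic bound.
.resolve_lambda <- function(config, b) {
  if (is.null(config$lam)) gt_lambda_auto(config, b) else config$lam
}

#' Expand a stimulus to a dense M x T current matrix
#'
#' A stimulus course holds the external current `b_i` delivered to each
#' neuron at each time step. Accepted forms: a scalar (broadcast to all
#' neurons and steps), an M-vector (constant in time), or an M x T matrix.
#'
#' @param b scalar, length-M vector, or M x T matrix of currents (A).
#' @param M number of neurons.
#' @param n_steps number of time steps T.
#' @return M x T numeric matrix.
#' @export
as_stimulus <- function(b, M, n_steps) {
  if (is.matrix(b)) {
    if (nrow(b) != M) stop("stimulus matrix must have M rows")
    if (ncol(b) < n_steps) stop("stimulus matrix has fewer than n_steps columns")
    b <- b[, seq_len(n_steps), drop = FALSE]
  } else if (M == 1L && length(b) == n_steps) {
    b <- matrix(b, nrow = 1L)  # single-neuron time course
  } else {
    if (length(b) == 1L) b <- rep(b, M)
    if (length(b) != M) stop("stimulus vector must have length M")
    b <- matrix(b, nrow = M, ncol = n_steps)
  }
  if (!all(is.finite(b))) stop("stimulus must be finite")
  if (n_steps < 1L) stop("n_steps must be >= 1")
  b
}

#' Seeded initial membrane potentials
#'
#' Default initial condition is the origin; optionally a seeded uniform draw
#' strictly inside the bounds.
#'
#' @param config a [gt_network()].
#' @param random draw uniformly from `(-v_c, v_c)` instead of zeros.
#' @param seed integer seed used when `random = TRUE`.
#' @return length-M numeric vector.
#' @export
gt_init_state <- function(config, random = FALSE, seed = 1L) {
  if (!random) return(rep(0, config$M))
  set.seed(seed)
  stats::runif(config$M, -config$v_c, config$v_c) * 0.999
}
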