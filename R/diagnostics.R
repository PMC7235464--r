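#' Windowed first-order (KKT) residual
#'
#' The certificate sequence `z_i,n = (v_c^2 - v_i,n * v_i,n+1) * dH/dv_i,n`
#' has vanishing long-run mean along Growth Transform trajectories: at a
#' non-spiking fixed point the gradient itself is zero, and on a spiking
#' limit cycle the oscillation around the threshold averages the gradient
#' out. The windowed empirical mean over the final `window` steps is a
#' convergence diagnostic for both regimes.
#'
#' @param trace a `gt_trace` from [run_discrete()] or [run_continuous()].
#' @param window number of trailing steps to average over (`>= 1`). The
#'   final recorded state has no successor, so at least 2 recorded steps
#'   per window element are required.
#' @return length-M vector of windowed mean residuals.
#' @export
kkt_residual <- function(trace, window = 5000L) {
  config <- trace$config
  T_ <- ncol(trace$v)
  if (window < 1L || window > T_ - 1L) {
    stop("window must lie in [1, n_steps - 1]")
  }
  idx <- (T_ - window):(T_ - 1L)  # steps n with successor n + 1
  v_n <- trace$v[, idx, drop = FALSE]
  v_n1 <- trace$v[, idx + 1L, drop = FALSE]
  g <- config$Q %*% v_n - trace$b[, idx, drop = FALSE] +
    psi_current(v_n, config$I_psi)
  z <- (config$v_c^2 - v_n * v_n1) * g
  rowMeans(z)
}

#' Steady-state encoding residuals
#'
#' Checks the time-averaged first-order balance
#' `sum_j Q_ij mean(v_j) - mean(b_i) + mean(Psi_i) = 0` over a trailing
#' window of a (stationary-stimulus) trace, and the composite-signal
#' encoding identity `mean(s_i) = C * mean(b_i)` that holds exactly for an
#' uncoupled network with `C = 1/Q0`.
#'
#' @param trace a `gt_trace`.
#' @param window number of trailing steps to average over.
#' @return list with per-neuron vectors: `residual` (the absolute balance
#'   error, A), `s_mean`, `b_mean`, `encoding_error` (`|mean(s) - C*mean(b)|`,
#'   V), plus the window means `v_mean` and `psi_mean`.
#' @export
steady_state_encoding_check <- function(trace, window = 5000L) {
  config <- trace$config
  T_ <- ncol(trace$v)
  if (window < 1L || window > T_) stop("window must lie in [1, n_steps]")
  idx <- (T_ - window + 1L):T_
  v_bar <- rowMeans(trace$v[, idx, drop = FALSE])
  psi_bar <- rowMeans(trace$psi[, idx, drop = FALSE])
  b_bar <- rowMeans(trace$b[, idx, drop = FALSE])
  s_bar <- rowMeans(trace$s[, idx, drop = FALSE])
  res <- abs(drop(config$Q %*% v_bar) - b_bar + psi_bar)
  list(
    residual = res,
    s_mean = s_bar,
    b_mean = b_bar,
    encoding_error = abs(s_bar - config$C * b_bar),
    v_mean = v_bar,
    psi_mean = psi_bar
  )
}
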