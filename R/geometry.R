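#' Gaussian-kernel coupling matrix from a neuron embedding
#'
#' Places neurons at coordinates `x_i` in a metric space and couples them by
#' `Q_ij = exp(-gamma * ||x_i - x_j||^2)`: symmetric, unit diagonal,
#' positive semi-definite, entries in `(0, 1]`. Nearby neurons are strongly
#' coupled; `gamma -> Inf` recovers the identity.
#'
#' @param coords M x D matrix of neuron coordinates (rows are neurons).
#' @param gamma positive kernel scale.
#' @return M x M coupling matrix.
#' @export
gaussian_kernel_Q <- function(coords, gamma = 1) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (gamma <= 0) stop("gamma must be positive")
  d2 <- unname(as.matrix(stats::dist(coords)))^2
  Q <- exp(-gamma * d2)
  unname((Q + t(Q)) / 2)
}

#' Hyperplane weights and kernel-space distances
#'
#' In the geometric view the windowed mean spike current of neuron `i`
#' equals its signed distance from a stimulus-specific network hyperplane:
#' `mean(Psi_i) = w . x_i + mean(b_i)` with `w = -sum_j x_j mean(v_j)`.
#' The explicit `w` is exact for a linear kernel (`Q = X X'`); for kernel
#' couplings such as [gaussian_kernel_Q()] the distance is evaluated in the
#' implicit feature space as `-(Q mean(v))_i + mean(b_i)`, which is what
#' this function returns and checks against the realized `mean(Psi_i)`.
#'
#' @param trace a `gt_trace` recorded under a stationary stimulus.
#' @param coords M x D embedding used to build `Q` (for the explicit `w`).
#' @param window trailing window (steps) for the time averages.
#' @return list with `w_vec` (length-D explicit weight vector),
#'   `distance` (per-neuron kernel-space hyperplane distance),
#'   `psi_mean` (realized windowed mean spike current) and
#'   `check_error` (`|distance - psi_mean|`, A).
#' @export
hyperplane_weights <- function(trace, coords, window = 5000L) {
  coords <- as.matrix(coords)
  config <- trace$config
  if (nrow(coords) != config$M) stop("coords must have one row per neuron")
  T_ <- ncol(trace$v)
  if (window < 1L || window > T_) stop("window must lie in [1, n_steps]")
  idx <- (T_ - window + 1L):T_
  v_bar <- rowMeans(trace$v[, idx, drop = FALSE])
  b_bar <- rowMeans(trace$b[, idx, drop = FALSE])
  psi_bar <- rowMeans(trace$psi[, idx, drop = FALSE])
  w <- -drop(crossprod(coords, v_bar))
  dist_i <- -drop(config$Q %*% v_bar) + b_bar
  list(
    w_vec = w,
    distance = dist_i,
    psi_mean = psi_bar,
    check_error = abs(dist_i - psi_bar)
  )
}

#' Mean firing rate and time-to-first-spike
#'
#' Rate coding and latency coding metrics over a stimulus window: per
#' neuron, the fraction of steps with a spike event from `onset` to the end
#' of the trace (or `onset + window - 1`), and the latency (in steps,
#' relative to onset) of the first spike at or after the onset. Neurons
#' that never spike in the window get rate 0 and an infinite
#' time-to-first-spike.
#'
#' @param trace a `gt_trace`.
#' @param onset first step of the stimulus window (1-based).
#' @param window optional window length in steps.
#' @return data.frame with columns `neuron`, `rate` (spikes/step in
#'   `[0, 1]`) and `ttfs` (steps; `Inf` if no spike).
#' @export
rate_and_ttfs <- function(trace, onset = 1L, window = NULL) {
  T_ <- ncol(trace$v)
  if (onset < 1L || onset > T_) stop("onset must lie within the trace")
  end <- if (is.null(window)) T_ else min(T_, onset + window - 1L)
  M <- nrow(trace$v)
  rate <- numeric(M)
  ttfs <- rep(Inf, M)
  for (i in seq_len(M)) {
    sp <- trace$spikes[[i]]
    sp <- sp[sp >= onset & sp <= end]
    rate[i] <- length(sp) / (end - onset + 1L)
    if (length(sp)) ttfs[i] <- sp[1] - onset
  }
  data.frame(neuron = seq_len(M), rate = rate, ttfs = ttfs)
}

#' Time-binned population trajectory
#'
#' Collapses the spike raster into a (bins x M) matrix of per-bin firing
#' rates (spike count / bin length), the representation in which population
#' responses to different stimuli trace separable trajectories.
#'
#' @param trace a `gt_trace`.
#' @param bin_len bin length in steps (`>= 1`); trailing steps that do not
#'   fill a bin are dropped.
#' @return numeric matrix with `floor(T / bin_len)` rows and M columns.
#' @export
binned_trajectory <- function(trace, bin_len = 50L) {
  if (bin_len < 1L) stop("bin_len must be >= 1")
  T_ <- ncol(trace$psi)
  n_bins <- T_ %/% bin_len
  if (n_bins < 1L) stop("trace shorter than one bin")
  events <- trace$psi[, seq_len(n_bins * bin_len), drop = FALSE] > 0
  M <- nrow(events)
  out <- matrix(0, n_bins, M)
  grp <- rep(seq_len(n_bins), each = bin_len)
  for (i in seq_len(M)) {
    out[, i] <- tapply(events[i, ], grp, sum) / bin_len
  }
  out
}
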