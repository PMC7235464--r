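#' Seeded random binary memory patterns
#'
#' Generates `S` binary patterns over `M` neurons, each with exactly `m`
#' active units at uniformly random positions. Reproducible for a given
#' seed.
#'
#' @param M number of neurons.
#' @param m active units per pattern (`0 < m <= M`).
#' @param S number of patterns.
#' @param seed integer seed.
#' @return object of class `gt_patterns`: list with the `S x M` 0/1 matrix
#'   `patterns`, and the storage metadata `m` and Hebbian scale `k`
#'   (defaulting to `m`).
#' @export
gen_patterns <- function(M, m, S, seed = 1L) {
  if (m <= 0 || m > M) stop("m must satisfy 0 < m <= M")
  set.seed(seed)
  P <- matrix(0L, S, M)
  for (s in seq_len(S)) {
    P[s, sample.int(M, m)] <- 1L
  }
  structure(list(patterns = P, M = M, m = m, S = S, k = m),
            class = "gt_patterns")
}

#' @export
print.gt_patterns <- function(x, ...) {
  cat("<gt_patterns>", x$S, "patterns x", x$M, "neurons,",
      x$m, "active each, k =", x$k, "\n")
  invisible(x)
}

#' Synthetic stimulus courses
#'
#' Piecewise current time-courses for single-neuron and protocol
#' experiments. Kinds:
#' * `step`: zero until `onset`, then constant `amplitude`.
#' * `ramp`: linear rise from 0 at step 1 to `amplitude` at the last step.
#' * `pulses`: `n_pulses` rectangular pulses of `amplitude` and
#'   `width` steps separated by `gap` steps, on a constant `baseline`
#'   (slightly negative for the leaky-integrator experiment).
#' * `two_phase_history`: `stim1` (an M-vector) for `len1` steps, a zero
#'   gap of `gap` steps, then `stim2` for `len2` steps -- the
#'   stimulus-history protocol.
#'
#' @param kind one of `"step"`, `"ramp"`, `"pulses"`, `"two_phase_history"`.
#' @param n_steps total length (ignored for `two_phase_history`, whose
#'   length is `len1 + gap + len2`).
#' @param amplitude,onset,baseline,width,gap,n_pulses scalar parameters as
#'   described above.
#' @param stim1,stim2,len1,len2 parameters of the history course.
#' @return for the scalar kinds a length `n_steps` vector (broadcastable to
#'   any M by the run functions); for `two_phase_history` an M x T matrix.
#' @export
gen_stimulus <- function(kind = c("step", "ramp", "pulses",
                                  "two_phase_history"),
                         n_steps = 1000L, amplitude = 0.5, onset = 1L,
                         baseline = 0, width = 5L, gap = 20L, n_pulses = 5L,
                         stim1 = NULL, stim2 = NULL,
                         len1 = 500L, len2 = 500L) {
  kind <- match.arg(kind)
  switch(kind,
    step = {
      b <- rep(0, n_steps)
      if (onset <= n_steps) b[onset:n_steps] <- amplitude
      b
    },
    ramp = {
      if (n_steps == 1L) return(amplitude)
      seq(0, amplitude, length.out = n_steps)
    },
    pulses = {
      b <- rep(baseline, n_steps)
      t0 <- onset
      for (p in seq_len(n_pulses)) {
        if (t0 > n_steps) break
        t1 <- min(t0 + width - 1L, n_steps)
        b[t0:t1] <- amplitude
        t0 <- t1 + gap + 1L
      }
      b
    },
    two_phase_history = {
      if (is.null(stim1) || is.null(stim2)) {
        stop("two_phase_history needs stim1 and stim2 vectors")
      }
      if (length(stim1) != length(stim2)) {
        stop("stim1 and stim2 must have equal length")
      }
      M <- length(stim1)
      cbind(
        matrix(stim1, M, len1),
        matrix(0, M, gap),
        matrix(stim2, M, len2)
      )
    }
  )
}

#' Corrupt a binary pattern with additive white Gaussian noise
#'
#' Adds zero-mean Gaussian noise whose variance is set by the pattern's
#' signal power and the requested SNR, `var = mean(x^2) / 10^(snr_db/10)`,
#' then re-thresholds at 0.5 to return a binary vector. `snr_db = Inf`
#' returns the pattern unchanged.
#'
#' @param pattern binary (0/1) vector.
#' @param snr_db signal-to-noise ratio in dB.
#' @param seed integer seed.
#' @return binary vector of the same length.
#' @export
gen_noisy_binary <- function(pattern, snr_db, seed = 1L) {
  if (!all(pattern %in% c(0, 1))) stop("pattern must be binary")
  if (is.infinite(snr_db) && snr_db > 0) return(as.integer(pattern))
  sig_pow <- mean(pattern^2)
  noise_sd <- sqrt(sig_pow / 10^(snr_db / 10))
  set.seed(seed)
  noisy <- pattern + stats::rnorm(length(pattern), sd = noise_sd)
  as.integer(noisy > 0.5)
}
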