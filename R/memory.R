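#' Hebbian coupling matrix from binary patterns
#'
#' Outer-product storage rule `Q_ij = (1/k) * sum_s t_i^s t_j^s`: symmetric
#' and non-negative, with `Q_ii` equal to the number of patterns containing
#' neuron `i`, scaled by `1/k`. The default scale `k = m` (active units per
#' pattern) keeps coupling entries at most `S/m`-ish and of order one for
#' typical loads.
#'
#' @param pattern_set a [gen_patterns()] object, or a plain `S x M` 0/1
#'   matrix.
#' @param k positive Hebbian scale; defaults to the pattern set's `k`
#'   (itself defaulting to `m`).
#' @return M x M coupling matrix.
#' @export
hebbian_couplings <- function(pattern_set, k = NULL) {
  P <- if (inherits(pattern_set, "gt_patterns")) {
    pattern_set$patterns
  } else {
    as.matrix(pattern_set)
  }
  if (!all(P %in% c(0, 1))) stop("patterns must be binary")
  if (is.null(k)) {
    k <- if (inherits(pattern_set, "gt_patterns")) pattern_set$k else
      max(rowSums(P))
  }
  if (k <= 0) stop("k must be positive")
  crossprod(P) / k
}

# Shared runner for storage/recall/classification simulations: constant
# depolarizing drive on `active` neurons; discrete dynamics by default or
# modulated continuous dynamics when a spec is given.
.memory_run <- function(Q, active, drive, n_steps, modulation = NULL,
                        I_psi = 1, v_c = 1) {
  M <- nrow(Q)
  config <- gt_network(Q, v_c = v_c, I_psi = I_psi, C = 1)
  b <- numeric(M)
  b[active] <- drive
  if (is.null(modulation)) {
    run_discrete(config, b = b, v0 = 0, n_steps = n_steps)
  } else {
    run_continuous(config, b = b, v0 = 0, n_steps = n_steps,
                   modulation = modulation, dt = 1)
  }
}

#' Storage (reference) run for one pattern
#'
#' Simulates the network with a steady depolarizing input on *all* active
#' neurons of a stored pattern; the resulting spiking trajectory is the
#' reference against which recalls are scored.
#'
#' @param Q coupling matrix (typically from [hebbian_couplings()]).
#' @param pattern binary vector of length M.
#' @param drive steady depolarizing current (A).
#' @param n_steps simulation length.
#' @param modulation optional modulation spec (e.g. [mod_global()]);
#'   `NULL` runs the discrete-time network.
#' @return a `gt_trace`.
#' @export
storage_run <- function(Q, pattern, drive = 0.2, n_steps = 1000L,
                        modulation = NULL) {
  active <- which(pattern > 0)
  if (!length(active)) stop("pattern has no active neurons")
  .memory_run(Q, active, drive, n_steps, modulation)
}

#' Partial-cue recall run
#'
#' Stimulates a seeded random fraction of a pattern's active neurons with a
#' steady depolarizing input and records the network response. Hebbian
#' reinforcement drives the un-cued members of the pattern above the rest
#' of the population even though they receive no direct input.
#'
#' @inheritParams storage_run
#' @param cue_fraction fraction of active neurons to stimulate, in `(0, 1]`.
#' @param seed integer seed for the cue subset draw.
#' @return a `gt_trace`; the cued indices are attached as attribute `"cue"`.
#' @export
recall_run <- function(Q, pattern, cue_fraction = 0.5, drive = 0.2,
                       n_steps = 1000L, modulation = NULL, seed = 1L) {
  if (cue_fraction <= 0 || cue_fraction > 1) {
    stop("cue_fraction must lie in (0, 1]")
  }
  active <- which(pattern > 0)
  n_cue <- max(1L, round(cue_fraction * length(active)))
  if (!length(active)) stop("pattern has no active neurons: empty cue set")
  set.seed(seed)
  cue <- sort(sample(active, n_cue))
  tr <- .memory_run(Q, cue, drive, n_steps, modulation)
  attr(tr, "cue") <- cue
  tr
}

#' Decode a spike trace into per-bin feature vectors
#'
#' Splits the raster into bins of `bin_len` steps and computes, per bin and
#' neuron: the mean firing rate `r` (spikes/step), the mean inter-spike
#' interval (mean gap between consecutive events inside the bin, set to the
#' bin length when the bin holds a single spike and to twice the bin length
#' when it holds none), and the rate change `dr` relative to the previous
#' bin (the first bin is differenced against zero). The full decode vector
#' per bin is the concatenation `[r, isi, dr]` across the population;
#' `rate_only = TRUE` truncates it to `[r]`, the weaker purely rate-based
#' code.
#'
#' @param trace a `gt_trace`.
#' @param bin_len bin length in steps (`>= 2`).
#' @param rate_only drop the inter-spike-interval and rate-change blocks.
#' @return matrix with `floor(T / bin_len)` rows and `3M` (or `M`) columns,
#'   of class `gt_decode`.
#' @export
decode_trace <- function(trace, bin_len = 50L, rate_only = FALSE) {
  if (bin_len < 2L) stop("bin_len must be >= 2")
  T_ <- ncol(trace$psi)
  n_bins <- T_ %/% bin_len
  if (n_bins < 1L) stop("trace shorter than one bin")
  M <- nrow(trace$psi)
  r <- matrix(0, n_bins, M)
  isi <- matrix(2 * bin_len, n_bins, M)
  for (i in seq_len(M)) {
    sp <- trace$spikes[[i]]
    sp <- sp[sp <= n_bins * bin_len]
    if (!length(sp)) next
    bin_of <- (sp - 1L) %/% bin_len + 1L
    cnt <- tabulate(bin_of, nbins = n_bins)
    r[, i] <- cnt / bin_len
    for (bn in unique(bin_of)) {
      s_in <- sp[bin_of == bn]
      isi[bn, i] <- if (length(s_in) >= 2L) mean(diff(s_in)) else bin_len
    }
  }
  dr <- rbind(r[1, , drop = FALSE],
              if (n_bins > 1L) diff(r) else NULL)
  out <- if (rate_only) r else cbind(r, isi, dr)
  structure(out, class = c("gt_decode", "matrix"),
            bin_len = bin_len, rate_only = rate_only)
}

#' Mean per-bin distance between two decode matrices
#'
#' The (un-normalized) dissimilarity of two spiking trajectories: the
#' Euclidean distance between their decode vectors, bin by bin, averaged
#' over bins.
#'
#' @param d1,d2 decode matrices from [decode_trace()] with equal shapes.
#' @return non-negative scalar.
#' @export
decode_distance <- function(d1, d2) {
  if (!all(dim(d1) == dim(d2))) stop("decode matrices must have equal shape")
  mean(sqrt(rowSums((d1 - d2)^2)))
}

#' Similarity matrix between stored and recalled trajectories
#'
#' Computes all pairwise mean per-bin distances between stored and recalled
#' decode matrices, min-max normalizes the distances to `[0, 1]` over the
#' whole comparison set (so 0 and 1 are attained by the closest and the
#' most dissimilar pair), and returns `s = 1 - dist_norm`. If all pairs are
#' equidistant the normalized distance is defined as 0 (all pairs maximally
#' similar).
#'
#' @param stored list of decode matrices for the stored patterns.
#' @param recalled list of decode matrices for the recall runs.
#' @return `length(stored) x length(recalled)` matrix with entries in
#'   `[0, 1]`; rows index stored patterns, columns recalls.
#' @export
similarity_matrix <- function(stored, recalled) {
  S_u <- length(stored)
  S_v <- length(recalled)
  D <- matrix(0, S_u, S_v)
  for (u in seq_len(S_u)) {
    for (v in seq_len(S_v)) {
      D[u, v] <- decode_distance(stored[[u]], recalled[[v]])
    }
  }
  rng <- max(D) - min(D)
  Dn <- if (rng > 0) (D - min(D)) / rng else D * 0
  1 - Dn
}

#' Recall accuracy from a similarity matrix
#'
#' Fraction of recalls whose best-matching stored pattern (row-wise argmax
#' of similarity down each column) is the correct one; ties break toward
#' the lowest pattern index.
#'
#' @param sim similarity matrix (stored x recalled, square).
#' @return scalar accuracy in `[0, 1]`.
#' @export
recall_accuracy <- function(sim) {
  hits <- vapply(seq_len(ncol(sim)), function(v) {
    which.max(sim[, v]) == v
  }, logical(1))
  mean(hits)
}

# Decode all storage + recall runs for one pattern set / condition.
.memory_decodes <- function(Q, P, drive, n_steps, bin_len, modulation,
                            cue_fraction, rate_only, seed) {
  S <- nrow(P)
  stored <- vector("list", S)
  recalled <- vector("list", S)
  spikes <- numeric(S)
  for (s in seq_len(S)) {
    tr_s <- storage_run(Q, P[s, ], drive, n_steps, modulation)
    stored[[s]] <- decode_trace(tr_s, bin_len, rate_only)
    tr_r <- recall_run(Q, P[s, ], cue_fraction, drive, n_steps, modulation,
                       seed = seed + s)
    recalled[[s]] <- decode_trace(tr_r, bin_len, rate_only)
    spikes[s] <- spike_count(tr_r)
  }
  list(stored = stored, recalled = recalled, spikes = spikes)
}

#' Associative-memory capacity experiment
#'
#' For each memory load `S` in `S_list` and each trial: draw `S` random
#' binary patterns (`M` neurons, `m` active), store them with the Hebbian
#' rule, simulate a reference run per pattern and a partial-cue recall per
#' pattern, decode both trajectories, score the similarity matrix and
#' record the recall accuracy and the spikes emitted per recall. Run with
#' and without global adaptation to compare spike budgets.
#'
#' @param M,m network size and active units per pattern.
#' @param S_list ascending vector of memory loads.
#' @param trials number of independent trials per load.
#' @param drive steady depolarizing cue current.
#' @param cue_fraction fraction of a pattern's active neurons cued.
#' @param n_steps simulation length per run.
#' @param bin_len decoding bin length.
#' @param global_adapt logical vector of conditions to run (`FALSE` = the
#'   baseline network with pre-synaptic adaptation only, `TRUE` = the same
#'   network under [mod_global()]).
#' @param modulation modulation spec used for the adaptive condition.
#' @param baseline_modulation modulation spec of the non-adaptive baseline;
#'   `NULL` runs the raw discrete-time network instead.
#' @param rate_only use the rate-only decoder.
#' @param seed master seed; trial `t` uses `seed + 1000 * t`.
#' @return tidy data.frame with columns `S`, `trial`, `condition`
#'   (`"none"`/`"global"`), `accuracy` and `mean_spikes` (per recall run).
#' @export
capacity_experiment <- function(M = 100L, m = 10L, S_list = 10L,
                                trials = 10L, drive = 0.2,
                                cue_fraction = 0.5, n_steps = 1000L,
                                bin_len = 50L,
                                global_adapt = FALSE,
                                modulation = mod_global(),
                                baseline_modulation = mod_presynaptic(),
                                rate_only = FALSE, seed = 1L) {
  stopifnot(trials >= 1, all(diff(S_list) >= 0))
  rows <- list()
  for (S in S_list) {
    for (t in seq_len(trials)) {
      trial_seed <- seed + 1000L * t + S
      P <- gen_patterns(M, m, S, seed = trial_seed)$patterns
      Q <- hebbian_couplings(P, k = m)
      for (ga in global_adapt) {
        mod <- if (ga) modulation else baseline_modulation
        dec <- .memory_decodes(Q, P, drive, n_steps, bin_len, mod,
                               cue_fraction, rate_only, seed = trial_seed)
        sim <- similarity_matrix(dec$stored, dec$recalled)
        rows[[length(rows) + 1L]] <- data.frame(
          S = S, trial = t,
          condition = if (ga) "global" else "none",
          accuracy = recall_accuracy(sim),
          mean_spikes = mean(dec$spikes)
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Classify noisy binary patterns with the associative memory
#'
#' Builds the Hebbian memory from clean class prototypes, then presents
#' noisy test items: each prototype is corrupted with additive white
#' Gaussian noise at the requested SNR, re-thresholded to binary, its
#' non-zero units driven with the steady depolarizing input, and the
#' response assigned the class of the most similar stored trajectory.
#'
#' @param pattern_set a [gen_patterns()] object; each pattern is one class
#'   prototype.
#' @param snr_db_list SNR levels (dB) to test.
#' @param n_test number of noisy test items per class and SNR.
#' @param drive,n_steps,bin_len,modulation as in [capacity_experiment()].
#' @param seed master seed for the noise draws.
#' @return tidy data.frame with columns `snr_db`, `accuracy` and
#'   `mean_spikes` (per test item).
#' @export
noisy_pattern_classify <- function(pattern_set, snr_db_list = c(20, 10, 0),
                                   n_test = 2L, drive = 0.2,
                                   n_steps = 1000L, bin_len = 50L,
                                   modulation = mod_presynaptic(),
                                   seed = 1L) {
  P <- pattern_set$patterns
  S <- nrow(P)
  Q <- hebbian_couplings(pattern_set)
  stored <- lapply(seq_len(S), function(s) {
    decode_trace(storage_run(Q, P[s, ], drive, n_steps, modulation), bin_len)
  })
  rows <- list()
  for (snr in snr_db_list) {
    hits <- 0L
    total <- 0L
    spikes <- numeric(0)
    for (s in seq_len(S)) {
      for (r in seq_len(n_test)) {
        noise_seed <- seed + 7919L * s + 104729L * r + round(100 * snr)
        test <- gen_noisy_binary(P[s, ], snr, seed = noise_seed)
        active <- which(test > 0)
        if (!length(active)) {
          total <- total + 1L  # fully erased item counts as a miss
          next
        }
        tr <- .memory_run(Q, active, drive, n_steps, modulation)
        d <- decode_trace(tr, bin_len)
        dists <- vapply(stored, decode_distance, numeric(1), d2 = d)
        pred <- which.min(dists)
        hits <- hits + as.integer(pred == s)
        total <- total + 1L
        spikes <- c(spikes, spike_count(tr))
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      snr_db = snr,
      accuracy = hits / total,
      mean_spikes = if (length(spikes)) mean(spikes) else NA_real_
    )
  }
  do.call(rbind, rows)
}
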