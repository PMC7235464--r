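#' Canned experiment protocols
#'
#' A protocol bundles a network builder, a stimulus schedule, a run spec
#' and the analysis that the simulator's demonstration experiments use.
#' Available protocols:
#' * `"tonic"`: uncoupled neuron, constant drive, constant modulation;
#'   near-constant inter-spike intervals after the transient.
#' * `"bursting"`: counter-based modulation; spike groups of length `B`
#'   separated by long quiescent gaps.
#' * `"adaptation"`: spike-frequency adaptation; firing rate decays from a
#'   fast initial value to a lower steady state under constant drive.
#' * `"integrator"`: slightly negative baseline plus input pulses; spikes
#'   for closely spaced pulses only.
#' * `"history"`: 4-neuron stimulus-history experiment run under three
#'   couplings (uncoupled, positive definite, non-positive definite) and
#'   two histories each; an uncoupled network responds to the second
#'   stimulus identically for both histories, a non-positive-definite
#'   coupling admits several attractors and may not.
#' * `"population"`: 20 kernel-coupled neurons on a seeded planar layout;
#'   rate / time-to-first-spike metrics against hyperplane distance.
#'
#' @param name protocol name (see above).
#' @param seed integer seed controlling every stochastic element.
#' @param params named list of overrides for the protocol's documented
#'   defaults.
#' @return object of class `gt_protocol`.
#' @export
gt_protocol <- function(name = c("tonic", "bursting", "adaptation",
                                 "integrator", "history", "population"),
                        seed = 1L, params = list()) {
  name <- match.arg(name)
  structure(list(name = name, seed = seed, params = params),
            class = "gt_protocol")
}

#' @export
print.gt_protocol <- function(x, ...) {
  cat("<gt_protocol>", x$name, "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

# Default parameter sets, exposed so tests and docs can see them.
.protocol_defaults <- function(name) {
  switch(name,
    tonic = list(Q0 = 1, b = 0.5, I_psi = 1, n_steps = 2000L, tau = 1),
    bursting = list(Q0 = 1, b = 0.5, I_psi = 1, n_steps = 3000L,
                    tau1 = 20, tau2 = 1, B = 5L),
    adaptation = list(Q0 = 1, b = 0.4, I_psi = 1, n_steps = 2000L,
                      tau = 10, alpha = 0.001),
    integrator = list(Q0 = 1, I_psi = 1, baseline = -0.05, amplitude = 0.2,
                      width = 6L, gap_narrow = 2L, gap_wide = 150L,
                      n_pulses = 6L, n_steps = 1200L, tau = 20),
    history = list(drive = 0.5, I_psi = 1, len1 = 400L, gap = 300L,
                   len2 = 600L, window = 200L, shift = 1.5),
    population = list(M = 20L, gamma = 2, I_psi = 1, n_steps = 6000L,
                      b_scale = 1, tau = 50)
  )
}

.protocol_params <- function(protocol) {
  p <- .protocol_defaults(protocol$name)
  p[names(protocol$params)] <- protocol$params
  p
}

#' Run a canned experiment protocol
#'
#' Executes the protocol deterministically under its seed and optionally
#' writes the artifact bundle (trace CSVs, spike CSVs, metrics CSV, flat
#' config file, and a manifest with md5 content hashes) to a directory.
#'
#' @param protocol a [gt_protocol()].
#' @param out_dir optional output directory (created if missing).
#' @return list with protocol-specific `traces` and `metrics`, the resolved
#'   `params`, and `files` (paths written; empty when `out_dir` is NULL).
#' @export
run_protocol <- function(protocol, out_dir = NULL) {
  stopifnot(inherits(protocol, "gt_protocol"))
  p <- .protocol_params(protocol)
  res <- switch(protocol$name,
    tonic = .proto_tonic(p),
    bursting = .proto_bursting(p),
    adaptation = .proto_adaptation(p),
    integrator = .proto_integrator(p),
    history = .proto_history(p),
    population = .proto_population(p, protocol$seed)
  )
  res$params <- p
  res$files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (nm in names(res$traces)) {
      f1 <- file.path(out_dir, paste0(nm, "_trace.csv"))
      f2 <- file.path(out_dir, paste0(nm, "_spikes.csv"))
      write_trace_csv(res$traces[[nm]], f1, f2)
      files <- c(files, f1, f2)
    }
    fm <- file.path(out_dir, "metrics.csv")
    utils::write.csv(res$metrics, fm, row.names = FALSE, quote = FALSE)
    fc <- file.path(out_dir, "config.txt")
    cfg <- c(list(protocol = protocol$name, seed = protocol$seed),
             p[vapply(p, is.numeric, logical(1))])
    write_gt_config(cfg, fc)
    files <- c(files, fm, fc)
    fman <- file.path(out_dir, "manifest.csv")
    write_manifest(files, fman)
    res$files <- c(files, fman)
  }
  res
}

.uncoupled_net <- function(Q0, I_psi) {
  gt_network(matrix(Q0), I_psi = I_psi, C = if (Q0 > 0) 1 / Q0 else 1)
}

# Inter-spike intervals of one neuron, after dropping a transient.
.isis <- function(trace, neuron = 1L, discard = 0L) {
  sp <- trace$spikes[[neuron]]
  sp <- sp[sp > discard]
  if (length(sp) < 2L) return(numeric(0))
  diff(sp)
}

.proto_tonic <- function(p) {
  net <- .uncoupled_net(p$Q0, p$I_psi)
  tr <- run_continuous(net, b = p$b, n_steps = p$n_steps,
                       modulation = mod_constant(p$tau))
  isi <- .isis(tr, discard = p$n_steps %/% 4L)
  cv <- if (length(isi) > 1L && mean(isi) > 0) {
    stats::sd(isi) / mean(isi)
  } else {
    0
  }
  list(traces = list(tonic = tr),
       metrics = data.frame(n_spikes = length(tr$spikes[[1]]),
                            isi_mean = mean(isi), isi_cv = cv))
}

# Segment a spike train into bursts: gaps > threshold split groups.
.burst_segments <- function(sp, gap_thresh) {
  if (!length(sp)) return(list())
  split(sp, cumsum(c(1, diff(sp) > gap_thresh)))
}

.proto_bursting <- function(p) {
  net <- .uncoupled_net(p$Q0, p$I_psi)
  tr <- run_continuous(net, b = p$b, n_steps = p$n_steps,
                       modulation = mod_bursting(p$tau1, p$tau2, p$B))
  discard <- p$n_steps %/% 4L
  sp <- tr$spikes[[1]]
  sp <- sp[sp > discard]
  isi <- if (length(sp) > 1L) diff(sp) else numeric(0)
  intra <- isi[isi <= 3]
  segs <- .burst_segments(sp, gap_thresh = 3)
  gaps <- isi[isi > 3]
  list(traces = list(bursting = tr),
       metrics = data.frame(
         n_bursts = length(segs),
         burst_len_mode = if (length(segs)) {
           as.numeric(names(which.max(table(lengths(segs)))))
         } else 0,
         intra_isi = if (length(intra)) mean(intra) else NA_real_,
         gap_mean = if (length(gaps)) mean(gaps) else NA_real_
       ))
}

.proto_adaptation <- function(p) {
  net <- .uncoupled_net(p$Q0, p$I_psi)
  tr <- run_continuous(net, b = p$b, n_steps = p$n_steps,
                       modulation = mod_sfa(p$tau, p$alpha))
  q <- p$n_steps %/% 4L
  rate_q <- vapply(0:3, function(k) {
    sum(tr$psi[1, (k * q + 1L):((k + 1L) * q)] > 0) / q
  }, numeric(1))
  list(traces = list(adaptation = tr),
       metrics = data.frame(rate_q1 = rate_q[1], rate_q2 = rate_q[2],
                            rate_q3 = rate_q[3], rate_q4 = rate_q[4]))
}

.proto_integrator <- function(p) {
  net <- .uncoupled_net(p$Q0, p$I_psi)
  run_one <- function(gap) {
    b <- gen_stimulus("pulses", n_steps = p$n_steps,
                      amplitude = p$amplitude, baseline = p$baseline,
                      width = p$width, gap = gap, n_pulses = p$n_pulses,
                      onset = 50L)
    run_continuous(net, b = b, n_steps = p$n_steps,
                   modulation = mod_constant(p$tau))
  }
  tr_narrow <- run_one(p$gap_narrow)
  tr_wide <- run_one(p$gap_wide)
  list(traces = list(narrow = tr_narrow, wide = tr_wide),
       metrics = data.frame(
         spikes_narrow = length(tr_narrow$spikes[[1]]),
         spikes_wide = length(tr_wide$spikes[[1]])
       ))
}

# Stimulus-history experiment: two histories x three couplings.
.proto_history <- function(p) {
  drive <- p$drive
  # asymmetric within-block drive: excites the unstable (memory) mode of the
  # non-positive-definite coupling, parking the block in a lasting attractor
  stim1a <- c(drive, 0.5 * drive, 0, 0)
  stim1b <- c(0, 0, drive, 0.5 * drive)
  stim2 <- c(0, drive, 0.5 * drive, 0)
  mk_course <- function(s1) {
    gen_stimulus("two_phase_history", stim1 = s1, stim2 = stim2,
                 len1 = p$len1, gap = p$gap, len2 = p$len2)
  }
  blocks <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                  c(0, 0, 1, 1), c(0, 0, 1, 1))
  Qs <- list(
    uncoupled = diag(4),
    posdef = blocks + 0.5 * diag(4),
    nonposdef = blocks - p$shift * diag(4)
  )
  T_ <- p$len1 + p$gap + p$len2
  win <- (T_ - p$window + 1L):T_
  traces <- list()
  rows <- list()
  for (nm in names(Qs)) {
    net <- gt_network(Qs[[nm]], I_psi = p$I_psi, C = 1)
    tr_a <- run_discrete(net, b = mk_course(stim1a), n_steps = T_)
    tr_b <- run_discrete(net, b = mk_course(stim1b), n_steps = T_)
    traces[[paste0(nm, "_histA")]] <- tr_a
    traces[[paste0(nm, "_histB")]] <- tr_b
    rate_a <- rowMeans(tr_a$psi[, win] > 0)
    rate_b <- rowMeans(tr_b$psi[, win] > 0)
    stim2_idx <- (p$len1 + p$gap + 1L):T_
    identical_raster <- identical(tr_a$psi[, stim2_idx] > 0,
                                  tr_b$psi[, stim2_idx] > 0)
    rows[[nm]] <- data.frame(
      coupling = nm,
      min_eigen = min(eigen(Qs[[nm]], symmetric = TRUE,
                            only.values = TRUE)$values),
      identical_stim2_raster = identical_raster,
      max_rate_diff = max(abs(rate_a - rate_b))
    )
  }
  list(traces = traces, metrics = do.call(rbind, rows))
}

.proto_population <- function(p, seed) {
  set.seed(seed)
  coords <- matrix(stats::runif(p$M * 2L, 0, 4), ncol = 2L)
  Q <- gaussian_kernel_Q(coords, gamma = p$gamma)
  net <- gt_network(Q, I_psi = p$I_psi, C = 1)
  # graded drives, some sub-threshold (silent neurons) but none strong
  # enough to pin a potential at the bound
  b <- p$b_scale * stats::runif(p$M, -0.4, 0.8)
  # hyperpolarized start + slow constant modulation: spreads first-spike
  # latencies so the time-to-first-spike code resolves the distance ordering
  tr <- run_continuous(net, b = b, v0 = -0.5 * net$v_c,
                       n_steps = p$n_steps,
                       modulation = mod_constant(p$tau))
  window <- min(5000L, p$n_steps)
  hp <- hyperplane_weights(tr, coords, window = window)
  met <- rate_and_ttfs(tr, onset = 1L)
  met$distance <- hp$distance
  met$psi_mean <- hp$psi_mean
  list(traces = list(population = tr), metrics = met,
       coords = coords, hyperplane = hp)
}
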