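# Shared simulation engine.
#
# Per step n (with state v = v_{n-1}, stimulus column b_n):
#   1. psi_n   = Psi(v)                      (spike currents at the old state)
#   2. g_n     = Q v - b_n + psi_n           (energy gradient)
#   3. tau_n   = modulation(spec, ...)       (NULL spec -> discrete map)
#   4. G       = GT map of (v, g_n)
#      v_n     = v + min(dt/tau, 1) * (G - v)   (exactly G when dt >= tau)
#   5. record v_n, Psi(v_n), s(v_n), H(v_n; b_n)
#
# The convex-combination step preserves |v| <= v_c whenever dt <= tau because
# both endpoints lie inside the box; dt > tau clamps the mixing coefficient
# to 1 which reproduces the discrete map exactly (also bit-for-bit when a
# constant modulation tau equals dt).
.gt_engine <- function(config, b, v0, n_steps, modulation = NULL, dt = 1) {
  M <- config$M
  B <- as_stimulus(b, M, n_steps)
  if (length(v0) == 1L) v0 <- rep(v0, M)
  if (length(v0) != M) stop("v0 must have length M")
  if (any(abs(v0) > config$v_c)) stop("|v0| must be <= v_c")
  lam <- .resolve_lambda(config, B)
  v_c <- config$v_c
  I_psi <- config$I_psi
  Q <- config$Q

  v_rec <- matrix(NA_real_, M, n_steps)
  psi_rec <- matrix(NA_real_, M, n_steps)
  H_rec <- numeric(n_steps)
  tau_rec <- if (!is.null(modulation)) matrix(NA_real_, M, n_steps) else NULL
  F_rec <- if (!is.null(modulation)) numeric(n_steps) else NULL

  state <- if (is.null(modulation)) NULL else mod_state_init(modulation, M)
  v <- v0
  qv <- drop(Q %*% v)
  psi_lag <- numeric(M)  # spike currents already emitted (previous step)
  for (n in seq_len(n_steps)) {
    b_n <- B[, n]
    psi_v <- ifelse(v > 0, I_psi, 0)
    g <- qv - b_n + psi_v
    if (max(abs(g)) >= lam) {
      stop(sprintf(
        "lambda-dominance violated at step %d: lambda = %g, max|dH/dv| = %g",
        n, lam, max(abs(g))
      ))
    }
    G <- .gt_map(v, g, v_c, lam)
    if (is.null(modulation)) {
      v <- G
    } else {
      # Filter-based modulations see the spike history up to the previous
      # step (causal lag); the burst counter sees the current indicator.
      mt <- .mod_tau(modulation, state, v, psi_lag, Q,
                     H_rec[seq_len(n - 1L)], dt)
      state <- mt$state
      tau <- pmax(mt$tau, 0)
      a <- ifelse(tau <= dt, 1, dt / tau)
      v <- ifelse(a >= 1, G, v + a * (G - v))
      tau_rec[, n] <- tau
      if (!is.null(mt$F)) F_rec[n] <- mt$F
    }
    psi_lag <- psi_v
    qv <- drop(Q %*% v)
    v_rec[, n] <- v
    psi_rec[, n] <- ifelse(v > 0, I_psi, 0)
    H_rec[n] <- 0.5 * sum(v * qv) - sum(b_n * v) + I_psi * sum(pmax(v, 0))
  }

  spikes <- apply(psi_rec > 0, 1L, which, simplify = FALSE)
  structure(
    list(
      v = v_rec,
      psi = psi_rec,
      s = v_rec + config$C * psi_rec,
      H = H_rec,
      spikes = spikes,
      v0 = v0,
      b = B,
      lam = lam,
      dt_equiv = dt,
      tau = tau_rec,
      F_gate = F_rec,
      config = config,
      modulation = modulation
    ),
    class = "gt_trace"
  )
}

#' Simulate the discrete-time Growth Transform network
#'
#' Iterates the multiplicative GT update from `v0` for `n_steps` steps,
#' recording membrane potentials, spike currents, composite spike signals
#' and the network energy at every step. A spike event is recorded at each
#' step whose potential is strictly above threshold.
#'
#' @param config a [gt_network()].
#' @param b stimulus: scalar, M-vector (constant in time) or M x T matrix.
#' @param v0 initial potentials (scalar broadcast or M-vector), `|v0| <= v_c`.
#' @param n_steps number of update steps.
#' @return A `gt_trace`: list with M x T matrices `v`, `psi`, `s`, energy
#'   vector `H`, per-neuron spike step indices `spikes`, the realized
#'   stimulus `b`, and the `lambda` used.
#' @examples
#' net <- gt_network(Q = matrix(1), I_psi = 0)
#' tr <- run_discrete(net, b = 0.4, v0 = 0, n_steps = 200)
#' tail(tr$v[1, ], 1)  # converges to b / Q0 = 0.4
#' @export
run_discrete <- function(config, b = 0, v0 = 0, n_steps = 1000L) {
  .gt_engine(config, b, v0, n_steps, modulation = NULL, dt = 1)
}

#' Simulate the continuous-time Growth Transform network
#'
#' Forward-Euler integration of the modulated dynamical system
#' `tau_i dv_i/dt + v_i = G_i(v)`, where `G` is the Growth Transform map
#' and `tau_i(t)` comes from a per-neuron modulation function. Each step
#' applies the convex combination `v + (dt/tau) (G - v)`, which preserves
#' the bound constraint whenever `dt <= tau`; `tau <= dt` means
#' instantaneous relaxation (the discrete map). With `tau = dt` everywhere
#' the trace is bit-for-bit identical to [run_discrete()].
#'
#' @inheritParams run_discrete
#' @param modulation a modulation spec (see [modulation-specs]) broadcast to
#'   all neurons.
#' @param dt integration step; modulation time constants share its unit.
#' @return A `gt_trace`; additionally carries the realized per-neuron `tau`
#'   matrix and, for global adaptation, the gate value per step (`F_gate`).
#' @export
run_continuous <- function(config, b = 0, v0 = 0, n_steps = 1000L,
                           modulation = mod_constant(1), dt = 1) {
  stopifnot(inherits(modulation, "gt_modulation"), dt > 0)
  .gt_engine(config, b, v0, n_steps, modulation = modulation, dt = dt)
}

#' One continuous-time integration step
#'
#' Exposes the Euler step used by [run_continuous()]:
#' `v + (dt/tau) * (G(v) - v)` per neuron, with instantaneous relaxation
#' (`v <- G(v)`) wherever `tau <= dt`. `tau = dt` therefore reproduces
#' [gt_update()] exactly, and infinite `tau` freezes the neuron.
#'
#' @param v membrane potential vector, `|v| <= v_c`.
#' @param config a [gt_network()].
#' @param b stimulus vector (A).
#' @param tau per-neuron time constants (scalar broadcast), `>= 0`.
#' @param dt integration step.
#' @param lam optional GT current parameter override.
#' @return updated potential vector.
#' @export
continuous_step <- function(v, config, b = 0, tau = 1, dt = 1, lam = NULL) {
  if (is.null(lam)) lam <- .resolve_lambda(config, b)
  if (any(tau < 0)) stop("tau must be non-negative")
  g <- energy_gradient(v, config, b)
  if (max(abs(g)) >= lam) {
    stop(sprintf(
      "lambda-dominance violated: lambda = %g but max|dH/dv| = %g",
      lam, max(abs(g))
    ))
  }
  G <- .gt_map(v, g, config$v_c, lam)
  tau <- rep_len(tau, length(v))
  a <- ifelse(tau <= dt, 1, dt / tau)
  ifelse(a >= 1, G, v + a * (G - v))
}

#' @export
print.gt_trace <- function(x, ...) {
  M <- nrow(x$v)
  T_ <- ncol(x$v)
  n_sp <- sum(lengths(x$spikes))
  cat("<gt_trace>", M, "neurons x", T_, "steps,", n_sp, "spikes\n")
  cat("  H: first =", format(x$H[1]), " last =", format(x$H[T_]),
      " lambda =", format(x$lam), "\n")
  invisible(x)
}

#' Total spike count of a trace
#'
#' @param trace a `gt_trace`.
#' @return integer number of spike events (supra-threshold steps) summed
#'   over all neurons.
#' @export
spike_count <- function(trace) {
  sum(lengths(trace$spikes))
}
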