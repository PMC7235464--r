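#' Modulation function specifications
#'
#' A modulation spec selects and parameterizes the per-neuron time constant
#' `tau_i(t)` of the continuous-time Growth Transform system. `tau` shapes
#' the trajectory and spiking statistics of the network without moving the
#' energy minimum: small `tau` means fast relaxation toward the
#' instantaneous GT map, large `tau` means slow dynamics and sparse
#' threshold crossings.
#'
#' Available kinds:
#' * `mod_constant(tau)`: tonic spiking; fixed `tau` for all neurons.
#' * `mod_bursting(tau1, tau2, B)`: spikes arrive in groups. While the
#'   per-neuron counter of consecutive supra-threshold steps is below `B`
#'   the neuron runs slowly (`tau1`), prolonging the supra-threshold
#'   excursion into a `B`-spike burst; when the counter reaches `B` one fast
#'   step (`tau2`) snaps the potential below threshold and the counter
#'   resets, leaving a long quiescent gap. Requires `tau1 > tau2`.
#' * `mod_sfa(tau, alpha)`: spike-frequency adaptation,
#'   `tau_i = tau - 2*phi(h * Psi_i)` where `h` is a first-order low-pass
#'   filter with coefficient `alpha`; fast initial firing that settles to a
#'   lower steady rate. Negative values are clamped at the integrator floor.
#' * `mod_presynaptic(tau, alpha)`: `tau_i = phi(h * sum_j Q_ij Psi_j)`;
#'   excitatory (positive) filtered pre-synaptic drive speeds a neuron up,
#'   inhibitory drive slows it down.
#' * `mod_global(tau, alpha, F0, T_w, eps_H)`: pre-synaptic adaptation plus
#'   an energy gate: once the windowed least-squares slope of the energy
#'   (window `T_w` steps, absolute tolerance `eps_H`; `eps_H = NULL`
#'   selects the scale-adaptive `1e-4 * |H| + 1e-8`) is approximately
#'   zero, the constant `F0` is
#'   subtracted inside the filter argument, pushing every `tau_i` toward its
#'   ceiling and encoding the converged solution with fewer spikes.
#'
#' @param tau,tau1,tau2 time constants, in units of the integration step.
#' @param B burst length (positive integer count of supra-threshold steps).
#' @param alpha low-pass filter coefficient in `(0, 1]`.
#' @param F0 positive adaptation current applied once the network energy has
#'   converged.
#' @param T_w window (steps) over which `dH/dt` is averaged.
#' @param eps_H absolute tolerance declaring `E[dH/dt] ~ 0`, or `NULL` for
#'   the adaptive default.
#' @return an object of class `gt_modulation`.
#' @name modulation-specs
NULL

.mod_spec <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "gt_modulation")
}

#' @rdname modulation-specs
#' @export
mod_constant <- function(tau = 1) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0)
  .mod_spec("constant", tau = tau)
}

#' @rdname modulation-specs
#' @export
mod_bursting <- function(tau1 = 20, tau2 = 1, B = 5L) {
  stopifnot(tau1 > 0, tau2 > 0, tau1 > tau2, B >= 1)
  .mod_spec("bursting", tau1 = tau1, tau2 = tau2, B = as.integer(B))
}

#' @rdname modulation-specs
#' @export
mod_sfa <- function(tau = 10, alpha = 0.1) {
  stopifnot(tau > 0, alpha > 0, alpha <= 1)
  .mod_spec("spike_freq_adapt", tau = tau, alpha = alpha)
}

#' @rdname modulation-specs
#' @export
mod_presynaptic <- function(tau = 20, alpha = 0.3) {
  stopifnot(tau > 0, alpha > 0, alpha <= 1)
  .mod_spec("presynaptic", tau = tau, alpha = alpha)
}

#' @rdname modulation-specs
#' @export
mod_global <- function(tau = 20, alpha = 0.3, F0 = 5, T_w = 100L,
                       eps_H = 1e-3) {
  stopifnot(tau > 0, alpha > 0, alpha <= 1, F0 > 0, T_w >= 2)
  .mod_spec("global_adapt", tau = tau, alpha = alpha, F0 = F0,
            T_w = as.integer(T_w), eps_H = eps_H)
}

#' @export
print.gt_modulation <- function(x, ...) {
  ps <- x[setdiff(names(x), "kind")]
  cat("<gt_modulation>", x$kind, ":",
      paste(names(ps), unlist(ps), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Compressive map from filtered drive to time constant
#'
#' `phi(x) = tau / (1 + exp(x))`: a falling sigmoid with range `(0, tau)`.
#' Zero drive gives `tau/2`; strong positive (excitatory) drive gives a
#' small time constant (fast dynamics), strong negative drive saturates at
#' the ceiling `tau`.
#'
#' @param x filtered drive (A), any shape.
#' @param tau time-constant ceiling.
#' @return time constant(s), same shape as `x`.
#' @export
phi_compress <- function(x, tau) {
  tau / (1 + exp(x))
}

#' One step of the first-order smoothing filter
#'
#' Exponential smoothing `out <- (1 - alpha) * out + alpha * input`, the
#' discrete surrogate of the continuous first-order filter `h(t)`.
#' DC gain is 1; an impulse decays geometrically with rate `1 - alpha`.
#'
#' @param state current filter output (vector or scalar).
#' @param input new input sample.
#' @param alpha coefficient in `(0, 1]`; `alpha = 1` disables smoothing.
#' @return list with the updated `state` and the filter `output` (equal).
#' @export
lowpass_step <- function(state, input, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  out <- (1 - alpha) * state + alpha * input
  list(state = out, output = out)
}

#' Initialize per-neuron modulation state
#'
#' @param spec a modulation spec (see [modulation-specs]).
#' @param M number of neurons.
#' @return list with burst counters `c`, filter accumulators `filt`, and an
#'   energy history placeholder `H_hist`.
#' @export
mod_state_init <- function(spec, M) {
  list(c = integer(M), filt = numeric(M), H_hist = numeric(0))
}

#' Bursting time constants
#'
#' Implements the counter law: while a neuron's counter is below `B` it is
#' incremented by the supra-threshold indicator and the slow constant
#' `tau1` applies; once the counter reaches `B`, the fast constant `tau2`
#' applies for that step and the counter resets to zero.
#'
#' @param state modulation state from [mod_state_init()].
#' @param spiked logical/0-1 vector of current supra-threshold indicators.
#' @param spec a [mod_bursting()] spec.
#' @return list with per-neuron `tau` and the updated `state`.
#' @export
tau_bursting <- function(state, spiked, spec) {
  cnt <- state$c
  cnt <- ifelse(cnt >= spec$B, 0L, cnt + as.integer(spiked > 0))
  tau <- ifelse(cnt >= spec$B, spec$tau2, spec$tau1)
  state$c <- as.integer(cnt)
  list(tau = tau, state = state)
}

#' Spike-frequency-adaptation time constants
#'
#' `tau_i = tau - 2 * phi(h * Psi_i)`. At zero spike history the expression
#' is exactly zero (fast initial firing, clamped at `tau_floor`); sustained
#' spiking drives `tau_i` toward the ceiling `tau` and a lower firing rate.
#'
#' @param state modulation state.
#' @param psi current spike currents `Psi(v_i)` (A).
#' @param spec a [mod_sfa()] spec.
#' @param tau_floor lower clamp, normally the integration step.
#' @return list with per-neuron `tau` and the updated `state`.
#' @export
tau_spike_freq_adapt <- function(state, psi, spec, tau_floor = 1) {
  lp <- lowpass_step(state$filt, psi, spec$alpha)
  state$filt <- lp$state
  tau <- spec$tau - 2 * phi_compress(lp$output, spec$tau)
  list(tau = pmax(tau, tau_floor), state = state)
}

#' Pre-synaptic adaptation time constants
#'
#' `tau_i = phi(h * sum_j Q_ij Psi_j)`: each neuron's speed follows its
#' filtered, coupling-weighted pre-synaptic spike input. Net excitatory
#' input yields `tau_i < tau/2` (faster), net inhibitory input
#' `tau_i > tau/2` (slower).
#'
#' @param state modulation state.
#' @param psi current spike-current vector of the whole population (A).
#' @param Q coupling matrix.
#' @param spec a [mod_presynaptic()] spec.
#' @return list with per-neuron `tau` and the updated `state`.
#' @export
tau_presynaptic <- function(state, psi, Q, spec) {
  drive <- drop(Q %*% psi)
  lp <- lowpass_step(state$filt, drive, spec$alpha)
  state$filt <- lp$state
  list(tau = phi_compress(lp$output, spec$tau), state = state)
}

#' Global-adaptation time constants
#'
#' Pre-synaptic adaptation with an energy-convergence gate:
#' `tau_i = phi(h * (sum_j Q_ij Psi_j - F))` where `F = F0` once the
#' windowed mean of `dH/dt` over the last `T_w` recorded energies is within
#' `eps_H` of zero, and `F = 0` during transients. With `F0` active the
#' filter argument is pushed negative and every `tau_i` rises toward its
#' ceiling, so a converged network keeps encoding the same attractor with
#' fewer spikes.
#'
#' @param state modulation state.
#' @param psi current spike-current vector (A).
#' @param Q coupling matrix.
#' @param H_hist numeric vector of recorded network energies up to now.
#' @param spec a [mod_global()] spec.
#' @param dt integration step used for the finite-difference `dH/dt`.
#' @return list with per-neuron `tau`, the updated `state`, and the gate
#'   value `F` applied this step.
#' @export
tau_global_adapt <- function(state, psi, Q, H_hist, spec, dt = 1) {
  F_now <- 0
  n <- length(H_hist)
  if (n >= spec$T_w) {
    hw <- H_hist[(n - spec$T_w + 1L):n]
    # least-squares slope: insensitive to limit-cycle phase at the window
    # endpoints, unlike the telescoping mean of first differences
    tt <- seq_along(hw)
    hdot <- sum((tt - mean(tt)) * (hw - mean(hw))) /
      (sum((tt - mean(tt))^2) * dt)
    eps <- spec$eps_H
    if (is.null(eps)) eps <- 1e-4 * abs(hw[length(hw)]) + 1e-8
    if (abs(hdot) < eps) F_now <- spec$F0
  }
  drive <- drop(Q %*% psi) - F_now
  lp <- lowpass_step(state$filt, drive, spec$alpha)
  state$filt <- lp$state
  list(tau = phi_compress(lp$output, spec$tau), state = state, F = F_now)
}

# Dispatch used by the simulation engine: one broadcast spec for the whole
# population. Returns list(tau, state).
.mod_tau <- function(spec, state, v, psi, Q, H_hist, dt) {
  switch(spec$kind,
    constant = list(tau = rep(spec$tau, length(v)), state = state),
    bursting = tau_bursting(state, v > 0, spec),
    spike_freq_adapt = tau_spike_freq_adapt(state, psi, spec, tau_floor = dt),
    presynaptic = tau_presynaptic(state, psi, Q, spec),
    global_adapt = tau_global_adapt(state, psi, Q, H_hist, spec, dt),
    stop("unknown modulation kind: ", spec$kind)
  )
}
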