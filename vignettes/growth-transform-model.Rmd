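---
title: "The Growth Transform spiking network: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Growth Transform spiking network: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtneuron)
```

## The model

`gtneuron` simulates populations of spiking neurons whose dynamics are not
postulated as differential equations per cell but *derived* from a network
objective. A population of $M$ neurons with membrane potentials
$v \in \mathbb{R}^M$, coupling matrix $Q$ (trans-conductances,
$\Omega^{-1}$) and external currents $b$ minimizes the energy

$$H(v) \;=\; \tfrac12 v^\top Q v \;-\; b^\top v \;+\;
  I_\Psi \sum_i \max(v_i, 0),
\qquad |v_i| \le v_c ,$$

which can be read as the extrinsic power supplied to the network: coupling
dissipation, stimulus power, and the power dissipated by spiking. The last
term is a barrier whose gradient is the discontinuous spike current
$\Psi(v_i) = I_\Psi \,[v_i > 0]$: below the threshold (0 V, with potentials
normalized to $v_c = 1$ V) the neuron behaves like a graded unit; any
attempt to cross the threshold is penalized, so when the unconstrained
minimum would put $v_i$ above 0, the potential oscillates around the
discontinuity instead. Those supra-threshold excursions are the spikes; a
hyperpolarized step after each excursion plays the role of a refractory
period.

The minimization is performed by the Growth Transform (GT) multiplicative
update, a fixed-point map derived from the Baum–Eagon inequality:

$$v_i \leftarrow v_c \,
 \frac{-\,g_i v_c + \lambda v_i}{-\,g_i v_i + \lambda v_c},
 \qquad g_i = \frac{\partial H}{\partial v_i}
  = (Qv)_i - b_i + \Psi(v_i).$$

Provided the normalization current dominates the gradient,
$\lambda > |g_i|$ at every visited state, the map (a) keeps every
$|v_i| \le v_c$ exactly, (b) never increases $H$ where the gradient is
continuous, and (c) drives the long-run mean of the certificate
$z_{i,n} = (v_c^2 - v_{i,n} v_{i,n+1})\, g_{i,n}$ to zero. The third
property is the useful one in the spiking regime: the network settles in a
limit cycle whose *time averages* satisfy the first-order condition
$Q\bar v - \bar b + \bar\Psi = 0$, so mean spike rates encode the
constrained optimum. For an uncoupled neuron with $Q_0 = 1$, $C = 1/Q_0$,
the composite spike signal $s = v + C\Psi(v)$ therefore time-averages to
$C\,\bar b$ — the encoding identity checked by
`steady_state_encoding_check()`.

A continuous-time version wraps the same map in a relaxation
$\tau_i(t)\, \dot v_i + v_i = G_i(v)$ with a per-neuron *modulation
function* $\tau_i(t)$. Crucially, $\tau$ shapes the trajectory and the
spiking statistics but not the attractor, so firing patterns can be
redesigned (tonic, bursting, adapting, …) without touching the network
solution.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `v_c` | V | 1 | potential bound; also the saturation level of the implied squashing nonlinearity |
| `I_psi` | A | 1 | spike current; sets both the barrier slope and the rate scale (an uncoupled neuron fires at $\approx b/I_\Psi$ events per step) |
| `C` | $\Omega$ | `1/Q0` (uncoupled) else 1 | spike height of the composite signal is $C I_\Psi$ volts |
| `lam` | A | auto | GT normalization; see "Numerical choices" |
| `tau` (modulation) | steps | per spec | relaxation time constant, in units of the integration step `dt = 1` |
| `alpha` (modulation) | – | 0.3 | low-pass coefficient of the smoothing filter $h$; memory $\approx 1/\alpha$ steps |
| `F0`, `T_w`, `eps_H` | A, steps, W/step | 5, 100, 1e-3 | global-adaptation gate: once the least-squares slope of $H$ over `T_w` steps is within `eps_H` of zero, `F0` is subtracted inside the filter argument |

## Numerical choices

**$\lambda$ selection.** The theory requires $\lambda > |g_i|$ but fixes no
value. `gt_network(lam = NULL)` uses the static bound
$1.2\,(\lVert Q\rVert_\infty v_c + \max|b| + I_\Psi)$, which dominates the
gradient on the whole reachable box; a user value is still checked at
every step and a violation aborts the run with the offending step index.
$\lambda$ is also the map's *resolution*: the limit-cycle amplitude around
the threshold scales like $v_c |g| / \lambda$, and time-average identities
(e.g. $\bar s = C\bar b$) carry a discretization bias of order
$(v_c/\lambda)^2$. We measured an 8% relative bias at $b = 0.1$ with the
default bound and 0.3% at $\lambda = 10$; the encoding acceptance check
therefore runs at $\lambda = 10$. Nothing else in the package depends on
this choice.

**Integrator.** The continuous system is integrated by forward Euler in
the convex-combination form $v \leftarrow v + (dt/\tau)(G(v) - v)$, which
inherits the bound guarantee whenever $dt \le \tau$. $\tau \le dt$ means
instantaneous relaxation and is implemented as direct assignment
$v \leftarrow G(v)$; consequently a constant $\tau = dt$ reproduces the
discrete map *bit for bit* (an acceptance criterion). No higher-order or
adaptive solver is offered: the right-hand side is discontinuous at the
threshold, and the fixed-step convex form is the contract that keeps the
GT guarantees.

**Threshold and spike conventions.** A spike is recorded at every step
with $v > 0$ strictly; $v = 0$ is non-spiking. Under $\lambda$-dominance
and moderate drive ($b \lesssim I_\Psi/2$ for an uncoupled unit)
supra-threshold excursions last one step, so "supra-threshold step" and
"spike event" coincide; at drives approaching $I_\Psi$ excursions can span
consecutive steps (the above-threshold gradient $\approx I_\Psi - b$
shrinks), which is why the refractoriness test is stated for
$b \le 0.5\,I_\Psi$.

**Modulation timing.** Within one step the engine evaluates
$\tau$ *before* the update, feeding the filters the spike indicator of the
*previous* step (the events already emitted). This causal convention is
not cosmetic. The steady firing rate of this model is pinned by a
duty-cycle balance — over a cycle the sub-threshold climb
($|g| \approx b$) and the supra-threshold descent
($|g| \approx I_\Psi - b$) must cancel — and a *constant* $\tau$ of any
size cancels out of that balance: slowing the whole cycle shrinks the
oscillation amplitude instead of lengthening the inter-spike interval.
Rate changes therefore require $\tau$ to be *phase-correlated* with the
cycle. With the causal lag, a spike raises the filtered activity just
after the crossing, so the escape is fast and the early recovery slow;
that asymmetry lowers the duty cycle and produces genuine
spike-frequency adaptation. With the anti-causal ordering the correlation
reverses and "adaptation" *raises* the rate — we measured both. The same
analysis explains two deviations from first-pass defaults, both ledgered:
the filter coefficient must act on the inter-spike timescale
(`alpha = 0.3`, not 0.01, for the pre-synaptic/global laws; the
spike-frequency-adaptation demo uses a deliberately slow
`alpha = 0.001` so the decay is visible across a 2000-step window), and
the convergence gate of global adaptation uses a least-squares slope of
the energy history rather than a mean of first differences — the latter
telescopes to an endpoint difference that fluctuates with limit-cycle
phase and makes the gate flicker. `eps_H` defaults to the absolute
`1e-3` for the same reason.

**Bursting.** The counter law increments a per-neuron count on each
supra-threshold step while it is below `B`, switches the time constant
from the slow `tau1` to the fast `tau2` when the count reaches `B`, and
resets immediately. Mechanistically, the slow `tau1` *prolongs* the
supra-threshold excursion into a group of exactly `B` spike-steps; the
single fast step snaps the potential below threshold, and the slow
sub-threshold recovery creates the quiescent gap. Intra-burst intervals
are 1–2 steps while gaps are an order of magnitude longer, which is how
the burst segmentation in the protocol (gap threshold 3 steps) separates
them.

**Pseudo-inverse.** `remap_weights()` maps a synaptic matrix to coupling
space, $Q = -(1-\gamma)W^{-1}$, $b = -W^{-1}y$; for singular $W$ an SVD
pseudo-inverse drops singular values below $10^{-10}\sigma_{\max}$.

## The associative memory

Binary patterns $t^s$ (exactly $m = 10$ active of $M = 100$ units) are
stored by the Hebbian rule $Q_{ij} = \frac1k \sum_s t_i^s t_j^s$ with
$k = m$. A recall stimulates a seeded random half of a pattern's active
units with a steady depolarizing current and the full spiking trajectory
is compared against the reference trajectories of all stored patterns.
Decoding (per `bin_len = 50` steps and neuron) concatenates mean rate,
mean intra-bin inter-spike interval (bin length if a bin holds one spike,
twice the bin length if none) and the rate change against the previous
bin; similarity is one minus the min–max-normalized mean per-bin Euclidean
distance, normalized over the full stored-by-recalled comparison set so
that 0 and 1 are attained. Accuracy is argmax-similarity classification
with ties broken toward the lowest pattern index.

Two documented choices differ from a literal first reading and are in the
ledger. First, the non-adaptive baseline runs under the *pre-synaptic*
modulation law (the coupled-network law the model family prescribes for
these networks), not the raw discrete map: in discrete mode the large
limit-cycle amplitude makes every spiking neuron's mean potential
markedly negative, which leaks drive through the Hebbian couplings into
non-pattern neurons ("spread activation") and degrades recall at
moderate drives; under the pre-synaptic law both conditions recall
perfectly at $S = 10$. Second, the cue drive defaults to
$0.2\,v_c$ — strong enough to put cued units mid dynamic range, weak
enough not to saturate them.

The energy argument for global adaptation is visible in the numbers: with
the gate engaged the network encodes the same attractor (first-order
residuals agree within 5% of the current scale) using 20–30% fewer spikes
per recall; the acceptance suite checks the reduction on ten paired seeds.

## What the synthetic generators emulate — and what they do not

`gen_patterns()` reproduces the stated storage ensemble (uniform random
$m$-sparse binary patterns); `gen_noisy_binary()` reproduces the
additive-white-Gaussian-noise corruption with variance set by the SNR in
dB and re-thresholding at 0.5; `gen_stimulus()` provides the step, ramp,
pulse-train and two-phase history drives used by the protocols. The
classification demo replaces the handwritten-digit images of the original
experiments with this seeded synthetic ensemble: same structure (binary
images, Hebbian storage, unseen noisy test items), but none of the
correlated pixel statistics of real images. A green classification test
therefore establishes the mechanism (similarity decoding of spiking
trajectories survives binary noise), not any particular image-benchmark
accuracy; real images can be supplied to `hebbian_couplings()` and
`noisy_pattern_classify()` directly.

Protocol defaults that the source material leaves open (stimulus
amplitudes, pulse spacings, regime time constants, the 4-neuron
non-positive-definite coupling, the planar layout of the kernel
population) were chosen once, to sit well inside the qualitative regime
they demonstrate, and are recorded in `.protocol_defaults()`; the
non-positive-definite coupling is built as a two-block Hebbian matrix
shifted by $-1.5 I$ (eigenvalues $\{2.5, 0.5, -1.5\}$-type spectrum,
logged per run), and the history stimuli are asymmetric within a block
because a symmetric drive never excites the unstable direction that
stores the memory.

## Degenerate inputs and edge rules

* `psi_current(0) = 0`: the threshold itself does not spike.
* Empty decode bins get ISI `2 * bin_len`; single-spike bins `bin_len`;
  the first bin's rate change is differenced against zero.
* A similarity comparison set in which all pairs are equidistant
  normalizes to distance 0 (all pairs maximally similar).
* A fully erased noisy test item (no active units) is scored as a miss
  rather than simulated.
* `tau = Inf` freezes a neuron; `tau <= dt` relaxes it instantaneously;
  negative `tau` is an error.
* Time-to-first-spike is `Inf` (serialized as an empty field) for neurons
  that never fire in the window.

## Known limitations

* The intra-spike runaway process is not modeled; spikes are stereotyped
  events of height $C I_\Psi$ superimposed on the sub-threshold waveform.
* No synaptic learning during recall; couplings are fixed after Hebbian
  storage.
* One modulation spec is broadcast to the whole population per run;
  heterogeneous per-neuron modulation kinds are not supported by the
  runner (the per-neuron `tau_*` functions themselves are vectorized).
* Rate quantization: with `dt = 1` the discrete map locks onto short
  periodic orbits, so tuning curves move in rational steps (visible as
  plateaus); larger `lambda` or slower `tau` refine them.
* The time-average identities hold to $O((v_c/\lambda)^2)$; exact
  agreement is asymptotic in $\lambda$.
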