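test_that("compressive map and low-pass filter obey their definitions", {
  expect_equal(phi_compress(0, 1), 0.5)
  expect_lt(phi_compress(50, 1), 1e-20)
  expect_equal(phi_compress(-50, 1), 1, tolerance = 1e-12)
  # range (0, tau)
  x <- seq(-10, 10, length.out = 101)
  expect_true(all(phi_compress(x, 3) > 0 & phi_compress(x, 3) < 3))

  # alpha = 1: no smoothing
  expect_equal(lowpass_step(0.7, 2, alpha = 1)$output, 2)
  # DC gain 1
  st <- 0
  for (i in 1:2000) st <- lowpass_step(st, 0.8, alpha = 0.05)$state
  expect_equal(st, 0.8, tolerance = 1e-6)
  # impulse response: geometric decay
  st <- lowpass_step(0, 1, 0.5)$state
  outs <- st
  for (i in 1:2) {
    st <- lowpass_step(st, 0, 0.5)$state
    outs <- c(outs, st)
  }
  expect_equal(outs, c(0.5, 0.25, 0.125))
})

test_that("burst counter law: count, switch, reset", {
  spec <- mod_bursting(tau1 = 20, tau2 = 1, B = 3L)
  st <- mod_state_init(spec, 2)
  # no spikes: tau1 for all, counters stay 0
  r <- tau_bursting(st, spiked = c(FALSE, FALSE), spec)
  expect_equal(r$tau, c(20, 20))
  expect_equal(r$state$c, c(0L, 0L))
  # B consecutive spikes on neuron 1: one step at tau2, then reset
  st <- mod_state_init(spec, 1)
  taus <- integer(0)
  for (k in 1:4) {
    r <- tau_bursting(st, spiked = TRUE, spec)
    st <- r$state
    taus <- c(taus, r$tau)
    expect_lte(st$c, spec$B)  # counter never exceeds B
  }
  expect_equal(taus, c(20, 20, 1, 20))  # switch at c = B, immediate reset
})

test_that("bursting run emits spike groups of length B separated by gaps", {
  pr <- run_protocol(gt_protocol("bursting"))
  m <- pr$metrics
  expect_gt(m$n_bursts, 10)
  expect_equal(m$burst_len_mode, 5)  # B = 5
  expect_gt(m$gap_mean, 3 * m$intra_isi)
})

test_that("spike-frequency adaptation: zero history floors tau, history raises it", {
  spec <- mod_sfa(tau = 10, alpha = 0.5)
  st <- mod_state_init(spec, 1)
  r0 <- tau_spike_freq_adapt(st, psi = 0, spec, tau_floor = 1)
  expect_equal(r0$tau, 1)  # tau - 2*phi(0) = 0, clamped to the floor
  # sustained spiking drives tau toward the ceiling
  st <- mod_state_init(spec, 1)
  for (k in 1:200) {
    r <- tau_spike_freq_adapt(st, psi = 5, spec, tau_floor = 1)
    st <- r$state
  }
  expect_gt(r$tau, 0.9 * spec$tau)
  expect_lte(r$tau, spec$tau)
})

test_that("adaptation regime: firing rate decays under constant input", {
  pr <- run_protocol(gt_protocol("adaptation"))
  m <- pr$metrics
  expect_gt(m$rate_q1, m$rate_q4)
  # monotone trend across quartiles
  expect_gte(m$rate_q1, m$rate_q2)
  expect_gte(m$rate_q2, m$rate_q4)
})

test_that("pre-synaptic adaptation: excitatory speeds up, inhibitory slows down", {
  spec <- mod_presynaptic(tau = 10, alpha = 1)  # alpha 1: no smoothing lag
  Q <- matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE)  # 1<-2 excit., 2<-1 inhib.
  st <- mod_state_init(spec, 2)
  r0 <- tau_presynaptic(st, psi = c(0, 0), Q, spec)
  expect_equal(r0$tau, c(5, 5))  # phi(0) = tau/2
  r1 <- tau_presynaptic(st, psi = c(1, 1), Q, spec)
  expect_lt(r1$tau[1], 5)  # excitatory input -> faster
  expect_gt(r1$tau[2], 5)  # inhibitory input -> slower
})

test_that("global adaptation gate switches on energy convergence", {
  spec <- mod_global(tau = 10, alpha = 1, F0 = 4, T_w = 10L, eps_H = 1e-3)
  Q <- diag(2)
  st <- mod_state_init(spec, 2)
  # transient: clearly decreasing energy -> F = 0, identical to presynaptic
  H_trans <- seq(5, 1, length.out = 20)
  rg <- tau_global_adapt(st, psi = c(1, 0), Q, H_trans, spec)
  expect_equal(rg$F, 0)
  pre <- tau_presynaptic(mod_state_init(spec, 2), psi = c(1, 0), Q,
                         mod_presynaptic(tau = 10, alpha = 1))
  expect_equal(rg$tau, pre$tau)
  # converged: flat energy -> F = F0 and tau strictly larger (phi decreasing)
  H_flat <- rep(1, 20)
  rg2 <- tau_global_adapt(mod_state_init(spec, 2), psi = c(1, 0), Q,
                          H_flat, spec)
  expect_equal(rg2$F, 4)
  expect_true(all(rg2$tau > rg$tau))
  # short history: gate off
  rg3 <- tau_global_adapt(mod_state_init(spec, 2), psi = c(0, 0), Q,
                          rep(1, 3), spec)
  expect_equal(rg3$F, 0)
})

test_that("all tau outputs respect their stated ranges (property)", {
  set.seed(31)
  specs <- list(mod_bursting(15, 2, 4), mod_sfa(12, 0.2),
                mod_presynaptic(9, 0.4), mod_global(9, 0.4, 3, 10, 1e-3))
  Q <- random_symmetric_Q(3)
  for (spec in specs) {
    st <- mod_state_init(spec, 3)
    for (k in 1:50) {
      psi <- sample(c(0, 1), 3, replace = TRUE)
      r <- switch(spec$kind,
        bursting = tau_bursting(st, psi > 0, spec),
        spike_freq_adapt = tau_spike_freq_adapt(st, psi, spec, tau_floor = 1),
        presynaptic = tau_presynaptic(st, psi, Q, spec),
        global_adapt = tau_global_adapt(st, psi, Q, stats::runif(20), spec)
      )
      st <- r$state
      ceiling_tau <- if (spec$kind == "bursting") spec$tau1 else spec$tau
      expect_true(all(r$tau <= ceiling_tau + 1e-12))
      expect_true(all(r$tau > 0))
    }
  }
})

test_that("global adaptation saves spikes without moving the attractor", {
  Q <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  net <- gt_network(Q, I_psi = 1, C = 1)
  b <- c(0.6, 0.3)
  tr_pre <- run_continuous(net, b = b, n_steps = 4000,
                           modulation = mod_presynaptic(20, 0.3))
  tr_glo <- run_continuous(net, b = b, n_steps = 4000,
                           modulation = mod_global(20, 0.3, 5, 100, 1e-3))
  expect_lt(spike_count(tr_glo), spike_count(tr_pre))
  r_pre <- steady_state_encoding_check(tr_pre, window = 1000)$residual
  r_glo <- steady_state_encoding_check(tr_glo, window = 1000)$residual
  scale <- max(net$I_psi, max(abs(b)))
  expect_lt(max(abs(r_pre - r_glo)), 0.05 * scale)
})

test_that("modulation spec constructors validate parameters", {
  expect_error(mod_bursting(tau1 = 1, tau2 = 2))   # needs tau1 > tau2
  expect_error(mod_sfa(alpha = 0))
  expect_error(mod_global(F0 = -1))
  expect_error(mod_constant(tau = -1))
})
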