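test_that("spiking nonlinearity, barrier and energy match their definitions", {
  # threshold is strictly non-spiking
  expect_identical(psi_current(c(0.5, 0, -0.3), I_psi = 1), c(1, 0, 0))
  expect_identical(psi_current(-0.3, I_psi = 7), 0)

  expect_equal(barrier_energy(0.5, 1), 0.5)
  expect_equal(barrier_energy(-2, 1), 0)
  expect_equal(barrier_energy(c(0.5, -0.1), 2), 1)

  n1 <- gt_network(matrix(1), I_psi = 0, C = 1)
  expect_equal(network_energy(0.5, n1, b = 0), 0.125)
  n2 <- gt_network(matrix(1), I_psi = 1, C = 1)
  expect_equal(network_energy(0.5, n2, b = 0), 0.625)
  n3 <- gt_network(diag(2), I_psi = 5, C = 1)
  expect_equal(network_energy(c(0, 0), n3, b = c(0.3, -0.2)), 0)
})

test_that("gradient and GT update reproduce the printed algebra", {
  n0 <- gt_network(matrix(1), I_psi = 0, C = 1)
  expect_equal(energy_gradient(0.5, n0, b = 0.5), 0)
  n1 <- gt_network(matrix(1), I_psi = 1, C = 1)
  expect_equal(energy_gradient(0.5, n1, b = 0), 1.5)
  n2 <- gt_network(2 * diag(2), I_psi = 1, C = 1)
  expect_equal(energy_gradient(c(0.1, -0.1), n2, b = c(0, 0)), c(1.2, -0.2))

  # direct substitution: v = 0, g = 2, lambda = 10 -> -0.2
  net <- gt_network(matrix(0), v_c = 1, lam = 10, I_psi = 0, C = 1)
  expect_equal(gt_update(0, net, b = -2), -0.2)
  # zero gradient is a fixed point
  netfp <- gt_network(matrix(1), lam = 5, I_psi = 0, C = 1)
  expect_equal(gt_update(0.37, netfp, b = 0.37), 0.37)
  # boundary states are algebraic fixed points
  netb <- gt_network(matrix(0), lam = 5, I_psi = 0, C = 1)
  expect_equal(gt_update(1, netb, b = 2), 1)    # g = -2, |g| < lambda
  expect_equal(gt_update(-1, netb, b = -2), -1)
  # lambda-dominance violation raises
  expect_error(gt_update(0, netb, b = 6), "lambda-dominance")
})

test_that("composite spike adds C * I_psi above threshold only", {
  net <- gt_network(matrix(1), I_psi = 1, C = 1)
  expect_equal(composite_spike(0.2, net), 1.2)
  expect_equal(composite_spike(-0.2, net), -0.2)
  net2 <- gt_network(matrix(1), I_psi = 2, C = 0.5)
  expect_equal(composite_spike(0.2, net2), 1.2)
})

test_that("weight remapping matches closed forms and round-trips", {
  r <- remap_weights(-2 * diag(2), gamma = 0, y = c(1, 1))
  expect_equal(r$Q, 0.5 * diag(2))
  expect_equal(r$b, c(0.5, 0.5))

  r2 <- remap_weights(-2 * diag(2), gamma = 0.5)
  expect_equal(r2$Q, 0.25 * diag(2))
  expect_equal(r2$b, c(0, 0))

  # singular W: pseudo-inverse, checked against a spectral-decomposition oracle
  W <- matrix(1, 2, 2)
  r3 <- remap_weights(W, gamma = 0)
  expect_equal(r3$Q, -spectral_pinv(W), tolerance = 1e-10)

  # round-trip for well-conditioned W
  set.seed(4)
  for (i in 1:5) {
    W <- random_symmetric_Q(4) + 3 * diag(4)
    r4 <- remap_weights(W, gamma = 0.3)
    W_back <- -(1 - 0.3) * solve(r4$Q)
    expect_equal(W_back, W, tolerance = 1e-8)
  }
  expect_error(remap_weights(matrix(1, 2, 3)), "square")
})

test_that("discrete runs converge to the expected fixed points", {
  net <- gt_network(matrix(1), I_psi = 0, C = 1)
  tr <- run_discrete(net, b = 0, v0 = 0.8, n_steps = 200)
  expect_lt(abs(tr$v[1, 200]), 1e-6)

  tr2 <- run_discrete(net, b = 0.4, v0 = 0, n_steps = 200)
  expect_lt(abs(tr2$v[1, 200] - 0.4), 1e-6)

  # spiking neuron: oscillates around the threshold, never converging
  nets <- gt_network(matrix(1), I_psi = 1, C = 1)
  tr3 <- run_discrete(nets, b = 0.4, v0 = 0, n_steps = 2000)
  late <- tr3$v[1, 1001:2000]
  expect_gt(sum(late > 0), 100)
  expect_gt(sum(late <= 0), 100)
  expect_gt(length(tr3$spikes[[1]]), 100)
})

test_that("non-spiking steady states match the projected-gradient QP oracle", {
  set.seed(5)
  for (i in 1:10) {
    M <- sample(2:5, 1)
    Q <- random_pd_Q(M)
    b <- stats::runif(M, -1.5, 1.5)
    net <- gt_network(Q, I_psi = 0, C = 1)
    tr <- run_discrete(net, b = b, n_steps = 6000)
    expect_equal(tr$v[, 6000], pg_qp_oracle(Q, b), tolerance = 1e-6)
  }
})

test_that("KKT residual diagnoses fixed points and limit cycles", {
  net <- gt_network(matrix(1), I_psi = 0, C = 1)
  tr <- run_discrete(net, b = 0.4, n_steps = 500)
  expect_lt(abs(kkt_residual(tr, window = 100)), 1e-6)

  nets <- gt_network(matrix(1), I_psi = 1, C = 1)
  trs <- run_discrete(nets, b = 0.4, n_steps = 10000)
  expect_lt(abs(kkt_residual(trs, window = 5000)), 0.01 * 1 * 1)

  # window 1 equals the definition at a single step
  n <- ncol(tr$v)
  g_n <- energy_gradient(tr$v[, n - 1], net, tr$b[, n - 1])
  z_def <- (net$v_c^2 - tr$v[, n - 1] * tr$v[, n]) * g_n
  expect_equal(kkt_residual(tr, window = 1), z_def)
  expect_error(kkt_residual(tr, window = 1000), "window")
})

test_that("steady-state encoding identities hold", {
  # quiescent fixed point: all residuals vanish
  net <- gt_network(matrix(1), I_psi = 1, C = 1)
  tr <- run_discrete(net, b = 0, n_steps = 500)
  chk <- steady_state_encoding_check(tr, window = 100)
  expect_lt(max(chk$residual), 1e-6)

  # uncoupled spiking neuron, C = 1/Q0: mean composite signal encodes C*b
  tr2 <- run_discrete(net, b = 0.5, n_steps = 20000)
  chk2 <- steady_state_encoding_check(tr2, window = 20000)
  expect_equal(chk2$s_mean, 0.5, tolerance = 0.02)

  # Q0 = 0: mean spike current tracks the stimulus (rate = b / I_psi)
  net0 <- gt_network(matrix(0), I_psi = 1, C = 1)
  tr3 <- run_discrete(net0, b = 0.5, n_steps = 20000)
  rate <- length(tr3$spikes[[1]]) / 20000
  expect_equal(rate, 0.5, tolerance = 0.02)
})

test_that("bound constraint holds on random networks (property)", {
  set.seed(9)
  for (i in 1:10) {
    M <- sample(2:20, 1)
    net <- gt_network(random_symmetric_Q(M), I_psi = 1, C = 1)
    v0 <- gt_init_state(net, random = TRUE, seed = i)
    tr <- run_discrete(net, b = stats::runif(M, -1, 1), v0 = v0,
                       n_steps = 2000)
    expect_lte(max(abs(tr$v)), net$v_c + 1e-12)
  }
})

test_that("energy is non-increasing in the smooth regime (property)", {
  set.seed(10)
  for (i in 1:10) {
    M <- sample(2:10, 1)
    net <- gt_network(random_symmetric_Q(M), I_psi = 0, C = 1)
    v0 <- gt_init_state(net, random = TRUE, seed = 100 + i)
    tr <- run_discrete(net, b = stats::runif(M, -1, 1), v0 = v0,
                       n_steps = 1000)
    expect_lte(max(diff(tr$H)), 1e-12)
  }
})

test_that("refractoriness: no two adjacent supra-threshold steps at moderate drive", {
  net <- gt_network(matrix(1), I_psi = 1, C = 1)
  for (b in c(0.1, 0.2, 0.3, 0.4, 0.5)) {
    tr <- run_discrete(net, b = b, n_steps = 3000)
    sp <- tr$spikes[[1]]
    expect_true(all(diff(sp) >= 2), label = paste("refractory at b =", b))
  }
})

test_that("firing rate is non-decreasing in the stimulus and saturates", {
  net <- gt_network(matrix(1), I_psi = 1, C = 1)
  bs <- seq(0.1, 2, by = 0.1)
  rates <- vapply(bs, function(b) {
    tr <- run_discrete(net, b = b, n_steps = 4000)
    length(tr$spikes[[1]]) / 4000
  }, numeric(1))
  expect_true(all(diff(rates) >= -1e-9))
  # saturation: the curve is flat at the top of its range
  expect_equal(diff(rates[bs >= 1.2]), rep(0, sum(bs >= 1.2) - 1))
  expect_lte(max(rates), 1)
  expect_lt(rates[1], 0.25)
})

test_that("lambda auto bound dominates the gradient on random states", {
  set.seed(11)
  for (i in 1:10) {
    M <- sample(2:8, 1)
    net <- gt_network(random_symmetric_Q(M), I_psi = 1, C = 1)
    b <- stats::runif(M, -2, 2)
    lam <- gt_lambda_auto(net, b)
    v <- stats::runif(M, -1, 1)
    expect_gt(lam, max(abs(energy_gradient(v, net, b))))
  }
})

test_that("network constructor validates inputs", {
  expect_error(gt_network(matrix(1:6, 2, 3)), "square")
  expect_error(gt_network(matrix(1), v_c = -1), "v_c")
  expect_error(gt_network(matrix(1), I_psi = -1), "I_psi")
  expect_error(run_discrete(gt_network(matrix(1)), b = c(1, 2)), "length M")
  expect_error(run_discrete(gt_network(matrix(1)), v0 = 2), "v0")
  net <- gt_network(matrix(2), C = NULL)
  expect_equal(net$C, 0.5)  # C defaults to 1/Q0 when uncoupled
})
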