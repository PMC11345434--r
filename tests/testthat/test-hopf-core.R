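test_that("drift reproduces the normal-form algebra", {
  # radial fixed point at r = sqrt(a): a = 0.25, state (0.5, 0)
  s <- one_node(a = 0.25, f = 0)
  expect_equal(hopf_drift(s$params, s$C, c(0.5, 0)), c(0, 0))
  # origin is an equilibrium
  s2 <- one_node(a = -0.05, f = 1.3)
  expect_equal(hopf_drift(s2$params, s2$C, c(0, 0)), c(0, 0))
})

test_that("drift coupling term adds G * C_ij * (x_j - x_i)", {
  p <- oscillator_params(a = c(-0.1, -0.1), f = c(0, 0), G = 1, beta = 0, n = 2)
  C <- coupling_matrix(rbind(c(0, 0), c(0.3, 0)))
  d <- hopf_drift(p, C, c(1, 0, 0, 0))
  # node 2: local part is 0 at the origin, coupling contributes 0.3 * (1 - 0)
  expect_equal(d[2], 0.3)
})

test_that("drift validates dimensions with informative errors", {
  p <- oscillator_params(a = -0.02, f = 1, n = 2)
  expect_error(hopf_drift(p, coupling_matrix(matrix(0, 3, 3)), rep(0, 4)),
               "values")
  expect_error(hopf_drift(p, coupling_matrix(matrix(0, 2, 2)), rep(0, 3)),
               "state")
})

test_that("simulation is bit-identical under the same seed and config", {
  s <- two_node_chain(beta = 0.02)
  cfg <- sim_config(n_steps = 3000, burn_in = 500, seed = 42)
  t1 <- simulate_hopf(s$params, s$C, cfg)
  t2 <- simulate_hopf(s$params, s$C, cfg)
  expect_identical(t1$values, t2$values)
  t3 <- simulate_hopf(s$params, s$C, sim_config(n_steps = 3000, burn_in = 500,
                                                seed = 43))
  expect_false(identical(t1$values, t3$values))
})

test_that("noiseless supercritical node settles on the limit cycle", {
  # radius sqrt(a) to 1e-3 after 10/|a| time units; spectral peak at f
  s <- one_node(a = 0.25, f = 1)
  ts <- simulate_hopf(s$params, s$C,
                      sim_config(n_steps = 50000, burn_in = 45000, seed = 1))
  amp <- max(abs(ts$values))
  expect_lt(abs(amp - sqrt(0.25)), 1e-3)
  sp <- hopfec:::welch_psd(ts$values[, 1], dt = 1e-3)
  peak <- sp$freq[which.max(sp$psd)]
  expect_lt(abs(peak - 1), 1 / (4 * 1) + 1e-9)  # within one 4-s-segment bin
})

test_that("noiseless subcritical node decays monotonically to the origin", {
  s <- one_node(a = -0.05, f = 1)
  ts <- simulate_hopf(s$params, s$C,
                      sim_config(n_steps = 20000, burn_in = 0, seed = 2,
                                 initial_state = c(0.4, 0.1)))
  r <- abs(ts$values[, 1])
  env <- sapply(split(r, rep(1:20, each = 1000)), max)  # per-second envelope
  expect_true(all(diff(env) < 1e-8))
  # radius decays at rate |a|: exp(-0.05 * 19) = 0.39 over the window
  expect_lt(env[20], 0.5 * env[1])
})

test_that("uncoupled nodes are statistically independent", {
  p <- oscillator_params(a = c(-0.5, -0.5), f = c(0.8, 1.4), G = 0,
                         beta = 0.05, n = 2)
  C <- coupling_matrix(matrix(0, 2, 2))
  for (seed in 1:3) {
    ts <- simulate_hopf(p, C, sim_config(n_steps = 22000, burn_in = 2000,
                                         seed = seed))
    fc <- compute_fc(ts)
    expect_lt(abs(fc[1, 2]), 3 / sqrt(nrow(ts$values) * 1e-3 * 0.5 * 2))
  }
})

test_that("a directed link induces the expected lag asymmetry", {
  # corr(x2(t+tau), x1(t)) > corr(x1(t+tau), x2(t)) in >= 95% of replicates
  # at the study working point (fast regional integration timescales)
  s <- two_node_chain(w = 0.05, a = -5, f = c(1, 1), G = 150, beta = 0.02)
  hits <- 0
  for (seed in 1:20) {
    ts <- simulate_hopf(s$params, s$C,
                        sim_config(n_steps = 202000, burn_in = 2000,
                                   seed = seed))
    fs <- compute_lagged_fs(ts, 0.02)
    hits <- hits + (fs[2, 1] > fs[1, 2])
  }
  expect_gte(hits, 19)
})

test_that("weak coupling preserves the uncoupled spectral peaks", {
  p <- oscillator_params(a = c(0.25, 0.25), f = c(1, 1.5), G = 1, beta = 0,
                         n = 2)
  C <- coupling_matrix(rbind(c(0, 0.01), c(0.01, 0)))
  ts <- simulate_hopf(p, C, sim_config(n_steps = 120000, burn_in = 20000,
                                       seed = 3))
  bin <- 1 / 4  # 4-s Welch segments
  for (i in 1:2) {
    sp <- hopfec:::welch_psd(ts$values[, i], dt = 1e-3)
    expect_lt(abs(sp$freq[which.max(sp$psd)] - p$f[i]), bin + 1e-9)
  }
})

test_that("numerical blow-up is caught with advice", {
  p <- oscillator_params(a = 10, f = 0, beta = 0, G = 0, n = 1)
  C <- coupling_matrix(matrix(0, 1, 1))
  expect_error(
    simulate_hopf(p, C, sim_config(dt = 1, n_steps = 100, burn_in = 0,
                                   seed = 1, initial_state = c(1e5, 0))),
    "smaller dt|a_i < 0")
})

test_that("constructors enforce the container invariants", {
  expect_error(oscillator_params(a = -0.02, n = 2), "f|omega")
  expect_error(oscillator_params(a = -0.02, f = 1, omega = 3, n = 1),
               "disagree")
  expect_error(oscillator_params(a = -0.02, f = 1, beta = -1, n = 1), "beta")
  p <- oscillator_params(a = -0.02, omega = 2 * pi * 1.3, n = 1)
  expect_equal(p$f, 1.3)
  expect_error(coupling_matrix(matrix(1, 2, 2)), "diagonal")
  expect_error(coupling_matrix(rbind(c(0, -0.1), c(0, 0))), "nonnegative")
  expect_error(coupling_matrix(matrix(0, 2, 3)), "square")
  expect_error(region_ts(matrix(1, 1, 2), dt = 1e-3), "2 samples")
  expect_error(region_ts(matrix(c(1, NA, 1, 1), 2, 2), dt = 1e-3),
               "non-finite")
  expect_error(moment_pair(fc = matrix(c(1, 0.5, 0.2, 1), 2, 2),
                           fs = diag(2), tau = 0.02), "symmetric")
})
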