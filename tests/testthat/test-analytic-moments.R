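test_that("jacobian has the block rotation-plus-decay structure", {
  p <- oscillator_params(a = -0.05, f = 1, beta = 0.02, G = 0, n = 1)
  sys <- build_jacobian(p, coupling_matrix(matrix(0, 1, 1)))
  om <- 2 * pi
  expect_equal(sys$jacobian, rbind(c(-0.05, -om), c(om, -0.05)),
               ignore_attr = TRUE)
  ev <- eigen(sys$jacobian)$values
  expect_equal(sort(Re(ev)), c(-0.05, -0.05))
  expect_equal(sort(Im(ev)), c(-om, om))
})

test_that("diffusive coupling enters the jacobian diagonal and off-diagonal", {
  p <- oscillator_params(a = c(-0.1, -0.2), f = c(1, 1), G = 1, beta = 0.02,
                         n = 2)
  C <- coupling_matrix(rbind(c(0, 0), c(0.3, 0)))
  A <- build_jacobian(p, C)$jacobian
  expect_equal(A[2, 2], -0.2 - 0.3)  # a_2 - G * rowsum
  expect_equal(A[2, 1], 0.3)         # + G * C_21
  expect_equal(A[4, 4], -0.2 - 0.3)  # same structure in the y block
  expect_equal(A[4, 3], 0.3)
})

test_that("jacobian commutes with the block rotation when omega is scalar", {
  set.seed(10)
  n <- 4
  C <- random_sparse_coupling(n, 0.4, seed = 10)
  p <- oscillator_params(a = runif(n, -0.3, -0.1), f = rep(1.2, n), G = 1,
                         beta = 0.02, n = n)
  A <- build_jacobian(p, C)$jacobian
  R <- rbind(cbind(matrix(0, n, n), -diag(n)), cbind(diag(n), matrix(0, n, n)))
  expect_lt(max(abs(A %*% R - R %*% A)), 1e-12)
})

test_that("stationary covariance matches the Ornstein-Uhlenbeck closed form", {
  p <- oscillator_params(a = -0.05, f = 1, beta = 0.02, G = 0, n = 1)
  sys <- build_jacobian(p, coupling_matrix(matrix(0, 1, 1)))
  S <- stationary_covariance(sys)
  expect_lt(abs(S[1, 1] - 0.02^2 / (2 * 0.05)), 1e-8)
  expect_lt(abs(S[2, 2] - 0.02^2 / (2 * 0.05)), 1e-8)
})

test_that("Lyapunov residual is at machine precision and Sigma is PSD", {
  set.seed(11)
  n <- 5
  C <- random_sparse_coupling(n, 0.4, seed = 11)
  p <- oscillator_params(a = runif(n, -0.4, -0.1), f = runif(n, 0.5, 2),
                         G = 1, beta = 0.02, n = n)
  sys <- build_jacobian(p, C)
  S <- stationary_covariance(sys)
  A <- sys$jacobian
  Q <- diag(p$beta^2, 2 * n)
  expect_lt(max(abs(A %*% S + S %*% t(A) + Q)), 1e-8)
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
  # independent oracle: Kronecker-vectorised linear solve
  I2n <- diag(2 * n)
  S2 <- matrix(solve(kronecker(I2n, A) + kronecker(A, I2n), -as.vector(Q)),
               2 * n, 2 * n)
  expect_lt(max(abs(S - S2)), 1e-10)
})

test_that("uncoupled nodes give a block-diagonal stationary covariance", {
  p <- oscillator_params(a = c(-0.1, -0.3), f = c(0.7, 1.6), G = 0,
                         beta = 0.02, n = 2)
  S <- stationary_covariance(build_jacobian(p, coupling_matrix(matrix(0, 2, 2))))
  # cross-node entries vanish: nodes are independent
  cross <- abs(S[cbind(c(1, 1, 2, 2), c(2, 4, 1, 3))])
  expect_lt(max(cross), 1e-12)
})

test_that("unstable systems are rejected with the stability message", {
  p <- oscillator_params(a = 0.1, f = 1, beta = 0.02, G = 0, n = 1)
  sys <- build_jacobian(p, coupling_matrix(matrix(0, 1, 1)))
  expect_error(stationary_covariance(sys), "stable linear regime")
  expect_error(model_moments(p, coupling_matrix(matrix(0, 1, 1)), 0.02),
               "stable linear regime")
})

test_that("lagged covariance reduces to Sigma at tau = 0 and to the 2x2 closed form", {
  p <- oscillator_params(a = -0.05, f = 1.2, beta = 0.02, G = 0, n = 1)
  sys <- build_jacobian(p, coupling_matrix(matrix(0, 1, 1)))
  S <- stationary_covariance(sys)
  expect_identical(lagged_covariance(sys, S, 0), S)
  tau <- 0.02
  Cv <- lagged_covariance(sys, S, tau)
  expect_lt(abs(Cv[1, 1] - S[1, 1] * exp(-0.05 * tau) * cos(2 * pi * 1.2 * tau)),
            1e-12)
})

test_that("analytic moments match long-simulation moments", {
  # fast-decay regime so 500 s pins the sampling error well below 5%
  set.seed(12)
  n <- 5
  C <- random_sparse_coupling(n, 0.4, seed = 12, lo = 0.2, hi = 0.8)
  p <- oscillator_params(a = rep(-2, n), f = runif(n, 0.9, 1.3), G = 5,
                         beta = 0.02, n = n)
  sys <- build_jacobian(p, C)
  S <- stationary_covariance(sys)
  ts <- simulate_hopf(p, C, sim_config(n_steps = 702000, burn_in = 2000,
                                       seed = 12))
  emp_cov <- cov(ts$values)
  sxx <- S[1:n, 1:n]
  expect_lt(max(abs(diag(emp_cov) - diag(sxx)) / diag(sxx)), 0.05)
  expect_lt(max(abs(emp_cov - sxx)), 0.05 * max(diag(sxx)))
  # lagged covariance against the same simulation
  Cv <- lagged_covariance(sys, S, 0.02)[1:n, 1:n]
  xc <- ts$values
  xc <- sweep(xc, 2, colMeans(xc))
  Tn <- nrow(xc)
  emp_lag <- crossprod(xc[21:Tn, ], xc[1:(Tn - 20), ]) / (Tn - 21)
  expect_lt(max(abs(emp_lag - Cv)), 0.05 * max(diag(sxx)))
  # normalised model moments correlate with empirical ones at r > 0.99
  mm <- model_moments(p, C, 0.02)
  em <- empirical_moments(ts, 0.02)
  expect_gt(cor(offdiag_v(mm$fc), offdiag_v(em$fc)), 0.99)
  expect_gt(cor(offdiag_v(mm$fs), offdiag_v(em$fs)), 0.99)
})

test_that("uncoupled model moments are the closed-form limit", {
  p <- oscillator_params(a = rep(-0.1, 3), f = rep(1, 3), G = 1, beta = 0.02,
                         n = 3)
  mm <- model_moments(p, coupling_matrix(matrix(0, 3, 3)), 0.02)
  expect_equal(mm$fc, diag(3), ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(unname(diag(mm$fs)),
               rep(exp(-0.1 * 0.02) * cos(2 * pi * 0.02), 3),
               tolerance = 1e-10)
  # fs diagonal approaches 1 as tau -> 0
  mm0 <- model_moments(p, coupling_matrix(matrix(0, 3, 3)), 1e-6)
  expect_lt(max(abs(diag(mm0$fs) - 1)), 1e-5)
})

test_that("directed coupling breaks FS symmetry the right way", {
  for (w in c(0.05, 0.2, 0.5)) {
    s <- two_node_chain(w = w, a = -0.5, f = c(1, 1), G = 1)
    mm <- model_moments(s$params, s$C, 0.02)
    expect_gt(mm$fs[2, 1], mm$fs[1, 2])
  }
})
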