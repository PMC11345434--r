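test_that("elementary update step: fixed point, arithmetic, clamp, mask", {
  n <- 3
  fc <- matrix(0.2, n, n); diag(fc) <- 1
  fs <- matrix(0.1, n, n)
  emp <- moment_pair(fc, fs, tau = 0.02)
  C <- coupling_matrix(matrix(0.05, n, n) - diag(0.05, n))
  cfg <- fit_config(epsilon = 0.01)
  # matched moments are a fixed point
  expect_equal(update_step(C, emp, emp, cfg), unclass(C), ignore_attr = TRUE)
  # single-entry surplus of +0.1 moves the entry by epsilon * 0.1
  mod_fc <- fc; mod_fc[1, 2] <- mod_fc[2, 1] <- fc[1, 2] - 0.06
  mod_fs <- fs; mod_fs[1, 2] <- fs[1, 2] - 0.04
  model <- moment_pair(mod_fc, mod_fs, tau = 0.02)
  C0 <- coupling_matrix(matrix(0, n, n))
  up <- update_step(C0, emp, model, cfg)
  expect_equal(up[1, 2], 0.001)
  # a deficit pushing below zero clamps at exactly 0
  mod_fc2 <- fc; mod_fc2[1, 2] <- mod_fc2[2, 1] <- fc[1, 2] + 0.5
  model2 <- moment_pair(pmin(mod_fc2, 1), fs, tau = 0.02)
  expect_identical(update_step(C0, emp, model2, cfg)[1, 2], 0)
  # upper clamp at c_max
  big <- coupling_matrix(matrix(0.199, n, n) - diag(0.199, n))
  up2 <- update_step(big, emp, model, fit_config(epsilon = 10))
  expect_lte(max(up2), 0.2)
  # masked-out links stay fixed
  mask <- matrix(TRUE, n, n); diag(mask) <- FALSE; mask[1, 2] <- FALSE
  cfgm <- fit_config(epsilon = 0.01, mask = mask)
  expect_equal(update_step(C0, emp, model, cfgm)[1, 2], 0)
  # NaN anywhere is an error
  bad <- emp; bad$fc[1, 2] <- NaN
  expect_error(update_step(C0, bad, model, cfg), "NaN")
})

test_that("fit score is the off-diagonal Pearson correlation per moment", {
  set.seed(40)
  fc <- matrix(runif(25, -0.5, 0.5), 5, 5); fc <- (fc + t(fc)) / 2; diag(fc) <- 1
  fs <- matrix(runif(25, -0.5, 0.5), 5, 5)
  emp <- moment_pair(fc, fs, tau = 0.02)
  expect_equal(unname(fit_score(emp, emp)), c(1, 1))
  nfc <- -fc; diag(nfc) <- 1
  neg <- moment_pair(nfc, -fs, tau = 0.02)
  expect_equal(unname(fit_score(emp, neg)), c(-1, -1))
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    r1 <- matrix(rnorm(900), 30, 30); r1 <- (r1 + t(r1)) / 2
    r1 <- r1 / (max(abs(r1)) + 1); diag(r1) <- 1
    r2 <- matrix(rnorm(900), 30, 30); r2 <- (r2 + t(r2)) / 2
    r2 <- r2 / (max(abs(r2)) + 1); diag(r2) <- 1
    s1 <- matrix(rnorm(900), 30, 30) / 10
    s2 <- matrix(rnorm(900), 30, 30) / 10
    sc <- fit_score(moment_pair(r1, s1, 0.02), moment_pair(r2, s2, 0.02))
    hits <- hits + all(abs(sc) < 0.1)
  }
  expect_gte(hits, 19)
  const <- moment_pair(diag(5), matrix(0, 5, 5), tau = 0.02)
  expect_error(fit_score(const, const), "zero-variance")
})

test_that("analytic fit recovers a known sparse coupling from its own moments", {
  n <- 10
  C <- random_sparse_coupling(n, 0.2, seed = 41)
  p <- study_params(n, seed = 42)
  emp <- model_moments(p, C, 0.02)
  fit <- fit_ec(emp, p, fit_config(mode = "analytic"))
  expect_true(fit$converged)
  expect_gte(cor(offdiag_v(fit$c_hat), offdiag_v(unclass(C))), 0.95)
})

test_that("a unidirectional 2-node link is recovered with the right direction", {
  s <- two_node_chain(w = 0.05, a = -5, f = c(1, 1), G = 150)
  emp <- model_moments(s$params, s$C, 0.02)
  fit <- fit_ec(emp, s$params, fit_config(mode = "analytic"))
  expect_gte(fit$c_hat[2, 1], 3 * fit$c_hat[1, 2])
})

test_that("initialising at the true coupling converges immediately", {
  n <- 8
  C <- random_sparse_coupling(n, 0.25, seed = 43)
  p <- study_params(n, seed = 44)
  emp <- model_moments(p, C, 0.02)
  cfg <- fit_config(mode = "analytic", init = unclass(C))
  fit <- fit_ec(emp, p, cfg)
  expect_true(fit$converged)
  expect_lte(fit$n_iters, cfg$check_every * cfg$patience + 1)
  expect_lt(max(abs(fit$c_hat - C)), cfg$epsilon)
})

test_that("true asymmetry signs are recovered across seeds", {
  agree <- 0; total <- 0
  for (seed in 1:10) {
    n <- 8
    C <- random_sparse_coupling(n, 0.25, seed = 100 + seed)
    p <- study_params(n, seed = 200 + seed)
    emp <- model_moments(p, C, 0.02)
    fit <- fit_ec(emp, p, fit_config(mode = "analytic"))
    D_true <- asymmetry(unclass(C)); D_hat <- asymmetry(unclass(fit$c_hat))
    sel <- abs(D_true) >= 0.02   # clearly asymmetric links
    agree <- agree + sum(sign(D_hat[sel]) == sign(D_true[sel]))
    total <- total + sum(sel)
  }
  expect_gte(agree / total, 0.9)
})

test_that("analytic fit trajectory improves monotonically up to tolerance", {
  n <- 8
  C <- random_sparse_coupling(n, 0.25, seed = 45)
  p <- study_params(n, seed = 46)
  emp <- model_moments(p, C, 0.02)
  fit <- fit_ec(emp, p, fit_config(mode = "analytic"))
  r_fc <- fit$trajectory$r_fc
  expect_true(all(diff(r_fc) > -0.01))
})

test_that("masked links never move while free links are fitted", {
  n <- 6
  C <- random_sparse_coupling(n, 0.3, seed = 47)
  p <- study_params(n, seed = 48)
  emp <- model_moments(p, C, 0.02)
  mask <- matrix(TRUE, n, n); diag(mask) <- FALSE
  mask[1, ] <- FALSE  # freeze all inputs into node 1
  fit <- fit_ec(emp, p, fit_config(mode = "analytic", mask = mask))
  expect_true(all(fit$c_hat[1, ] == 0))
  expect_gt(max(fit$c_hat[-1, ]), 0)
})

test_that("fit results expose tidy, glance and autoplot methods", {
  n <- 5
  C <- random_sparse_coupling(n, 0.3, seed = 49)
  p <- study_params(n, seed = 50)
  fit <- fit_ec(model_moments(p, C, 0.02), p, fit_config(mode = "analytic"))
  tr <- tidy(fit)
  expect_s3_class(tr, "tbl_df")
  expect_named(tr, c("iter", "r_fc", "r_fs"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("fit validates conforming shapes", {
  p <- study_params(4, seed = 51)
  C <- random_sparse_coupling(5, 0.3, seed = 52)
  emp <- model_moments(study_params(5, seed = 53), C, 0.02)
  expect_error(fit_ec(emp, p, fit_config()), "n = 4")
})
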