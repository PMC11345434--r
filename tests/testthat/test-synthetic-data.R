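test_that("ground truth is feedforward-dominated by construction", {
  # no feedback at all: strictly one-directional between consecutive levels
  C0 <- make_ground_truth(c(3, 3), ff_strength = 0.05, fb_ratio = 0, seed = 1)
  lev <- attr(C0, "levels")
  up <- outer(lev, lev, function(i, j) i < j)  # receiver level < sender level
  expect_true(all(C0[up] == 0))
  expect_gt(sum(C0 > 0), 0)
  # with feedback: every forward entry at least its transpose entry
  C1 <- make_ground_truth(c(4, 4, 4), ff_strength = 0.05, fb_ratio = 0.3,
                          seed = 2)
  expect_true(all(C1 - t(C1) >= -1e-12 | t(C1) == 0.05))
  fwd <- which(C1 == 0.05)
  expect_true(all(t(C1)[fwd] == 0.015))
  # determinism
  expect_identical(unclass(make_ground_truth(c(4, 4), seed = 9)),
                   unclass(make_ground_truth(c(4, 4), seed = 9)))
  expect_error(make_ground_truth(c(5), seed = 1), "2 levels")
  expect_error(make_ground_truth(c(3, 3), ff_strength = 0, seed = 1),
               "ff_strength")
  expect_error(make_ground_truth(c(3, 3), fb_ratio = 1, seed = 1), "fb_ratio")
})

test_that("cohort generation is deterministic and correctly shaped", {
  C <- make_ground_truth(c(3, 3), seed = 3)
  p <- study_params(6, seed = 4, region_ids = rownames(C))
  spec <- cohort_spec(n_participants = 3, n_trials = 2,
                      samples_per_trial = 400, seed = 5)
  cohort <- generate_cohort(C, p, spec)
  expect_length(cohort, 3)
  for (ts in cohort) {
    expect_equal(dim(ts$values), c(400, 6))
    expect_equal(ts$dt, 1e-3)
  }
  cohort2 <- generate_cohort(C, p, spec)
  expect_identical(cohort[[2]]$values, cohort2[[2]]$values)
})

test_that("zero jitter gives identical generative systems across participants", {
  C <- make_ground_truth(c(3, 3), seed = 6)
  p <- study_params(6, seed = 7, region_ids = rownames(C))
  cohort <- generate_cohort(C, p, cohort_spec(n_participants = 3, n_trials = 1,
                                              samples_per_trial = 300,
                                              participant_jitter = 0, seed = 8))
  sys <- attr(cohort, "participants")
  expect_equal(sys[[1]]$params$a, sys[[2]]$params$a)
  expect_equal(sys[[1]]$params$f, sys[[3]]$params$f)
  expect_identical(unclass(sys[[1]]$C), unclass(sys[[3]]$C))
  # but the series differ (independent noise seeds)
  expect_false(identical(cohort[[1]]$values, cohort[[2]]$values))
})

test_that("trial averaging reduces the noise variance by about 1/n_trials", {
  C <- make_ground_truth(c(3, 3), seed = 10)
  p <- study_params(6, seed = 11, region_ids = rownames(C))
  v1 <- c(); v8 <- c()
  for (s in 1:4) {
    c1 <- generate_cohort(C, p, cohort_spec(n_participants = 1, n_trials = 1,
                                            samples_per_trial = 2700,
                                            participant_jitter = 0,
                                            seed = 20 + s))
    c8 <- generate_cohort(C, p, cohort_spec(n_participants = 1, n_trials = 8,
                                            samples_per_trial = 2700,
                                            participant_jitter = 0,
                                            seed = 40 + s))
    v1 <- c(v1, mean(apply(c1[[1]]$values, 2, var)))
    v8 <- c(v8, mean(apply(c8[[1]]$values, 2, var)))
  }
  ratio <- mean(v8) / mean(v1)
  expect_lt(abs(ratio - 1 / 8), 0.2 / 8)
})

test_that("two-condition cohorts share jitters and differ only in boosted links", {
  C <- make_ground_truth(c(3, 3), ff_strength = 0.05, fb_ratio = 0.3, seed = 12)
  ids <- rownames(C)
  p <- study_params(6, seed = 13, region_ids = ids)
  fwd <- which(unclass(C) == 0.05, arr.ind = TRUE)
  path_a <- cbind(from = ids[fwd[1, "col"]], to = ids[fwd[1, "row"]])
  path_b <- cbind(from = ids[fwd[2, "col"]], to = ids[fwd[2, "row"]])
  spec <- cohort_spec(n_participants = 2, n_trials = 1,
                      samples_per_trial = 300, seed = 14)
  both <- two_condition_cohort(C, p, spec, path_a, path_b, boost = 2)
  sys_a <- attr(both$condition_a, "participants")
  sys_b <- attr(both$condition_b, "participants")
  expect_equal(sys_a[[1]]$params$a, sys_b[[1]]$params$a)
  expect_equal(sys_a[[2]]$params$f, sys_b[[2]]$params$f)
  ca <- unclass(sys_a[[1]]$C); cb <- unclass(sys_b[[1]]$C)
  ia <- ca[path_a[1, "to"], path_a[1, "from"]]
  ib <- cb[path_a[1, "to"], path_a[1, "from"]]
  expect_equal(ia, 2 * ib)  # boosted in A only, same jitter factor
  ja <- ca[path_b[1, "to"], path_b[1, "from"]]
  jb <- cb[path_b[1, "to"], path_b[1, "from"]]
  expect_equal(2 * ja, jb)
  off_links <- setdiff(which(unclass(C) > 0),
                       c(which(rownames(C) %in% NA)))
  expect_error(two_condition_cohort(C, p, spec, path_a, path_a, boost = 2),
               "overlap")
  expect_error(two_condition_cohort(C, p, spec, path_a, path_b, boost = 1),
               "boost")
})

test_that("boosted pathways surface in the fitted group coupling", {
  # two conditions, one boosted forward link each; the fitted EC of the
  # boosted link is higher in its boosted condition
  C <- make_ground_truth(c(4, 4), ff_strength = 0.05, fb_ratio = 0.3, seed = 15)
  ids <- rownames(C)
  p <- study_params(8, seed = 16, region_ids = ids)
  fwd <- which(unclass(C) == 0.05, arr.ind = TRUE)
  path_a <- cbind(from = ids[fwd[1, "col"]], to = ids[fwd[1, "row"]])
  path_b <- cbind(from = ids[fwd[2, "col"]], to = ids[fwd[2, "row"]])
  spec <- cohort_spec(n_participants = 6, n_trials = 4, seed = 17)
  both <- two_condition_cohort(C, p, spec, path_a, path_b, boost = 2)
  fit_one <- function(cohort) {
    avg <- average_moments(lapply(cohort, empirical_moments, tau = 0.02))
    fit_ec(avg, p, fit_config(mode = "analytic"))$c_hat
  }
  ec_a <- fit_one(both$condition_a)
  ec_b <- fit_one(both$condition_b)
  expect_gt(ec_a[path_a[1, "to"], path_a[1, "from"]],
            ec_b[path_a[1, "to"], path_a[1, "from"]])
  expect_gt(ec_b[path_b[1, "to"], path_b[1, "from"]],
            ec_a[path_b[1, "to"], path_b[1, "from"]])
})

test_that("level contrasts resolve the hierarchy for directionality tests", {
  C <- make_ground_truth(c(3, 3, 3), seed = 18)
  ct <- level_contrast(C, 1, 2)
  expect_s3_class(ct, "directional_contrast")
  expect_length(ct$source, 3)
  expect_length(ct$target, 3)
  C_plain <- C; attr(C_plain, "levels") <- NULL
  expect_error(level_contrast(C_plain, 1, 2), "level")
})
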