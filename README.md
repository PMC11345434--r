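# hopfec

Generative effective connectivity from coupled Hopf oscillator networks.

## What this is for

Zero-lag functional connectivity (FC) between brain regions is symmetric:
it cannot say whether V3 drives the parahippocampal cortex or the other way
around. With fast parcellated recordings (e.g. MEG source time series at
1 kHz), the *time-lagged* normalised covariance
`FS_ij(tau) = corr(x_i(t + tau), x_j(t))` breaks that symmetry. `hopfec`
estimates *effective connectivity* — a directed, nonnegative coupling matrix
`C` — by fitting a generative whole-brain model so that the model's FC and
lagged FS reproduce the empirical ones.

Each region is a Stuart–Landau oscillator (Hopf normal form) with diffusive
coupling:

    dx_i/dt = (a_i - x_i^2 - y_i^2) x_i - w_i y_i + G * sum_j C_ij (x_j - x_i) + beta eta_i(t)
    dy_i/dt = (a_i - x_i^2 - y_i^2) y_i + w_i x_i + G * sum_j C_ij (y_j - y_i) + beta eta_i(t)

`C[i, j]` is the input region `i` receives from region `j` (the link
`j -> i`). The fit runs in two modes: an **analytic** mode, where the model
FC/FS come in closed form from the linearised system (Lyapunov stationary
covariance and a matrix-exponential lag), and a **simulation** mode, where
they are measured from seeded simulations of the current model. Both modes
optimise the same moment residuals with damped Gauss–Newton steps, an
analytic moment Jacobian, and a nonnegativity clamp that prunes unhelpful
couplings at zero.

Around the fit, the package provides the standard downstream analyses for
this kind of study: per-participant and group moment matrices, symmetrised
mean and directional-asymmetry views, display and density-matched
thresholds, right-minus-left laterality differences over homologous region
pairs, preplanned directional contrasts tested with paired t-tests across
participants, a packaged 30-region visual/medial-temporal atlas table, and a
synthetic multi-participant cohort generator with known directed ground
truth so the whole chain is testable end to end.

## Worked example

Simulate a small two-level hierarchy with known directed coupling, measure
its moments, and recover the coupling with the analytic fit:

```r
library(hopfec)

c_true <- make_ground_truth(level_sizes = c(3, 3), ff_strength = 0.05,
                            fb_ratio = 0.3, seed = 1)
set.seed(2)
params <- oscillator_params(a = -5, f = runif(6, 0.5, 2), G = 150,
                            beta = 0.02, region_ids = rownames(c_true))

ts  <- simulate_hopf(params, c_true,
                     sim_config(n_steps = 202000, burn_in = 2000, seed = 3))
emp <- empirical_moments(ts, tau = 0.02)
fit <- fit_ec(emp, params, fit_config(mode = "analytic"))
fit
#> <hopf_ec_fit> 6 nodes, 50 iterations (analytic mode), converged
#>   final r_fc = 0.9999, r_fs = 0.9997

off <- function(m) m[row(m) != col(m)]
cor(off(fit$c_hat), off(unclass(c_true)))
#> [1] 0.9927
round(fit$c_hat["n04", "n01"], 3); round(fit$c_hat["n01", "n04"], 3)
#> [1] 0.047
#> [1] 0.011
```

The fitted matrix reproduces the empirical moments almost perfectly
(`r_fc`, `r_fs`), correlates at 0.99 with the generating coupling, and
recovers the directed asymmetry: the feedforward link `n01 -> n04` (truth
0.05) comes back several times its feedback counterpart (truth 0.015).

Per-participant fits feed the directional statistics:

```r
cohort <- generate_cohort(c_true, params, cohort_spec(n_participants = 21, seed = 4))
ecs <- lapply(cohort, function(ts)
  fit_ec(empirical_moments(ts, 0.02), params, fit_config(mode = "analytic"))$c_hat)
fb <- vapply(ecs, pooled_directional_ec, numeric(2),
             contrast = level_contrast(c_true, 1, 2))
paired_directionality_test(fb["forward", ], fb["backward", ])
#> <contrast_result>
#>   t = 4.588, p = 0.0001783 (two-tailed, uncorrected), df = 20, mean diff = 0.01309
```

A cohort whose ground truth sends information level 1 → level 2 yields a
strongly positive paired t across 21 participants, with df = 20.

`run_pipeline()` chains the full workflow (cohort → frequencies → moments →
group and per-participant fits → thresholded matrix views → laterality →
the six preplanned visual-stream contrasts) and writes TSV/YAML artifacts
plus a manifest to an output directory.

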