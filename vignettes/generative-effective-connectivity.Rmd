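---
title: "Generative effective connectivity with coupled Hopf oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative effective connectivity with coupled Hopf oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopfec)
```

## The problem

Functional connectivity (FC) — the zero-lag Pearson correlation between two
regions' time series — is symmetric and says nothing about the direction of
interaction. For fast recordings (parcellated MEG source series sampled at
1 kHz, for example) directional information is carried by the *time-lagged*
normalised covariance: if region $j$ drives region $i$, then $x_i$ shifted
later by a lag $\tau$ correlates more strongly with $x_j$ than the reverse.
`hopfec` turns that asymmetry into an estimate of *effective connectivity*
(EC): the directed coupling matrix of a generative whole-brain model is
optimised until the model reproduces both the empirical FC and the empirical
lagged covariance. The coupling matrix that achieves this is the generative
effective connectivity.

## The model

Each region $i$ is a Stuart–Landau oscillator — the normal form of a
supercritical Hopf bifurcation — coupled diffusively to the rest of the
network:

$$
\dot x_i = (a_i - x_i^2 - y_i^2)\,x_i - \omega_i y_i
  + G \sum_j C_{ij}\,(x_j - x_i) + \beta\,\eta_i(t)
$$
$$
\dot y_i = (a_i - x_i^2 - y_i^2)\,y_i + \omega_i x_i
  + G \sum_j C_{ij}\,(y_j - y_i) + \beta\,\eta_i(t)
$$

* $a_i$ (1/s) is the bifurcation parameter: for $a_i > 0$ the isolated node
  has a stable limit cycle of radius $\sqrt{a_i}$ and frequency
  $f_i = \omega_i / 2\pi$; for $a_i < 0$ it has a stable fixed point and the
  dynamics is a noisy decaying oscillation. All fitting is done at a
  subcritical working point.
* $\omega_i$ (rad/s) is the intrinsic angular velocity. The frequencies are
  estimated from data as the narrowband spectral peak per region
  (`estimate_intrinsic_frequencies()`, default band 0.5–2 Hz).
* $G$ is a global gain on the total coupling input of every region.
* $\beta$ is the standard deviation of the additive Gaussian noise, applied
  independently to every scalar component of both equations.
* $C_{ij} \ge 0$ is the directed coupling: the input region $i$ receives
  from region $j$. All matrices in the package use this
  receiver-row/sender-column orientation, so the figure convention
  "column to row" is sender $\to$ receiver.

Only $x_i$ is read out; $y_i$ is internal phase-space machinery.

## Empirical and model moments

`empirical_moments()` computes, per participant:

* `fc`: Pearson correlation of all region pairs;
* `fs`: the lagged normalised covariance
  $\mathrm{fs}_{ij} = \mathrm{corr}(x_i(t+\tau), x_j(t))$, computed over the
  overlapping window without wrap-around, with columns demeaned over the full
  series and normalised by the static (lag-0) standard deviations. It reduces
  to the FC at $\tau \to 0$, stays in $[-1, 1]$, and its asymmetry is the
  directional signal. The default lag is $\tau = 20$ ms, of the order of one
  or two synaptic stages in a cortical hierarchy; a lag must be a positive
  integer multiple of the sampling interval.

Cross-participant analysis averages the per-participant matrices
(`average_moments()`); `split_half_reliability()` checks stability of
per-participant EC by correlating half-cohort means.

The *analytic* model moments come from linearising the network at the origin
(valid at the subcritical working point). The Jacobian has the block form
$A = \begin{pmatrix} K & -\Omega \\ \Omega & K \end{pmatrix}$ with
$K = G\,C + \mathrm{diag}(a_i - G \sum_j C_{ij})$, and the stationary
covariance solves the Lyapunov equation $A\Sigma + \Sigma A^\top + \beta^2 I
= 0$; the lagged covariance is $e^{A\tau}\Sigma$. Both are evaluated in the
eigenbasis of $A$ (a diagonal solve after two similarity transforms), which
also yields, at negligible extra cost per entry, the exact Jacobian of every
model moment with respect to every coupling entry — rank-2 perturbation
formulas for the Lyapunov solution and divided differences for the matrix
exponential. A stability margin (largest real part $\le -10^{-6}$) is
enforced before any solve; with nonnegative couplings and diffusive coupling
the linearised system is always stable (Gershgorin), so instability can only
arise from a misconfigured working point.

## Fitting the coupling matrix

The fit minimises the squared distance between the model's and the empirical
off-diagonal FC and FS entries. The elementary update — move each coupling
entry along the sum of its FC and FS residuals and clamp to $[0, c_\max]$ —
is exposed as `update_step()` and has the right fixed point (matched
moments), but iterating it raw does not converge in realistic regimes: the
moment map's Jacobian is strongly non-normal and has eigenvalues with
negative real part, so the residual iteration diverges along those
directions for *any* step size, and its condition number is of order $10^4$.
`fit_ec()` therefore takes damped Gauss–Newton (Levenberg–Marquardt) steps
on the same residuals:

* the analytic moment Jacobian is computed in compiled code and refreshed
  every few accepted steps;
* entries pinned at the zero bound whose gradient points further negative
  form an active set and are excluded from the step, so the nonnegativity
  clamp — which is what prunes couplings that do not help generate the
  moments — does not distort the direction of the remaining entries;
* the damping is relative to the mean curvature (invariant to the scale of
  $G$), shrinks toward pure Gauss–Newton on accepted steps, and a short line
  search handles the residual nonlinearity;
* analytic-mode convergence is declared on relative residual improvement:
  the Pearson fit scores saturate at 1 well before the ill-conditioned tail
  of $C$ has converged, so they are reported in the trajectory but not used
  to stop the fit.

On analytic moments of a known sparse network this recovers the generating
coupling essentially exactly (off-diagonal correlation indistinguishable
from 1 at $N = 10$–20), including every direction of asymmetric pairs.

### Simulation mode

The simulation variant measures the model moments by actually simulating
the current model and applying the same empirical estimators as for data.
Each objective evaluation integrates one continuous seeded trajectory of
four `sim_length` (200-s) segments; `max_iters` counts segments, making the
computational budget explicit. Three design points carry the weight:

* the seed is held *fixed* across the fit (a sample-average approximation),
  so the surrogate objective is deterministic and the same adaptive
  Levenberg–Marquardt machinery as in analytic mode — acceptance tests,
  line search, damping adaptation — applies without being fooled by noise.
  With fresh noise per evaluation the stochastic iteration provably settles
  far from the optimum at any damping level;
* the fit starts from zeros, like the analytic mode. Starting instead from
  the endpoint of a stochastic warm-up traps the optimiser in spurious
  basins shaped by the warm-up noise — the from-zero start discovers the
  supported couplings greedily, which is what makes sparse recovery work;
* the correlation estimator on a finite window is biased, with bias
  proportional to $1/T$. The empirical target carries the bias of its own
  window length; if the simulation side measured moments on independent
  200-s windows it would carry a *different* bias, and the ill-conditioned
  inversion amplifies that mismatch into a large coupling displacement.
  Pooling the segments into one long trajectory makes the simulation-side
  measurement effectively unbiased, so both fitting routes answer the same
  question. Initialised at the analytic solution, the simulation-mode
  objective keeps it there — the two routes share their optimum and differ
  only in how the moments are measured.

## The synthetic cohort generator

`make_ground_truth()` builds a directed hierarchical network: sampled links
from level $k$ to $k+1$ at `ff_strength`, reverse links scaled by
`fb_ratio` $< 1$, optional within-level links. Every node is guaranteed at
least one in-link (with feedback enabled) — a region with no input would sit
at its bare local decay rate, dynamically unlike any cortical region, and
its moments would be unestimable on realistic windows.

`generate_cohort()` emulates a multi-participant evoked-series study:
per participant, $a$, $f$ and the nonzero couplings are jittered with
mean-one lognormal factors (default relative SD 0.1 — multiplicative so that
signs, zeros and stability margins are preserved), `n_trials` independent
noisy runs of 2700 samples at 1 kHz are simulated and averaged into one
evoked-style series, and all randomness derives from `(seed, participant)`.
Defaults follow the emulated study design: 21 participants, 8 trial blocks,
2700-point series at 1 ms. `two_condition_cohort()` produces two cohorts
sharing all jitters and noise that differ only in a multiplicative boost of
named sub-pathways, emulating a two-condition (e.g. scenes-vs-faces) design
at the network level.

What the generator does *not* emulate: stimulus-locked deterministic
response components (the EC method consumes only second-order moments, and
trial averaging of independent noisy runs reproduces the moment structure of
an evoked series without them), sensor physics, source leakage, or
non-Gaussian physiological variability. Passing tests on these cohorts show
that the estimator chain recovers known directed structure under honest
noise and inter-individual variability — not that it is robust to leakage or
preprocessing artifacts of real recordings.

## The study working point

Where values are prescribed by the emulated study they are used as given:
2700-sample evoked series at 1 kHz, 21 participants, lag $\tau = 20$ ms,
intrinsic frequencies in the 0.5–2 Hz band, noise $\beta = 0.02$. The
bifurcation parameter and the global gain are not reported quantities, so
the package fixes one canonical working point for its synthetic experiments
and documents the reasoning:

* $a_i = -5\ \mathrm{s^{-1}}$, $G = 150$ with hierarchy couplings of order
  0.05 gives every region a total input of order $10\ \mathrm{s^{-1}}$ and
  integration timescales of tens of milliseconds — the timescale regime of
  cortical population dynamics, and fast enough that second-order moments
  are estimable inside a 2.7-s evoked window;
* at a near-critical slow working point (for instance $a_i = -0.02$ with
  weak total coupling) regional correlation times reach tens of seconds.
  Moments measured on 2.7-s windows are then dominated by sampling noise and
  *no* estimator can recover the coupling — a property of the window length,
  not of the algorithm. The cross-method comparison in the acceptance script
  keeps $a_i = -0.02$ (its prescribed setting) and relies on the strong
  coupling for fast mixing.

## Numerical choices

* Integration: stochastic Heun (predictor–corrector drift, additive noise
  once per step), default $dt = 1$ ms. Plain explicit Euler inflates the
  limit-cycle radius by $\omega^2 dt / 2$ — a 4% bias at 1 Hz — while the
  Heun radius bias is $O(dt^3)$.
* Noise generation: an internal `mt19937_64` with an explicit Box–Muller
  transform, seeded from R's RNG, so `set.seed()` fixes trajectories exactly
  and the stream is identical across platforms.
* Burn-in: 2 s by default; initial state $\mathcal N(0, 0.1^2)$ per
  component; overflow guard at $|{\rm state}| > 10^6$ with advice to reduce
  $dt$ or use a subcritical working point.
* Spectral estimation: Welch averaged periodogram, 4-s Hann segments, 50%
  overlap; the intrinsic-frequency peak search is restricted to the analysis
  band, the zero-phase equivalent of narrowband filtering at band edges far
  below Nyquist.
* Display thresholds: values strictly below a threshold are blanked; ties
  are kept. The density-matched threshold returns the smallest value whose
  kept fraction does not exceed the target, so it is monotone in the target
  density.
* Tests and the acceptance checks run at desk scale: networks of 2–20 nodes
  (36 for the end-to-end pipeline demo), cohorts of up to 21 participants,
  500-s stationary runs for moment validation.

## Directional statistics

`pooled_directional_ec()` pools a contrast's forward coupling as the
unweighted mean of `ec[target, source]` over all ordered pairs (averaging
homologous within-hemisphere pools when matrices are hemisphere-labelled),
and `paired_directionality_test()` applies a two-tailed paired t-test across
participants ($df = n - 1$; 20 at the 21-participant design). P values are
reported uncorrected and flagged as such — the intended use is a handful of
preplanned contrasts, e.g. the six shipped in `preplanned_contrasts()`
covering the ventromedial scene stream (early visual regions to the
prostriate/retrosplenial scene region, to the ventromedial visual regions,
to the medial parahippocampal regions, to the hippocampus) and the
ventrolateral face/object stream (fusiform/posterior-inferior-temporal
regions to inferior temporal TE2p and anterior temporal TE2a).

## Known limitations

* The inverse problem is ill-conditioned: entries between regions with
  weakly overlapping spectra are weakly identified, and noise in the moment
  matrices maps into large coupling uncertainty there. Group averaging and
  the sparsity-inducing zero clamp mitigate but do not remove this.
* The analytic route describes the linearised model; very close to the
  bifurcation, amplitude nonlinearity biases weakly damped nodes.
* Fits assume a known, common $(a, G, \beta)$ configuration; only the
  coupling matrix is estimated. Frequencies come from the data but are not
  refined inside the loop.
* The six preplanned contrasts are fixed region sets; the packaged region
  table covers the 30-region visual/medial-temporal selection (both
  hemispheres) with the full atlas loadable from a user TSV.
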