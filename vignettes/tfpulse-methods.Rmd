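---
title: "Models and methods behind tfpulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tfpulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tfpulse` implements the analysis machinery for a head-fixed visual
change-detection task: a drifting grating whose temporal frequency (TF) is
redrawn every 50 ms from a lognormal distribution (log2 TF with mean 0 and
s.d. 0.25 octaves, geometric mean 1 Hz), with sustained TF increases
("change epochs", 2.15 s, magnitudes 1.25-4 Hz) that the animal reports by
licking. Licks during the baseline period ("early licks") are the window
into how sensory evidence is, or is not, integrated over time. This
vignette explains each model, the numerical choices behind it, and what
the synthetic generators do and do not emulate.

## The stimulus and trial generators

`sample_baseline_tf()` draws i.i.d. normal log2-TF pulses;
`assign_trial_structure()` draws change onsets as the start of the block
window (early [3, 8] s, late [10.5, 15.5] s) plus an exponential delay
with mean 4 s truncated to the window, marks 15% of trials no-change and
10% probe; `simulate_stimulus_sessions()` assembles per-trial pulse
streams. Two deliberate choices:

* **Change onsets are snapped up to the 50-ms pulse grid.** The TF stream
  is resampled once per pulse, so a sustained change can only begin on a
  pulse boundary. Storing a continuous onset would introduce a 0-50 ms
  gap between the nominal and the physical change time that corrupts
  reaction-time-based delay fitting.
* **The change epoch keeps the baseline noise s.d.** (0.25 octaves around
  the shifted log2 mean); the task description does not state a separate
  change-epoch noise level and reusing the baseline value is the simplest
  consistent choice.

Pulses are classified `fast` above +1 s.d. (TF > 2^0.25 = 1.19 Hz),
`slow` below -1 s.d. (0.84 Hz), and `near_mean` within 0.5 s.d. (the
reference class used for baseline-response subtraction). The
untrained-animal reward schedule draws inter-reward intervals uniformly
on 60 +/- 15 s.

## The outlier-detection agent

The agent is the null model against which behavioural integration is
tested: at each 60-Hz video frame a noisy sensory sample
`Z_i = s_i + eps_i`, `eps_i ~ N(0, sigma^2)`, is compared with a bound
`b`; the decision time `D` is the first crossing (or infinity), the
per-frame survivor is `Phi((b - s_i)/sigma)`, and the response (movement
onset) is `R = D + Delta` with a shifted log-logistic delay
(location `alpha > 0`, scale `beta`, shape `gamma > 1`). All probability
arithmetic is in log space (`pnorm(log.p = TRUE)`, log-sum-exp), which
keeps bounds of up to ~10 s.d. finite.

Fitting is two-stage, as the model prescribes: the delay distribution is
fit by constrained maximum likelihood (L-BFGS-B on box constraints, ten
random starts) to reaction times on largest-change hit trials, where the
decision can be assumed to happen at the change point; then the decision
parameters `(sigma^2, b)` are fit by maximising the marginal likelihood
with the delay fixed, with miss trials entering as right-censored
observations. The decision optimiser is a coarse log-sigma x bound grid
(7 x 7) followed by Nelder-Mead refinement; neither stage is sensitive to
the starting point in our recovery checks.

One guard matters in practice: a rare pre-change bound crossing whose
lick happens to land inside the change epoch is classified a "hit" with a
near-zero reaction time, and a single such observation pins the
log-logistic location at ~0. `bigchange_hit_rts()` therefore excludes
reaction times at or below one video frame -- physically impossible for a
post-change decision, whose earliest expression is the first change
frame. The `alpha` estimate retains a +1/60 s bias (one frame) by
construction of the discrete decision grid; at the default study
conditions this is ~7% of `alpha`.

`sample_agent_datasets()` reuses each trial's stimulus (refilling
never-shown post-lick values from the baseline distribution), samples
crossings and delays, adds movement-to-lick delays resampled from a
measured pool, and classifies hit / early / miss from the lick against
the change epoch; dataset `k` derives its own sub-seed and is
individually reproducible.

## Movement-onset estimation

Orofacial movement onsets are dated from the motion-energy trace: the
values in a 2-s window centred on each lick are fitted with a
3-component univariate Gaussian mixture (plain EM with k-means
initialisation and a variance floor; `fit_gmm1d()`), the movement
threshold is `mu + 2 sd` of the lowest-mean component (the noise
floor), and the onset is the sample following the last sub-threshold
sample before the lick. A lick is flagged undefined when no burst is in
progress at the lick itself (energy below threshold there) or the trace
never drops below threshold in the window; degenerate windows fall back
to a median + 2 MAD floor.

## The leaky integrator

`leaky_integrate()` accumulates `y_i = y_{i-1} exp(-dt/tau) + s_i dt` on
the 50-ms pulse clock, so thresholds are in octave-seconds. The `dt`
factor is a deliberate reading: the printed threshold grid
([0.01, 0.16], 151 linear steps) is only dimensionally consistent with
integration of `log2 TF x dt` -- without it the stationary trace s.d. at
the shortest decay time already exceeds half the grid. Integrating raw
log2 TF rather than its deviation from the mean is equivalent at
baseline, where the mean is 0. The fit scans the full 58-decay-time
(50 log-spaced values over 0.05-3 s plus 4, 5, 6, 7, 8, 9, 20, 1000 s) x
151-threshold grid, scoring an early lick as predicted when the
integrated trace reaches the threshold within the second preceding the
lick; ties break toward the smaller decay time, then the smaller
threshold, making the argmax deterministic. Reaction-time prediction on
hit trials takes the first post-change crossing; correlations are
computed per change size and, pooled, on within-size z-scores.

## Pulse-probability statistics and the facilitation index

The single-pulse analysis bins baseline pulses into 15 equal-count
magnitude bins and estimates, per bin, the probability that a pulse is
followed by a counted early lick at a lag of 0.2-1 s. Two estimator
choices deserve comment, both validated against an exactly independent
(union-hazard) lick generator:

* **Per-pulse conditionals, not per-lick counts.** Counting pulse
  occurrences per lick gives quantities whose chance level scales with
  the class occupancy, and the two-pulse independence formula
  `P_Ind = P0 + dP1 + dP2 - dP1 dP2` is then incoherent between the pair
  term and the single-pulse terms. Conditioning on the pulse makes every
  term a probability with a common chance level. Eligibility requires the
  success window to open inside the countable lick span (after the 2-s
  impulsive-lick exclusion) and before the trial's end; without this,
  base and delay-shifted windows are diluted unequally and the
  facilitation index drifts negative with delay.
* **Marginal reference level.** The lick hazard is convex in log2 TF, so
  the mean-TF (central-bin) reference underestimates the marginal chance
  level, inflating the independent prediction by the difference. The
  facilitation index therefore uses the marginal (all-pulse) success
  probability of the matching window as its reference; the central-bin
  `P0` is still reported. On the independent generator this brings the
  index to zero within sampling error at every delay.

The facilitation index `I = (P_obs - P_Ind)/P_Ind` is bootstrapped by
resampling trials (multinomial weights over per-trial count rows). At
the package's study conditions the outlier agent's CIs contain zero at
all delays while a tau = 0.25 s integrator shows `I > 0` at delays up to
0.25 s, decaying beyond -- the qualitative dichotomy the analysis is
designed to expose.

The lick-triggered stimulus average reports the arithmetic mean TF in Hz
at 50-ms lags over the 1.5 s preceding early licks (flat at
`exp((0.25 ln 2)^2/2) = 1.015` Hz for stimulus-independent licks) with an
exponential decay fitted to the elevation above that mean (offset fixed,
multi-start nonlinear least squares).

## The encoding GLM

`build_design()` unfolds 19 predictor groups in 50-ms steps with the
standard windows (TF 0-1.5 s; trial start 0-1 s; a single time-since-
baseline ramp column rising linearly from 1 s after trial start to the
change onset; six change-size kernels 0-2 s -- five task magnitudes plus
a catch-all for off-menu sizes; lick preparation -1.25-0 s; execution
0-0.5 s; air-puff 0-0.25 s; reward 0-0.4 s; abort -1.25-0.25 s; 12-bin
grating phase for each drift direction, advanced by the integrated
instantaneous TF; motion energy and wheel -0.05-0.8 s; pupil
-0.75-0.75 s). Continuous signals are z-scored per session before
unfolding; shifts never cross trial boundaries.

`fit_poisson_ridge()` fits a Poisson ridge regression (glmnet, alpha = 0,
cyclical coordinate descent) with 10 outer folds assigned by trial and
the penalty tuned per outer fold by inner 10-fold cross-validation over
20 log-spaced lambdas (1e-3 to 1e3); held-out predictions are assembled
across folds. Classification of TF-responsive / preparation / execution
units uses two joint criteria per flag: the mean across folds of the
Pearson correlation between the full model's held-out prediction and the
actual event-aligned PETH (fast-minus-slow pulse response for TF) must
exceed 0.2, and a one-sided t-test across the 10 folds of the
correlation between the actual PETH and the residual prediction (full
minus reduced) must reach P < 0.01. The reduced models drop,
respectively, the TF group; the preparation group; and execution +
motion + wheel. On labelled synthetic populations the joint criteria
reach sensitivity above 0.8 at a false-positive rate below 5%.

Kernel summaries: the peak is the largest absolute weight within 1 s
(sign-flipped if negative) and FWHM is interpolated linearly at half
peak; change-kernel rise times average the 33.33rd/50th/66.66th
percentile-of-maximum crossings and are regressed on log2 change size
with unit-level bootstrap CIs; the focality index is
`F = sum(p_a^2)/(sum p_a)^2`.

## Model-free unit metrics

Pulse events must fall at least 1 s after baseline onset, more than
2 s + window before the movement onset on early-lick/abort trials, and
outside the change period plus window. Pulse PETHs subtract the
near-mean-pulse response, which removes slow ramps from the pulse shape.
Two-pulse facilitation of the neural response reads the pair response at
the single-pulse peak latency after the second pulse (peak within a
100-ms window centred there), with per-unit sign flipping for suppressed
units and a 2,000-rep unit bootstrap. Preparatory fractions threshold
|z| at 2.576 (z-scored against the 2 s before the reference event),
subtract the [-2, -1.8] s baseline level, and date activation latencies
by the earliest point whose following 100-ms window keeps the lower CI
above zero and the mean fraction above 0.1 (0.05 for the all-unit
variant) for at least 80 ms. Intrinsic timescales fit
`A exp(-lag/tau) + B` to the lag 1-20 (50-ms bins, 1 s) spike-count
autocorrelation of inter-trial windows, offsetting the fit start by up
to 3 bins when the autocorrelation rises initially; non-decaying units
are flagged rather than fitted. The quality filter applies the seven
printed criteria; rolling windows advance in 1-min steps with truncated
edges, and refractory contamination is estimated as sub-2-ms ISI
violations relative to the expectation for a Poisson train at the unit's
mean rate (a documented stand-in for the sorter's statistic).

## Movement and movement-null subspaces

Rate matrices (10-ms bins, 30-ms Gaussian smoothing, trial-averaged) are
soft-normalised `r/(7 + range(r))`, centred per unit and then per time
point, and reduced by SVD to 4 components for a target region and 2 for
the orofacial reference (motor/premotor nuclei standing in for the
muscles). Projections are initial-state-zeroed over [-2, -1.5] s before
lick. The movement mapping `M = W N` is ordinary least squares on the
[-0.1, 1.5] s window; fits with R-squared below 0.8 are flagged for
exclusion. `W_null` spans the null space of `W` (from the SVD of `W'`),
scaled to equal Frobenius norm -- "norm" is read as Frobenius where
unqualified -- and rotated in closed form (the 2-D variance-maximising
angle from the pre-lick covariance, verified against a 0.1-degree grid
search in the tests). Sign conventions follow the stated windows.
Occupancy is `O_R = (E_null - E_m)/(E_null + E_m)` with Euclidean
distances from the initial state; it is undefined where both distances
vanish.

The contribution decomposition zeroes the complement's loadings, so the
split projections are exactly additive. The printed contribution formula
ends in a factor written as a vector divided by its modulus, which has
no scalar reading; we implement the projection ratio
`w(t) = <x_flag(t), x(t)>/||x(t)||^2`, which makes flagged and
complement contributions sum to exactly 1 wherever the projection is
nonzero (the invariant the decomposition is meant to satisfy). Chance
levels come from 2,000 random same-size subsets. Pulse-response
alignment projects a pulse-response matrix with the hit-lick loadings
and takes cosines at the time of maximal 4-D distance within 0.75 s.
Cross-validation splits trials in half (odd trial to the fit half), fits
subspaces on one half, projects the other, aligns eigenvector signs to
the full-data solution, and reports 2.5/97.5 percentile bands over 2,000
repetitions.

Soft-normalisation is applied after smoothing (rates are smoothed, then
normalised); the ordering is not fully specified by the procedure text
and this is the conventional order of operations.

## Synthetic populations: what they emulate, and what they do not

`simulate_population()` draws inhomogeneous-Poisson spikes by exact
thinning against a 1-ms rate lattice; log-rate adds a boxcar TF-kernel
drive, a linear pre-lick ramp, a post-lick execution response, and an
exactly discretised (AR(1)) Ornstein-Uhlenbeck fluctuation restarted at
stationarity each trial. The orofacial reference mixes two shared
post-lick motifs with heterogeneous weights, giving the
population about two dominant components. Ground truth is stored with
the units, so tests never re-derive it.

These generators reproduce the statistical structure the analyses key on
-- kernels, ramps, timescales, shared motifs, lick-locked movement bursts
-- but not several properties of real recordings: no correlated noise
beyond the shared modes, no bursting or refractoriness, no
non-Poisson dispersion, no drift or unit loss, and behaviour generated
by exactly one of the two candidate strategies rather than a mixture.
Passing tests therefore demonstrate that each analysis recovers what it
is designed to recover under its own assumptions, not that those
assumptions hold in any particular dataset.

## Problem sizes and determinism

The validation suite uses study conditions chosen once: 12,000 trials
for the facilitation contrast (agent bound 1.2 octaves, delay location
0.1 s, scale 0.15 s, shape 3; integrator tau 0.25 s, threshold 0.07
octave-seconds), 5,000 trials for two-stage agent recovery (sigma 0.25
octaves, bound 1.6 octaves, delay 0.25/0.08/3.5 -- a bound high enough
that spurious pre-change "hits" are negligible), 800 trials for the
integrator grid fit, 50-trial sessions with 30 units for the GLM
classification check, and 550 pre-trial windows for the
intrinsic-timescale recovery. Every stochastic step takes an explicit
seed, and same-seed runs are bit-identical; bootstrap sizes follow the
analysis definitions (4,000 / 2,000 / 5,000 / 10,000) except where a
test only needs the estimator's location, where smaller counts are used
and stated inline.
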