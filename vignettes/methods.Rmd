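---
title: "Models and methods behind popdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popdyn analyses neural population activity recorded (or simulated) while a
subject makes perceptual decisions with variable reaction times (RT). The
central scientific question it serves is whether the *initial condition* —
the population state just before the stimulus — shapes the speed of the
subsequent decision dynamics. This vignette explains the models the package
implements, the choices made where the methods literature leaves options
open, and what the simulator does and does not emulate.

## The session model

A session couples a trial table (signed coherence, choice, correctness, RT,
event times, previous outcome) with per-unit, per-trial spike times. Units
are classified as single neurons when at most 1.5% of their inter-spike
intervals violate a 1.5 ms refractory period, otherwise as multi-units;
both enter population analyses.

RT-conditioned analyses use eleven overlapping bins — ten 100 ms windows
stepped by 25 ms from 300–400 ms up to 525–625 ms, plus a 600–1000 ms
catch-all. The published description lists the first bins and the last and
states that there are eleven levels; the stepped construction here is the
only one consistent with both. Non-overlapping mode defaults to tertiles of
the 300–1000 ms range (the published non-overlapping edges are not given);
the number of bins is configurable. Trials with RTs outside 300–1000 ms are
excluded from RT-binned analyses.

## The synthetic population

`simulate_session()` builds populations of 200 *increased*, 100 *decreased*
and 50 *perimovement* units over 600 trials (300 per choice), with
RT drawn as `200 + 100 * Gamma(shape 5, scale 0.5)` ms. Each increased unit
combines:

* a baseline of 5 spikes/s;
* a choice-selective gain, `5 + 7 U(0,1)` added on preferred-choice trials
  or `2 + U(0,1)` subtracted otherwise, multiplied by the ramp
  `max((t - t_lag)/RT, 0)` with `t_lag = t_latency + 0.2 RT`
  (`t_latency` = 100 ms);
* a condition-independent ramp `max(15 (t - t_lag), 0)` with time in
  seconds.

Decreased units are a matched increased profile minus 10 spikes/s, clipped
at zero. Perimovement units are specified only loosely — a transient
response around movement onset — so here they are a Gaussian bump
(amplitude 20 spikes/s, sigma 50 ms) centred on movement onset with a
per-unit lead/lag drawn uniformly from ±100 ms — all three parameters are
configurable. Slopes and the RT divisor are interpreted with time in
seconds; a milliseconds reading would produce physiologically absurd
(~0 spikes/s) modulations.

The three hypotheses differ only before the cue. Simulation 1 adds nothing.
Simulation 2 adds a per-trial bias, uniform on 0–4 spikes/s for one choice
and 0–2 for the other. Simulation 3 gives 20% of units a zero baseline and
the prestimulus rate `(2 + b)/RT` (RT in seconds, `b ~ U(0,3)` per unit).
The flagged units are the first `round(0.2 * n_units)` units of the
increased class: the decreased class is excluded because its profiles are
derived by subtraction (a flag there would be annihilated by the −10
clip), and a deterministic assignment makes the flagged fraction exact.
Decreased units are paired with the tail of the increased class so pairing
never touches a flagged unit under the defaults.

Per-trial uniform gains are redrawn every trial and unit; `b` is drawn once
per unit. Rates are evaluated on a 1 ms grid, held constant from movement
onset for a further 100 ms, and spikes are drawn as an inhomogeneous
Poisson process: by the time-rescaling theorem the count is Poisson with
mean equal to the integrated rate and the rescaled spike times are uniform
order statistics, which is how the draw is implemented; the tests verify
that rescaled inter-spike intervals pass a Kolmogorov–Smirnov test against
Exp(1). Trial coherences are drawn from seven log-spaced levels between 4%
and 90% (no canonical level set exists for simulated data), and correctness follows a
Weibull psychometric function with threshold 10.89% and slope 1.26.

What the simulator does *not* emulate: sensory-evidence dependence of RT
(RT and coherence are independent by construction, so chronometric
regressions on simulated data are a null check, not a realism check),
noise correlations between units, non-Poisson spiking statistics, and
change-of-mind trials. Passing tests on simulated sessions therefore
demonstrate the correctness and calibration of the pipeline, not that real
recordings would show a particular effect.

One consequence worth flagging: simulated prestimulus rates are constant
within a trial, so trial-averaged prestimulus trajectories are essentially
static and the measured state-space "speed" before the cue reflects
sampling noise (it is larger in RT bins with fewer trials). The scalar
speed operation is therefore validated against exact geometric oracles,
not against a planted prestimulus speed ordering.

## Firing rates and the movement mask

Spikes are binned at 1 ms aligned to checkerboard or movement onset and
convolved with a Gaussian kernel (sigma 30 ms by default; 15 ms Gaussian
and 50 ms causal boxcar are available as robustness options). For
checkerboard alignment, all spikes from 50 ms before movement onset to the
end of the trial are removed first, so movement-related firing cannot
masquerade as stimulus-period ramping. Because masking leaves gaps, both
the counts and a validity mask are smoothed and the rate is their ratio
(occupancy normalization); this is a design choice —
it keeps mask edges from biasing rates downward, and makes window edges
unbiased as well. Condition averages are computed the same way with
trial-summed counts and occupancy.

Each condition cell's usable window runs from −400 ms to its median RT
minus 25 ms (coherence and outcome conditionings) or its RT-bin lower bound
minus 25 ms (RT conditioning); the 25 ms guard keeps smoothed rates clear
of the mask boundary.

## PCA, soft normalization, and how many dimensions are signal

Condition-averaged rates are stacked (all left-choice cells above all
right-choice cells), each unit is mean-centred and divided by the square
root of its 99th-percentile rate. Note that this normalizer is *not* scale
invariant — multiplying a unit's rates by a² scales its normalized column
by a — it only compresses the influence of high-rate units. Silent units
are left unscaled and contribute zeros. PCA loading signs are fixed so
each component's largest-magnitude element is positive.

Trial averages mix signal with averaged noise. To decide how many leading
components are signal, differences between random disjoint trial pairs are
used as noise probes: the signal cancels in a difference and, scaled by
`1/sqrt(2M)` with M the number of pairs, the probe's variance sits at twice
the variance of the noise left in the trial average — a deliberately
conservative floor. The pair differences are averaged per condition (and
rescaled to keep that floor) so the noise matrix has exactly the shape of
the signal matrix; without this the two eigenvalue spectra have different
sampling spread and the comparison is meaningless. The estimated
dimensionality is the last component before the signal+noise eigenvalue
first falls at least 3 bootstrap-SEMs below the matched noise eigenvalue.
On planted data the estimator recovers a rank-4 signal exactly across 20
seeds when the stacked matrix has several times more rows than columns and
the per-dimension signal variance is a few times the noise floor
(tests use 300 rows x 20 units, signal-to-noise 3); with square-ish
matrices the spectra's sampling spread swamps the factor-2 separation and
the estimate degrades — a known limitation. Because the floor is
conservative, errors are one-sided: weak dimensions between one and two
times the averaged-noise variance are called noise.

## Trajectory kinematics (KiNeT)

Given six-dimensional trajectories per condition and a reference (middle
RT bin, or the correct-outcome trajectory), KiNeT measures, at each
reference timepoint: the time at which each trajectory comes closest to
the reference state (earlier = faster dynamics; the argmin takes the
earliest timepoint on ties and is reported missing beyond a trajectory's
own support rather than extrapolated); the signed minimum distance
(positive when the displacement from the reference is angularly closer to
the first condition's displacement than the last's); angles between
adjacent-trajectory difference vectors; and the rotation of the normalized
mean difference vector relative to the first timepoint (zero there by
construction, with trajectories weighted equally in the mean). Everything
is computed within a choice and then averaged across choices by reference
timepoint index. All outputs are invariant to a global rotation of the
state space, which the tests verify numerically.

Scalar speed is the L2 norm of the state change across 10 ms steps,
averaged across choices and over −400–0 ms for the prestimulus summary.

Bootstrap uncertainty comes from resampling trials with replacement within
unit and condition, re-averaging, re-fitting the PCA and re-projecting
(50 replicates by default); one-tailed p-values use the unbiased formula
`(1 + exceedances)/(1 + n)`, whose floor at n = 50 is 1/51 = 0.0196.
Because the PCA is refit per replicate, raw coordinates are defined only
up to rotation across replicates; uncertainty should be summarized on
rotation-invariant statistics.

## Choice selectivity and the initial-condition axis

The choice-selectivity signal CS(t) is the Euclidean distance between the
left- and right-choice trajectories. Its latency and slope come from
fitting `CS(t) = b` up to a latency and `m (t - t_latency)^2` after it —
fitted exactly as written, without forcing the two pieces to meet. The
latency is grid-searched over the curve's timepoints with `b` and `m` in
closed form; the candidate with one point after the latency is excluded
(a one-point quadratic fit is always exact, which would make the
second-to-last timepoint a spurious global minimizer), and a flat curve
resolves to the window end with a flatness flag.

The initial-condition (IC) axis summarizes prestimulus states: the mean
six-dimensional state over −400 to −100 ms per condition cell, the two
choices concatenated into 12 columns (77 x 12 for 7 coherences x 11 RT
bins), and the top principal component's scores taken as the IC. The axis
sign is oriented so IC correlates negatively with RT-bin centre; the
source fixes only the ordering, not the sign. Partial correlations of
selectivity metrics against IC and coherence use Pearson correlations of
residuals, with percentile intervals and sign-test p-values from the
50-replicate bootstrap; coherence enters as log10(C), matching the
chronometric convention (raw coherence is available as a configuration
switch).

## Decoders

RT regression uses ordinary least squares of RT on all units' spike counts
per 20 ms bin plus unsigned coherence, reporting in-sample R² against the
99th percentile of 500 trial permutations of the spike matrix (RT and
coherence stay aligned); the coherence-only R² is the baseline. Choice and
previous-outcome decoding use L2-regularized logistic regression with the
penalty 1/(in-fold observations), classes balanced by subsampling without
replacement, 5-fold stratified cross-validation, decisions at p = 0.5, and
accuracy = 1 − mean loss. Predictors are z-scored per training fold — the
reference implementation's internal conventions are unknown, and
standardization gives the penalty a stable meaning; the fit itself is a
damped-Newton iteration run to a 1e-6 gradient tolerance. The outcome
decoder uses 50 ms windows stepped by 25 ms — the step that yields 72
windows over the 1800 ms analysis span — with the step exposed as a
parameter.

Per-neuron regressions fit firing rate per 50 ms bin on choice (or RT,
in seconds), optionally partialling out coherence, and call a unit
selective when the 99% confidence interval of the coefficient excludes
zero (1% expected by chance). Units with zero rate variance in a bin are
skipped and counted; the reported fraction is over all units, so a silent
unit counts as non-selective.

## Single-trial dynamics

The autonomous linear dynamical system models the change in latent
activity over a 100 ms horizon (two 50 ms bins) as `X(t+100) - X(t) = X(t) J`,
with latents obtained by projecting binned single-trial rates onto their
top principal components (centering only) and one choice fitted at a time.
J is solved by pooled least squares — the published objective normalizes
by the summed squared derivative, which does not change the minimizer, and
the pooled (not per-trial) normalization follows the formula as written.
Fit quality is leave-one-trial-out R² = 1 − normalized error.

Reduced-rank regression predicts activity at time t from activity at t0
plus choice and coherence. The ordinary least-squares fit is computed on a
seed-controlled 80/20 train/validation split (the ratio is a package
default), the rank-s solution keeps the top s singular triplets
of the fitted values (Eckart–Young), and the smallest rank within
numerical tolerance of the minimum validation MSE is selected.

## Subspace overlap

The alignment index is `A = tr(D' C D) / sum(sigma)`: the variance of one
conditioning's soft-normalized stacked rates captured by the other
conditioning's top-6 principal axes, divided by the *total* variance (all
eigenvalues, not the top 6), so A is a fraction of everything the target
conditioning contains. Both conditionings share the exact preprocessing
used for PCA. Cross-projection applies one conditioning's centering,
normalizers and loadings to the other's rates and reports the captured
variance fraction alongside the projected trajectories.

## Orchestration, sizes and determinism

`run_pipeline()` chains the stages from a config list, derives per-stage
seeds from the global seed with fixed per-stage offsets (adding a stage
never shifts another stage's draws), writes every stage's CSV outputs and
a JSON manifest of parameters and file hashes, and halts on the first
failing stage, naming it. Identical config and seed give byte-identical
outputs.

Test and example problem sizes are chosen to exercise each method at the
smallest scale where its behaviour is unambiguous: full 350-unit/600-trial
sessions where the population-level claims are checked (hypothesis
discrimination, per-neuron calibration, RT-bin geometry), and sessions of
a few dozen units elsewhere. Decoder checks on simulated sessions use a
random 50-unit subset, mirroring the reference analysis of the synthetic
populations.

## Known limitations

* The signal-dimension estimator needs many more stacked rows than units;
  its noise floor is intentionally conservative (factor 2).
* The piecewise selectivity fit assumes a single latency and a quadratic
  rise; latency is only identified to the grid resolution and degrades
  when the plateau dwarfs the rise.
* Bootstrap trajectory coordinates are rotation-ambiguous across
  replicates; only invariant summaries are meaningful.
* The simulator's behavioural stream (coherence, correctness) is
  independent of its neural stream except through choice and RT; it
  cannot be used to study evidence-dependent neural dynamics.
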