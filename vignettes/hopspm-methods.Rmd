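---
title: "Step-down-hop waveform analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step-down-hop waveform analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopspm)
```

This vignette is the package's own account of its science: the processing
and inference models, the tunable parameters and their defaults, what the
synthetic cohorts emulate (and do not), and the numerical and design
choices made where the design was genuinely open.

## The task and the data model

A step-down hop is a single-leg landing-and-hop task used to probe knee
control after ACL reconstruction. One trial yields a dual-rate record: the
three ground-reaction-force components at the force-plate rate (2400 Hz by
default) and the knee flexion–extension moment `Mx` (normalised by body
weight and height) with angular velocity `ωx` at the kinematic rate
(120 Hz). The sign conventions are: a knee (external) flexion moment is
positive, a flexing knee has positive angular velocity, hence joint power
`JP = Mx · ωx` is positive during eccentric (energy-absorbing) muscle work
and negative during concentric work. Early stance after landing typically
shows a brief concentric phase on an injured side (an external extension
moment with the knee still flexing), then a large eccentric peak, then a
concentric propulsion trough.

## Processing chain

1. **Stance extraction.** Stance is bounded by the vertical force crossing
   20 N upward and downward. Because a bare threshold is fragile against
   noise spikes, a crossing only counts if sustained for 5 ms
   (`debounce_s`, configurable; 0 disables it). If several disjoint
   episodes qualify, the longest is taken with a warning. The debounce
   window is the package's own robustness choice; only the threshold value
   is inherited from the study design.
2. **Body-weight normalisation** divides each force component by
   `mass × 9.80665` N. The moment is already normalised upstream and is
   left untouched.
3. **Peak detection** ranks local maxima of the stance-cropped vertical
   force by topographic prominence and keeps the two most prominent,
   ordered in time; a trial is single-peak when the runner-up's prominence
   is below 10% of the global maximum. Prominence (rather than raw height)
   makes the classification robust to noise wiggles riding on a main peak.
4. **Three-phase time normalisation.** The cohort's mean relative times of
   the first and second peaks (the *anchors*) define nodes
   `n1 = round(1000·a1)` and `n2 = round(1000·a2)`; each trial's three
   phases are linearly resampled onto `[0,n1]`, `[n1,n2]`, `[n2,1000]`.
   All channels share one warp, and the kinematic channels are first
   brought onto the force time base by linear interpolation so a single
   mapping serves everything. Whether anchors should be cohort-wide or
   per-condition is not dictated by the design; the package computes them
   cohort-wide over all two-peak trials (every condition is warped to the
   same anchor nodes, which is what makes node-wise paired comparisons
   meaningful), and this is the only supported mode. Single-peak trials
   are uniformly resampled. Piecewise-linear interpolation is used rather
   than splines: it is monotone, cannot overshoot at the anchors, and maps
   the phase-boundary samples (onset, the two peaks, toe-off) onto their
   nodes exactly, so the attained peak values are preserved exactly.
5. **Averaging.** Discrete variables are computed per trial and then
   averaged over the (nominally five) trials of a cell, as are the
   trajectories; a warning is raised below three trials.

**Discrete variables.** Rate of force development is the first-peak
magnitude divided by the time from stance onset to that peak — a real-time
quantity, so it is computed before warping; single-peak trials use the
100 ms fallback duration. "First 5% of stance" is nodes 0–50 inclusive of
the 1001-node grid (5% of the 1000 intervals). Extrema are global over
stance, with no phase restriction — the anterior/posterior force peaks are
not constrained to the propulsion/absorption phases, since the underlying
waveforms place them there anyway.

## Waveform inference

t statistics (paired or pooled two-sample) and Hotelling's T² (one-sample
on paired differences, or two-sample with pooled covariance, across the
three GRF components) are computed node-wise. Zero-variance nodes get
statistic 0 with a warning rather than an infinity — constant padding must
not produce spurious significance. A singular node covariance is
regularised by a ridge of `1e-10 × trace`.

Residual smoothness is estimated with the standard normalised-gradient
estimator: with residual fields `r_i(t)`,
`FWHM = 1 / mean( sqrt( v(t) / 4·log 2 ) )` where
`v(t) = Σ_i r_i'(t)² / Σ_i r_i(t)²`, clamped to `[1, 1000]` nodes.

The critical threshold solves
`ρ₀(z*) + R·ρ₁(z*) = α` with resel count `R = (Q−1)/FWHM` and the 1D
Euler-characteristic densities of the t or F field; bisection stops at
`|Δp| < 1e-8`. T² fields are thresholded through their exact monotone F
transformation (`F = (v−p+1)/(p·v) · T²` with `v` error degrees of
freedom), and the implementation was checked against the single-component
identity `T²* = (t*)²`. t fields are tested **two-sided** (α/2 on the
upper tail of |t|) and T²/F fields upper-tail: the design does not state
sidedness, but differences in either direction are interpretable, and the
corresponding figures' thresholds are symmetric. A permutation threshold
(exhaustive sign flips or group relabellings when feasible) provides an
independent oracle; on smooth Gaussian nulls it agrees with the
random-field threshold to within a few percent.

Cluster-level p values use the standard 1D cluster-extent (Poisson
clumping) approximation and are reported descriptively only; the
scientific conclusions rest on suprathreshold existence at the family-wise
level. The per-test alpha is `round(0.05/3, 3) = 0.017`, Bonferroni over
the three planned comparisons.

## Discrete-variable inference

The repeated-measures ANOVA is implemented as an orthonormal-contrast
general linear model: project the participant × condition matrix onto
`k−1` orthonormal contrasts, regress each contrast score on an intercept
plus mean-centred between-subject covariates, and test the intercepts
jointly (univariate pooling). Without covariates this reproduces the
classic within-subject decomposition exactly (verified against both a
brute-force sums-of-squares oracle and `stats::anova.mlm`). Mauchly's W
and the Greenhouse–Geisser ε come from the residual contrast covariance;
the ε-corrected p is adopted when Mauchly's p ≤ 0.05. How exactly the
original covariate specification entered the software it was run in is
ambiguous, so the condition effect is computed both with and without
covariates; the with-covariates result is the default report.

Post-hoc paired t tests multiply p by the number of pairs and cap at 1
(which is why null entries print as 1.000); confidence intervals are
unadjusted paired-t intervals. Between-side differences are reported
signed as **injured minus uninjured** and between-condition differences as
**sleeved minus unsleeved**. Results tables in this design family often
mix sign conventions (a footnote defining positive as uninjured-higher
next to negative entries for uninjured-higher rows), so one convention is
fixed here and documented.

Change scores are follow-up minus baseline per participant. With nine
participants per group, group comparisons use the exact Mann–Whitney U
(enumeration when the combined sample is ≤ 20 without ties). For tied or
larger samples the mid-rank normal approximation is used **without**
continuity correction, so that identical groups give p = 1 exactly — the
convention of the mainstream commercial package for its asymptotic
two-sided significance.

## The synthetic cohorts

The generator exists to make every downstream stage testable with known
truth; its stated scope is the *statistical* structure the analysis
assumes, not musculoskeletal realism.

**Waveforms** (relative stance time `s ∈ [0,1]`):

* Vertical force: a support floor `v₀·sin(πs)^0.25` (amplitude 45% of the
  smaller peak) plus two Gaussian bumps (width 0.09). The four bump
  parameters are solved by Newton iteration so the two local maxima hit
  the requested magnitudes at the requested times *exactly*. The
  quarter-power floor rises so steeply that the 20 N crossings sit within
  one sample of the nominal stance boundary, and the mid-stance valley
  stays far above threshold plus noise.
* Antero-posterior force: a negative Gaussian at 20% of stance (posterior
  braking) and a positive one at 75% (anterior propulsion), widths 0.12.
* Medio-lateral force: `fx_amp · sin(2πs)`.
* Joint power is constructed directly:
  `JP(s) = off·h(s) + ecc·28.8·G(s; 0.30, 0.10) − con·14.2·G(s; 0.75, 0.10)`
  where `h(s)` is exactly 1 through the first 5% of stance with a smooth
  Gaussian decay after, so an additive `jp_early_offset` shifts the
  first-5% mean one-for-one. The angular velocity is the strictly positive
  `2 + 6·sin(πs)` rad/s and the moment is `JP/ω`; the kinematic pair is
  continued smoothly across the stance edges so that resampling the
  120 Hz channels onto the force base does not ramp the early-power
  plateau through zero at onset (the moment channel is an emulation
  device, not a physiological claim).

**Defaults** emulate the uninjured-side cohort means: first/second Fz
peaks 2.38/1.90 BW at 15%/70% of a 0.45 s stance (giving RFD ≈ 35 BW/s),
Fy −0.14/+0.27 BW, Fx ±0.08 BW, early power +0.4, eccentric peak 28.8,
concentric trough −14.2. The built-in condition deltas reproduce the
cross-over table's injured and sleeved means (e.g. first-5% power
0.4 / −1.5 / −0.2, hence the −1.9 and +1.3 worked differences), and the
group deltas the 6-week changes (−0.17 vs +0.27 BW on peak Fz, +0.07 vs
−0.02 on anterior Fy).

**Noise.** White Gaussian noise convolved with a Gaussian kernel of the
requested FWHM (default 25 nodes on the 1001-node scale), with the kernel
normalised to unit sum of squares so the per-node SD equals `noise_sd`
(default 0.05 BW on Fz; 0.3× on Fx/Fy; 1× and 2× on moment and angular
velocity). A trapezoidal taper confines noise to stance with clean edges.
This is exactly the smooth-Gaussian-field model under which the
random-field thresholds are valid, and `smooth_gaussian_fields()` doubles
as the null generator for calibration.

**Between-subject variability.** Participant-level lognormal factors
(sdlog 0.30, matching the cohort's coefficient of variation of roughly
0.25–0.4 on force and power magnitudes) on magnitudes, an additive
N(0, 3.0) spread on the early-power offset (its betweensubject SD in the
emulated cohort is ≈ 3), time jitter on the peaks (SD 0.010/0.015), and a
lognormal stance-duration factor (sdlog 0.06). One *shared* force factor
scales both vertical peaks, with only a 5%-sdlog wobble on their ratio:
with independent factors the second peak would overtake the first in a
large fraction of participants and a shift injected on the first peak
would no longer appear in the global maximum. Within-trial variability is
not reported for this design anywhere we know of; the waveform noise is
the generator's free parameter and is documented as such, not as a
calibrated claim.

**What passing tests do and do not show.** The cohorts are smooth,
complete (no dropouts within a generated study), Gaussian, and symmetric;
real records have impact transients, occasional single-peak landings,
marker artefacts and missing sessions. Recovery of injected effects here
validates the pipeline's arithmetic and calibration, not its robustness to
those real-data pathologies. Two quantitative caveats are intrinsic to the
emulation: multiplicative lognormal heterogeneity inflates recovered
multiplicative effects by `exp(sdlog²/2) ≈ 4.7%`, and under the default
smooth noise the detected peak *locations* wander with SD ≈ 7–10 nodes
(the noise-model prediction: gradient SD over peak curvature), which is
intended trial-to-trial variability, not detector error — with
sensor-scale noise the detector is node-accurate.

## Numerical choices and degenerate inputs

* Stance debounce 5 ms; minimum stance run 25 ms; all-zero force errors
  out as "no stance detected".
* Flat signals error in peak detection; degenerate time-to-peak (peak at
  onset) errors in RFD.
* The dual-rate chain bounds accuracy: 120 Hz kinematics interpolated to
  the force base reproduce joint-power extrema to about 0.1–0.5% relative
  (the sampling-resolution limit), while force-rate quantities round-trip
  to machine-level accuracy; tests assert exactly these two scales.
* RFT bisection to `|Δp| < 1e-8`; the T² threshold requires at least
  `p + 2` effective observations (the 1D F-field density does not decay
  for smaller error df).
* Permutation thresholds need ≥ `1/α` distinct permutations, else error.
* FWHM clamped to `[1, 1000]`; constant residual fields return the upper
  clamp with a warning.

## Problem sizes used by the tests and acceptance run

Family-wise-error calibration: 2000 simulated null studies of 10 smooth
curves (FWHM 20). Effect recovery: 200 cross-over cohorts of 30
participants × 3 conditions × 5 trials, simulated at a 600 Hz force rate —
a deliberate problem-size choice for the Monte-Carlo loops; the recovery
target is rate-independent, and the generator's default remains the
study's 2400 Hz. Unit tests run at 1200 Hz.

## Known limitations

Cluster-level p values are a descriptive approximation; no ANOVA-type 1D
fields (the design needs only t and T² fields); no missing-data handling
beyond logged exclusion of incomplete participants; cohort-wide anchors
are the only warping mode; the generator does not produce marker
trajectories or full-body kinematics.
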