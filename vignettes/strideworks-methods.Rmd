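---
title: "Methods: stride-level kinematics, coordination variability and 1D permutation inference"
author: "strideworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stride-level kinematics, coordination variability and 1D permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strideworks)
```

## The analysis problem

strideworks studies how running technique changes during a constant-speed
treadmill run to volitional exhaustion, comparing two technique clusters
of runners — a "neutral pelvis" and a "tilted pelvis" group — across
three landmarks of the trial (start, middle, end). The pipeline turns raw
200 Hz sagittal-plane kinematics into:

* **0D spatiotemporal descriptors** per participant and trial segment:
  duty factor (contact time / stride time) and stride frequency in a
  leg-length-normalised dimensionless form;
* **1D stride-cycle curves**: ensemble means of the trunk-to-pelvis,
  pelvis, hip, knee and ankle sagittal angles and of vertical
  centre-of-mass displacement, registered to 201 points of normalized
  stride time;
* **coordination variability** of three joint couplings
  (trunk-to-pelvis–hip, hip–knee, knee–ankle) via the angular-velocity
  ellipse-area method;
* **statistics**: a conventional two-way mixed-design repeated-measures
  ANOVA for the 0D variables and a nonparametric, permutation-based SPM
  (statistical parametric mapping) analogue of the same design for the
  1D curves, both followed by Bonferroni-corrected post hoc tests.

Because the underlying human dataset is not redistributable, the package
ships a synthetic gait generator with exact ground truth. Every
downstream stage is validated against what the generator injected.

## The synthetic gait generator

`generate_participant()` builds each trial as

> channel(t) = template(phase) + cluster offset + participant offset
>             + fatigue delta(phase) * ramp(t) + smooth noise(t)

with right foot-strike at phase 0. The per-channel templates are
periodic splines through hand-set keypoints shaped like textbook running
kinematics (hip flexion peaking mid-swing, knee flexion peaking in
early-mid swing, plantarflexion just after toe-off, twice-per-stride
pelvis/trunk and vertical-COM oscillations). They are plausible
stand-ins with known ground truth, not measurements, and results on them
should not be read as reproducing any specific experimental curve.

Sign convention (used consistently everywhere): flexion, anterior tilt
and dorsiflexion are positive; extension and plantarflexion negative.

Key defaults, chosen to describe the study conditions the package
models:

| parameter | default | unit | rationale |
|---|---|---|---|
| `n_neutral` / `n_tilted` | 32 / 28 | runners | the two-cluster cohort sizes |
| `sample_rate` | 200 | Hz | optical motion-capture rate |
| `trial_duration` | 1200 | s | ~20-min runs to exhaustion |
| `base_stride_time` | 0.685 | s | ≈137 frames at 200 Hz |
| `base_duty_factor` | 0.35 | – | typical for ~14.5 km/h running |
| `batch_length` / `gap_length` | 540 / 90 | s | 9-min recording batches with 1.5-min saving gaps |
| cluster offsets | +4° pelvis tilt, −5° trunk-to-pelvis flexion, +5° hip flexion, −0.015 duty factor | | direction of the tilted-pelvis technique; magnitudes are package choices of realistic size |
| fatigue deltas | +4° trunk-to-pelvis over 8–26% of stride; −6° ankle over 49–91%; +0.008 s stride time; +0.005 duty factor; swing noise ×1.5 | | end-of-trial values, ramped linearly in elapsed time |
| stride noise | 1.5° SD, band-limited < 6 Hz | | survives the 10 Hz trajectory filter by construction |
| between-participant SDs | 2° angles, 0.04 s stride time, 0.02 duty factor | | so the 0D fatigue drifts have small standardized magnitude (d ≈ 0.2 for stride frequency, ≈ 0.25 for duty factor) against the between-subject scale |

Fatigue is ramped linearly from zero at the trial start to the full
delta at the end; a monotone ramp is all the start/middle/end contrasts
can identify, and linearity makes midpoint predictions exactly testable
(the delta at mid-trial is half the end value). Phase-windowed deltas
use raised-cosine edges (3% of stride) so the injected change stays
band-limited. Samples inside recording gaps are missing (`NA`), never
interpolated; strides that touch a gap are unusable downstream.

The foot-vertical event-reference trajectory is engineered jointly with
the event detector: a symmetric V-shaped valley centred on foot-strike
(so the zero-phase filter rounds but does not displace the minimum) and
a linear ramp through the detector's height threshold crossing exactly
at toe-off, kept linear over ±7% of the stride — wider than the 10 Hz
filter kernel — so filtering preserves the crossing. This is what makes
±1-frame event recovery achievable and testable.

### What the generator does not emulate

No ground-reaction forces, no marker-level or 3D segment simulation, no
soft-tissue artefact, no treadmill-belt speed fluctuation, no
physiological modelling beyond simple breath records. Stride noise is
stationary Gaussian; real stride-to-stride variability is
heavier-tailed and serially correlated. Passing tests therefore certify
the *pipeline's* correctness and calibration on data with the assumed
statistical structure — not that real runners behave like the
templates.

## Signal preparation

* **Filtering.** "4th-order zero-lag Butterworth, 10 Hz" is implemented
  as a 2nd-order filter run forward and backward (`signal::filtfilt`),
  the dominant biomechanics convention, with the design cutoff raised by
  $1/(\sqrt{2}-1)^{1/4} \approx 1.2465$ so the −3 dB point of the dual
  pass sits at the nominal cutoff. Measured response: gain 0.99996 at
  1 Hz, 0.0055 at 40 Hz, −3 dB at 10 Hz. Each recording batch is
  filtered independently with 1 s reflection padding; reflection is
  linear, so filter linearity is preserved exactly.
* **Event detection.** Within each gap-free span the height threshold is
  the 5th percentile plus 20% of the p5–p95 range (the percentile range
  rather than the absolute range, so a single extreme swing peak cannot
  move the threshold). Each maximal below-threshold run is one ground
  contact: foot-strike is the parabolically refined minimum, toe-off the
  linearly interpolated upward crossing at the run's end. Runs touching
  span edges are discarded, so no events appear inside gaps. On
  generated trials with default noise both events land within one frame
  (5 ms) of ground truth.
* **Trimming.** The first and last 10 s (mounting/dismounting the belt)
  are flagged unusable; trimming narrows the usable-window set and is
  idempotent.
* **Registration.** Strides run from right foot-strike to the next
  right foot-strike and are registered by linear interpolation onto 201
  equally spaced points including both endpoints (0% and 100% sampled).
  Linear interpolation is exact for linear signals and its error is
  quadratic in the frame spacing for band-limited ones; the round-trip
  error back to the original grid is under 1% of channel range.
* **Segment selection.** Landmarks at 0%, 50% and 100% of the usable
  span; the 50 strides whose temporal midpoints are nearest each
  landmark are selected, ties broken toward the earlier stride. Short
  trials yield all available strides plus a warning, and segments may
  then share strides.
* **Breath cleaning.** Gas-exchange records are reviewed in
  non-overlapping 30 s windows aligned to the trial start; breaths
  outside ±2 SD of the window mean (VO2 or VCO2) are excluded. A window
  with zero spread keeps everything.

## Features

Duty factor is CT/ST per stride; stride frequency is normalised as
$(1/ST)\sqrt{L/g}$ with $L$ the leg length in metres and $g =
9.81\,\mathrm{m/s^2}$ — the standard dimensionless (Froude-style)
cadence form; the bare statement "normalised to leg length" admits
several formulas, and this choice is recorded here as the package's
single largest interpretive decision. vCOM is re-referenced to its
per-stride minimum (a displacement; absolute height is not meaningful
after normalisation) and divided by leg length. Segment-level 0D values
are unweighted means over the segment's strides.

## Coordination variability

Angular velocities are computed in original (unnormalised) time by
central differences — preserving physical deg/s magnitudes — and then
registered to the 201-point grid; second-order one-sided differences are
used at stride ends. At each grid point the 2×2 sample covariance
(n−1 divisor) of the coupling's velocity pair across a segment's strides
is summarised by the area of its 95% prediction ellipse,

$$ A = \pi \, \chi^2_{0.95,2} \, \sqrt{\lambda_1 \lambda_2}
     = \pi \, \chi^2_{0.95,2} \, \sqrt{\det \Sigma}, $$

with $\chi^2_{0.95,2} \approx 5.9915$. The scaling is validated by a
Monte-Carlo coverage oracle (fresh bivariate-normal draws fall inside
the ellipse 95.0% of the time) rather than assumed. Because the ordering
of differentiation and time-normalisation is a genuine degree of
freedom, absolute ellipse-area magnitudes are comparable only within
this package's convention.

## Statistics

The design crosses one between-subject factor (cluster: neutral/tilted,
unequal group sizes allowed) with one within-subject factor (segment:
start/middle/end). The 0D ANOVA uses the classical univariate
decomposition — cluster tested against subjects-within-cluster, segment
and interaction against the segment×subject residual — with no
sphericity correction (a documented limitation). The same vectorized
sums-of-squares kernel evaluated at every grid point yields the 1D F
continua; both are verified against `stats::aov` and a brute-force
loop-based computation.

Nonparametric SPM inference uses the permutation distribution of the
continuum maximum statistic:

* **between effect** — cluster labels permuted across subjects, on
  subject-mean curves (the between-subjects F depends on the data only
  through these);
* **within effect** — segment labels permuted independently within each
  subject (exact under exchangeability of segments);
* **interaction** — within-subject residual curves (after removing
  subject and segment means) permuted within subjects, the standard
  restricted-permutation approximation.

The critical threshold is the $k$-th largest of the $B$ permutation
maxima with $k = \lfloor \alpha (B+1) \rfloor$; an observed continuum is
significant where it strictly exceeds it, giving exact level
$k/(B+1) \approx \alpha$ under exchangeability. Suprathreshold clusters
are scored by extent (number of grid points), with
$p = (1 + \#\{b : \text{max extent}_b \ge \text{observed}\})/(B+1)$.
Exhaustive enumeration (all sign flips, label assignments, or per-subject
segment permutations) replaces random sampling whenever the total count
fits within `n_perm`; the default is 10,000.

Post hoc contrasts are two-sided t continua at Bonferroni-adjusted
levels: sign-flipping for paired (segment) contrasts, label exchange for
unpaired (cluster) contrasts. The 0D post hocs report Cohen's d —
mean difference over the SD of differences for paired contrasts, pooled
SD for unpaired — with a large-sample normal-approximation 95% CI
($d \pm 1.96\,\mathrm{SE}$); a noncentral-t CI would be tighter at small
n but the normal form is transparent and adequate at cohort scale.
Baseline participant characteristics use an equal-variance
independent-groups t-test when both clusters pass Shapiro–Wilk at 0.05,
a Mann–Whitney U otherwise, and a chi-squared test (no continuity
correction) for categorical variables.

### Calibration evidence

The test suite measures, rather than assumes, the machinery's operating
characteristics on cohorts from `simulate_curve_cohort()` (smooth
between-subject offset curves, SD 5°, plus smooth within-subject noise,
SD 3° — the curve-level analogue of the full generator):

* family-wise false-positive rates of all three effects on 500 null
  cohorts (12 subjects, 200 permutations) fall inside the 95% binomial
  band around α = 0.05;
* a +4° end-segment effect over 8–26% of the stride, at cohort scale
  (n = 60), is detected by the within-effect post hoc with a cluster
  overlapping the injected window in ≥ 90% of 50 cohorts (observed:
  100%).

## Numerical and degenerate-case choices

* Zero-variance grid points in t continua give t = 0 (a condition tested
  against itself yields a zero curve and no clusters); zero effect sums
  of squares give F = 0, p = 1.
* Covariance determinants are clipped at zero before the square root
  (round-off can make a rank-deficient determinant slightly negative).
* Stride slicing requires a toe-off strictly inside the stride and the
  whole stride inside one usable window; offending strides are dropped
  with a message, never silently repaired.
* All RNG flows from explicit seeds: the cohort from `sim_config$seed`,
  the statistical stage from `pipeline_config$seed`; identical
  configuration reproduces identical artifacts (checksummed in the run
  manifest).

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full 200 Hz chain on
cohorts of 2–12 participants with 60–600 s trials, and exercise the
statistics at cohort scale (n = 60) through the curve-level generator;
the acceptance script's pipeline run uses 60 participants × 600 s
trials. These sizes were chosen so that a complete desk-scale
replication, including the 500-cohort calibration study, finishes in
minutes while preserving every structural property of the full-scale
conditions (the fatigue ramp, batch gaps, 50-stride segments).

One consequence worth knowing: with 50-stride segments and the 10 Hz
filter, the *measured* end-minus-start change curves recover about
75–85% of the injected phase-windowed deltas (segment averaging spans a
window of trial time over which the ramp is below its end value, and the
filter attenuates short-duration bumps). The acceptance script reports
the measured values, not the injected constants.

## Known limitations

* Only sagittal-plane variables; no frontal/transverse angles, no
  kinetics.
* The within-effect and between-effect permutation schemes are exact
  under exchangeability, but the interaction scheme is approximate
  (residual exchangeability), as in standard practice.
* No sphericity correction for the 0D RM ANOVA.
* The event detector assumes a foot-reference trajectory with a single
  clear minimum per stride; it is validated on the generator's
  waveforms, not on pathological gait.
* Ellipse-area magnitudes depend on the velocity-computation convention
  and are not comparable across implementations that differentiate
  normalized-time curves.
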