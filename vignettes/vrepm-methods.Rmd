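---
title: "Scoring and reliability methods for the virtual-reality elevated plus-maze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and reliability methods for the virtual-reality elevated plus-maze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrepm)
```

## The assay and its coordinate conventions

A human elevated plus-maze session produces a head-tracking pose stream:
3D positions and orientations sampled at 5 Hz in a calibrated world frame
whose origin sits at the maze centre, whose x-axis runs along the closed
arms and whose z-axis runs along the open arms. Each arm is 175 cm long
and 30 cm wide, so the maze spans 350 × 350 cm. A session consists of a
baseline phase at the maze centre (negative timestamps) and a 300-s
exploration task beginning at the scene change (t = 0).

All planar computations ignore the vertical (y) coordinate: participants
walk on a flat maze and headset height varies with posture, not location.
Calibration residuals are handled by `calibration_transform()` /
`to_maze_frame()`, a rigid rotation–translation validated for
orthonormality.

## Zone scoring

A sample is **on an open arm** when |p_z| exceeds the zone threshold, **on
a closed arm** when |p_x| does, and **in the centre** otherwise. The
threshold defaults to 15 cm — the half-width of the arms, i.e. exactly the
edge of the central square where the arms begin. The threshold in the
original acquisition software is not documented, so the value is
configurable (`zone_threshold`); every downstream metric inherits it.

Points with both |p_x| and |p_z| above threshold cannot occur on the
physical maze but can arise from tracking noise. They are resolved by the
larger absolute coordinate, with ties going to the open arms. The bias this
introduces favours the primary outcome and is negligible in magnitude: it
requires a tracking error larger than the arm half-width.

Scoring conventions, each bounded by one sample period Δt = 0.2 s:

* **Dwell times** — each uniformly resampled task sample contributes Δt to
  its zone, so open + closed + centre time partitions the tracked task time
  exactly.
* **Entries** — pairs where sample i−1 is *not* in a zone of the requested
  type and sample i *is*. A literal signed threshold crossing cannot serve
  here, because each arm type has two arms at opposite signs; the
  membership-transition formulation counts centre→arm entries and
  (noise-induced) direct arm-type switches alike, matching how entries are
  counted in the rodent literature.
* **Latency first visit** — the timestamp of the first open-classified
  sample, not an interpolated crossing; error bounded by Δt.
* **Latency end-exploration** — first time |p_z| ≥ 160 cm. "End of an open
  arm" is not defined numerically in the assay description; the default is
  arm length minus one arm half-width, configurable via `end_threshold`.
* **Censoring** — sessions in which an event never occurs score the task
  duration (300 s) with an explicit censoring flag, so cohort means remain
  defined and comparable.
* **Distance and velocities** — horizontal (x, z) path lengths only,
  excluding head bobbing; velocities average per-step speeds whose both
  endpoints lie in the arm type, and are `NA` (not zero) when no step
  qualifies.

## Occupancy heatmaps

Positions are binned into a 35 × 35 grid of 10-cm cells covering
[−175, 175) on each axis, half-open bins with boundary and out-of-maze
points clamped into the edge bins. Cells accumulate seconds (samples × Δt)
rather than raw counts, making maps comparable across sampling rates; an
unnormalized per-session map therefore sums to the tracked task time.
Cohort maps are per-participant means ("normalized by the number of
participants"), difference maps subtract the first-exposure cohort map
from the second, and `dwell_mask()` selects cells at or above a minimum
mean stay (0.5 s by default, inclusive) for rendering.

Rows index x (closed axis) and columns z (open axis); the sidecar JSON
written next to each matrix records this orientation.

## Physiological intervals

Channels are averaged over half-open windows: [−30, 0) s baseline, then
[0, 30), [30, 60), … — 11 intervals for a 300-s task. Half-open windows
guarantee no sample is double-counted at boundaries, and the scheme is
invariant to rate refinement of a piecewise-constant signal. Empty windows
(artifact exclusion) become explicit `NA` markers; the ANOVA layer then
excludes affected participants listwise per channel, mirroring per-channel
dataset exclusion practice. Skin conductance is ln-transformed at the
level of interval means (the transform level is not specified in the assay
description; means-level is the more robust choice and is flagged in the
output). Amylase triplets carry below-detection flags at 25 U/mL and
deltas involving a flagged sample propagate as missing.

## Statistics layer

* **Pearson matrix** — all pairwise correlations among the selected
  measures at first and second exposure, pairwise-complete, `NA` for
  constant variables or fewer than 3 pairs.
* **ICC** — two-way mixed, consistency, *single measures* (Shrout–Fleiss
  ICC(3,1)): one score per occasion is analysed, so the single-measures
  form applies. The estimate comes from the subjects × occasions mean
  squares without replication; the 95% CI from F-distribution bounds on
  MS_subjects/MS_error. Consistency deliberately ignores additive occasion
  shifts (habituation/sensitization offsets do not reduce reliability).
  Degenerate inputs (no subject and no error variance) are flagged rather
  than returned as numbers; a zero error variance yields a CI collapsed at
  1 rather than NaN.
* **Split-plot rm-ANOVA** — classical univariate decomposition (between
  effect against subject-within-group error; within effects and their
  interactions with the between factor against the corresponding
  subject-by-effect stratum), computed via `stats::aov()` error strata.
  Sequential sums of squares are exact for the supported designs: within
  cells are complete and balanced after listwise exclusion, and the single
  between factor is the only term in its stratum. Greenhouse–Geisser ε is
  estimated per within effect from the pooled within-group covariance of
  orthonormal effect contrasts, ε = tr(T)²/(q·tr(T²)); single-df effects
  need no correction (ε = 1), and interactions with the between factor
  share the ε of their within-contrast space. Huynh–Feldt is deliberately
  not offered. Effect sizes are partial η² = SS_effect/(SS_effect +
  SS_error). Two-sided tests at α = .05 throughout, and **no
  multiple-testing correction anywhere** — by design.
* **Power** — exact noncentral-t power for the paired t-test
  (df = n − 1, noncentrality d√n); `required_n_paired_t()` returns the
  smallest n whose power reaches the target, located by bisection on the
  monotone power curve and verified for minimality.

## The synthetic cohort generator

The generator exists to make every stage verifiable with known ground
truth; it is not a model of human gait or of anxiety.

**Trajectories.** A heading-persistent walker on the plus-shaped surface:
per 0.2-s step it draws a speed from a normal distribution truncated at 0
(default 5 ± 7 cm/s), keeps its previous heading with probability 0.6 or
re-aims at its current waypoint with 20° angular jitter, and reverses
waypoint with hazard 0.004 per step. At the centre it chooses the next arm
with weight 1/(1 + anxiety) per open arm against 1 per closed arm; since
cohort traits enter as anxiety = exp(latent), the open-arm choice weight is
logistic in the latent trait. The centre square can only be left through
the corridor of the chosen target arm, so arm entries are gated by the
choice rule and an infinitely anxious agent provably never accrues
open-arm time. The movement defaults were chosen once so that default
sessions land on the scales reported for human cohorts on this assay
(roughly 90 s open-arm time, 13–17 m travelled, end-exploration latencies
around 180 s); they are configurable, not fitted.

**Cohorts.** Latent traits are bivariate normal across the two exposures
(default mean 0, SD 1, correlation 0.8) with an optional additive
second-exposure shift; version assignment follows the 18/21
Desert/VideoGame split of a 39-participant two-version design. Every
session gets its own recorded sub-seed, so cohorts are exactly
reproducible.

**Physiology.** Piecewise-constant levels plus white noise: baseline,
task onset response, an anticipatory baseline elevation at second
exposure, and a multiplicative sensitization factor on the second-exposure
onset response (values below 1 model a blunted repeated-exposure response).

**What the generator does *not* emulate.** Three simplifications matter
when interpreting green tests:

1. *Reliability attenuation.* A latent retest correlation of 0.8 does not
   produce a behavioural ICC of 0.8: an agent makes only a handful of
   independent arm choices per session, so session-level binomial noise
   attenuates the behavioural test–retest correlation well below the
   latent one. The recovery tests therefore check that ICC confidence
   intervals *cover the reliability actually implied by the generative
   model* (estimated from pooled replicate cohorts), and that open-arm
   time is monotone in anxiety — not that the synthetic ICC reproduces any
   particular human value. Human cohorts, whose within-person behaviour is
   far more consistent than independent Bernoulli choices, can show much
   higher reliability at the same latent stability.
2. *Locomotor traits.* Movement parameters are identical across agents, so
   distance and velocity have no participant-stable determinant and their
   synthetic retest reliability is near zero by construction — unlike
   human cohorts, where locomotion is among the most reliable markers.
3. *Autocorrelated physiology.* White noise around step levels makes
   30-s interval means extremely precise (SE = σ/√150), so simulated
   onset t-statistics are far larger than typical human ones; real
   autonomic signals drift and are autocorrelated. The type-I/power
   validation therefore uses analytically matched effect sizes rather
   than "realistic" ones.

## Numerical choices and problem sizes

Dwell, entry, latency, distance and velocity scans are validated against
independent brute-force per-sample loops on 100 random 1500-sample
streams; dwell agreement is required within one Δt and everything else to
1e−9. Conservation (time partition and heatmap mass) is asserted within
one Δt on every simulated session. The reliability-recovery study uses 150
replicate cohorts of n = 39 (300-s sessions at 5 Hz); the paired-t
size/power study uses 2000 replicates of 20 subjects with 30-s windows.
These sizes give Monte-Carlo standard errors comfortably below the
asserted tolerances (≈1.8% for the 95%-CI coverage check, ≈1% for
rejection rates). Resampling uses linear interpolation (head motion is
smooth at the 0.2-s scale) with per-component angle unwrapping for
orientations; trajectory files are written with 17 significant digits so
read→write→read round-trips are exact.

## Known limitations

* Head orientation is ingested and preserved but no orientation-derived
  marker (risk assessment, scanning) is computed.
* The ingest path reads the package's delimited pose-stream format only;
  proprietary HMD logs must be converted upstream.
* The rm-ANOVA supports one between-subjects factor and complete balanced
  within designs after listwise exclusion; no imputation, no mixed-effects
  fallback for unbalanced data.
* Whether the original acquisition software used a 15-cm zone threshold,
  sample counts or seconds in heatmaps, and a GG- or HF-style correction
  cannot be determined from the assay description; the defaults here are
  the documented, configurable choices above.
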