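---
title: "Models and methods in riskseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in riskseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

riskseq analyzes how mice organize exploratory behavior under risk on the
elevated plus maze (EPM), and how population calcium signals recorded by
fiber photometry track that organization. This vignette explains the
models, the tunable parameters, the numerical choices, and the places
where the design was genuinely open — in enough detail that a maintainer
can judge what a green test does and does not establish.

## The maze and its zones

The EPM is modeled with its origin at the center of the central square
platform (side 7.8 cm), closed arms on one axis and open arms on the
other, each arm 27.8 cm long. An arm therefore spans 3.9 cm to 31.7 cm
from the origin along its axis. Each arm is split at a configurable
fraction of its length (default 0.5, i.e. 17.8 cm from the origin) into a
proximal and a distal half, giving the five-zone partition used
throughout: `center`, `closed-proximal`, `closed-distal`,
`open-proximal`, `open-distal`, each tagged with an arm id. Ties at the
split count as distal, matching the "crossing at least 50%" stop rule.
Tracking output in pixels is converted with a 2-point calibration (two
opposite arm ends and their true separation); the package never assumes a
particular camera scale.

## Risk-ranked sequence segmentation

Continuous sessions are segmented into four sequence types ordered by
commitment to open-arm (risky) exploration:

* **CC** — closed arm to the opposite closed arm, no risk assessment;
* **NoGo** — risk assessment in the proximal open arm, then withdrawal to
  a closed arm;
* **Go** — risk assessment followed by full open-arm entry;
* **CO** — direct closed-to-open transition without risk assessment.

A sequence *opens* at the first frame in a closed-arm distal zone (the
start zone) where the heading lies within ±90° of the arm-to-center
direction **and** the centroid velocity component toward the center is
positive, both sustained for at least 3 consecutive frames (0.1 s at
30 fps). The qualitative orientation rule is stated by the source
methods; the ±90° cone, the positive-velocity gate and the 3-frame
persistence are this package's quantitative rendering, chosen to
suppress jitter-triggered starts and frozen by the round-trip tests. A
sequence *closes* at the first frame at or past 50% of a non-originating
arm. Risk-assessment events are consumed from annotations (BORIS-style
manual exports or the simulator), never re-detected from pose; events
located outside the proximal open arm are ignored for classification
with a warning. Classification is the exhaustive 2×2 table over
(terminal arm closed/open) × (≥1 risk event or none). Open-arm-origin
excursions fall outside this closed-origin taxonomy and are not
classified. The risk assessment index is (NoGo + Go) / total sequences.

## Photometry preprocessing

Both channels (470 nm signal, 415 nm isosbestic reference, interleaved
at 40 samples/s per channel) are processed as:

1. zero-phase Butterworth low-pass, 10 Hz cutoff, order 4, at the native
   channel rate (forward–backward filtering; effective magnitude is the
   squared Butterworth response);
2. RANSAC linear scaling of the reference to the signal (2-point
   candidate lines, consensus threshold = `ransac_residual_threshold` ×
   1.4826 × MAD of initial least-squares residuals, default multiplier 1,
   100 iterations, least-squares refit on the best consensus set; fully
   deterministic given `ransac_seed`);
3. dF/F = (signal − scaled reference) / scaled reference. The source
   description names the subtraction but not the denominator; the scaled
   reference is the standard convention and is used here;
4. z-scoring across the whole session, pooling both hemispheres of an
   animal so between-hemisphere differences survive in z units;
5. at peri-event extraction, each ±3 s window is smoothed with a discrete
   Gaussian (σ = 4 samples, kernel truncated at 4σ, unit mass,
   reflect-padded) and averaged into 90 half-open 1/15-s bins.

The published order of operations lists smoothing before z-scoring but
smooths "each peri-event trace" while z-scoring "across the whole
session"; the pipeline above preserves both scopes (session statistics
are computed on the unsmoothed dF/F; smoothing is per window). Since
Gaussian smoothing is linear and the session z-score is affine, the only
difference from the literal published order is a sub-percent change in
the session SD; the choice is visible in code, not buried.

Numerical notes: the Butterworth design is the bilinear transform of the
analog prototype (coefficients agree with standard DSP references);
forward–backward filtering uses odd-reflection padding with steady-state
initial conditions so constants pass exactly. The replaced
visual-inspection step of isosbestic fits is an automated QC report
(inlier fraction, inlier R², overlay plot) with a configurable
inlier-fraction floor; note that with the default MAD threshold a
pure-noise signal still retains ~68% "inliers", so the floor only
triggers on genuinely degenerate fits or when raised.

## Peri-event units and epochs

Events are aligned at the first risk-assessment onset (NoGo, Go) or the
center crossing (CC); CO has no published anchor and is excluded from
photometry analyses. Windows are [−3, 3) s in 90 half-open bins of
1/15 s; bin "centers" sit at left edge + 1/30 s, and bin values are means
of raw samples in the bin (robust to channel-rate changes; no
interpolation). The observational unit is animal × hemisphere × event.
Epochs are pre [−3, −0.5), peri [−0.5, 0.5), post [0.5, 3), membership by
bin center, which fixes the counts at 37, 15 and 38 bins — asserted in
tests to freeze the convention. Epoch comparisons across sequence types
default to bin-level observations (matching the large printed
denominator degrees of freedom in the source figures) with a unit-level
mode available.

## GEE model

Sequence-specific time courses are modeled as

    zdff ~ type + bs(time, df = 4) + type : bs(time, df = 4)

with Gaussian family, identity link, an AR(1) working correlation over
the 90 bins of each unit, and cluster-robust (sandwich) covariance. With
three types this gives 15 design columns (intercept, 2 type indicators,
4 spline columns, 8 interactions). The B-spline basis uses quantile
knots and excludes the intercept. Fitting iterates generalized least
squares with Liang–Zeger moment estimation of the dispersion and lag-1
correlation; each GLS step whitens clusters with the AR(1) innovations
transform, so no dense correlation matrix is ever formed.

**Small-sample corrections (a deliberate design choice).** The naive
sandwich covariance is biased downward by a factor of order p/K
(p = 15 parameters, K = clusters); with ~50 units the uncorrected joint
Wald χ²(8) interaction test rejected a true null at ~17% instead of 5%.
The package therefore defaults to the Mancl–DeRouen bias-corrected meat
(per-cluster leverage correction of the whitened residuals, the cluster
analogue of HC3) and refers the Wald statistic to the Hotelling-type
F reference `W (K − p) / ((K − 1) p) ~ F(p, K − p)`. Measured null
rejection after correction: 0.055 over 600 simulations. Both corrections
vanish asymptotically (at the published scale of 612 units they are
negligible) and both can be switched off (`correction = "none"`,
`small_sample = FALSE`) to recover the classical Liang–Zeger/χ² forms.
The published omnibus χ²(15) label is not derivable from the stated
reference-coded design (8 interaction columns; 10 with mains; 14
non-intercept); `wald_joint` exposes all three scopes rather than
guessing which produced that label.

## Bootstrap bands and time-resolved contrasts

Uncertainty uses the cluster (animal-level) bootstrap: animals are
resampled with replacement, each drawn animal contributing all its units
(with multiplicity); per-type mean time courses are recomputed per
resample (1000 resamples; percentile bands at 95% and 99%; deterministic
given the seed). One-sample significance marks bins whose 99% band
excludes zero; runs shorter than 2 bins are suppressed (configurable,
since the source once reports an isolated time point).

Pairwise contrasts follow the published procedure literally: the two
types' 95% bands are **subtracted** bin by bin and a bin is significant
where the subtracted band excludes zero — i.e. where the bands do not
overlap. A `method = "difference"` variant that bootstraps the per-bin
difference of means directly is also provided; it is a pointwise test
and, over a 90-bin family, flags spurious intervals in roughly a third
of null simulations, whereas band subtraction leaves ≥94% of null
simulations empty. This is why band subtraction is the default.

## The synthetic world

The simulator states one fixed world; none of its parameters are tuned
to test outcomes.

*Behavior*: 10-min sessions at 30 fps on the printed maze geometry.
Bouts follow constant-speed waypoint paths (12 cm/s cruising) with
Gaussian tracking jitter of SD 0.1 cm — a realistic sub-millimeter-per-
frame pose-estimation noise level. Risk-assessment point events are
emitted at pause onsets in the mid proximal open arm (0.6 s dwell per
event, 2 events per NoGo/Go bout by default), with the bounding box
elongated during the pause to mimic stretch-attend postures. Between
bouts the animal idles in a closed-arm distal zone facing away from the
center, so the start gate cannot fire. Idle-phase kinematics, bout
speeds and dwell times are plausible for mice but make no biomechanical
claims.

*Photometry*: interleaved 470/415 streams at 40 samples/s per channel
(the published "40 Hz" does not say per-channel or total; per-channel is
the default since a 10 Hz filter at a 20 Hz channel rate would sit at
Nyquist). Both channels share a single-exponential bleach (τ = 2000 s)
and a multiplicative motion artifact (smoothed Gaussian random walk,
default 5% of baseline); the signal channel adds double-exponential
calcium transients (τ rise 0.1 s, decay 1 s) at each bout's alignment
anchor with per-type amplitudes following the observed ordering — CC
elevated, NoGo intermediate, Go suppressed (defaults +1, +0.4, −0.8 in
nominal z units; the conversion to raw fluorescence via the expected
session dF/F SD is approximate, so recovered deflections are attenuated
by z-scoring against the transients themselves). White sensor noise
(SD 1.5 on a 200-unit baseline) completes the model. There is no photon
shot-noise physics and no hemodynamic component.

*Direct unit simulation*: calibration studies bypass the raw pipeline
and generate binned units as mean curve + small shared animal offset
(SD 0.1 z — small because within-animal session z-scoring removes
additive offsets by construction) + animal×type effect (SD 0.25 z,
modeling per-mouse response-amplitude heterogeneity, the dependence the
cluster bootstrap exists to respect) + bin-level AR(1) noise (ρ = 0.987,
the value estimated in the source data).

**What a green test establishes.** Round-trip recovery shows the
segmentation rules and the simulator agree on the stated world; it does
not validate pose tracking, manual annotation quality, or behavior of
real mice. Bootstrap coverage is checked in the procedure's asymptotic
regime (30 animals, measured ~94%); at the study scale of 14 animals,
percentile cluster bootstrap intervals under-cover by construction
(~91%, the t₁₃-versus-normal effect) — a property of the method, not of
this implementation, and worth remembering when reading 14-animal bands.

## Known limitations

* Sequence starts are implemented for closed-arm origins only (the
  published taxonomy is closed-origin; open-origin excursions are
  logged, not classified).
* "Horizontal movement" is per-frame Euclidean centroid displacement;
  the source does not define it further.
* The Greenhouse–Geisser epsilon uses the pooled within-group
  covariance; reference implementations that pool differently can give
  slightly different adjusted p-values (uncorrected F and p agree
  exactly).
* Percentile (not BCa) bootstrap, per the published description; see the
  coverage note above.
* The mixed ANOVA requires balanced within-subject coverage and rejects
  anything else by animal id, rather than imputing.
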