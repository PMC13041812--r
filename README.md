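# riskseq

Tools for asking how animals organize exploratory behavior under risk —
and how neural population signals track that organization — on the
elevated plus maze (EPM).

The package is aimed at behavioral neuroscientists who have (a)
frame-wise pose-tracking tables from EPM videos, (b) manually annotated
behavioral events (BORIS-style exports), and (c) dual-wavelength fiber
photometry recordings, and who want a tested, scriptable path from those
raw tables to sequence-resolved statistics. Everything also runs fully
offline on a built-in synthetic-data generator with known ground truth,
so every stage is verifiable without any recordings.

## What it computes

**Behavior.** Frame-wise kinematic and postural features (speed,
acceleration, horizontal movement, bounding-box area and aspect ratio,
heading with polar histograms and Rayleigh tests); a five-zone maze
partition built from the printed geometry (27.8 cm arms, 7.8 cm center);
and rule-based segmentation of the session into four risk-ranked
sequence types — `CC` (closed→closed), `NoGo` (risk assessment, then
withdrawal), `Go` (risk assessment, then open-arm entry), `CO`
(direct closed→open). A sequence opens in a closed-arm distal start zone
with heading and velocity oriented toward the center, and closes on
crossing ≥50% of a non-originating arm. The **risk assessment index** is
(NoGo + Go) / total sequences.

**Photometry.** 470/415 nm streams are low-pass filtered (zero-phase
Butterworth, 10 Hz), the isosbestic reference is RANSAC-scaled to the
signal and divided out (dF/F), and traces are z-scored within animal
across the session (zdF/F). Signals are aligned to the first
risk-assessment onset (NoGo/Go) or the center crossing (CC) in ±3 s
windows binned at 1/15 s (90 bins), with per-window Gaussian smoothing
(σ = 4 samples).

**Inference.** Sequence-specific time courses are modeled with a
generalized estimating equation,

    zdff ~ type + bs(time, df = 4) + type : bs(time, df = 4),

Gaussian family, identity link, AR(1) working correlation within each
peri-event unit (animal × hemisphere × event), and cluster-robust
sandwich covariance (Mancl–DeRouen bias-corrected by default), with
joint Wald tests on coefficient blocks. Uncertainty uses the
animal-level bootstrap (1000 resamples; 95%/99% percentile bands);
time-resolved pairwise contrasts subtract the two types' bands, flagging
bins where the bands do not overlap.

## Worked example

Four synthetic animals, each a scripted 10-min session; segmentation,
preprocessing, alignment, GEE and bootstrap end to end:

```r
library(riskseq)

geom <- maze_geometry()
all_units <- list()
all_counts <- c(CC = 0L, NoGo = 0L, Go = 0L, CO = 0L)
for (a in 1:4) {
  script <- random_script(12, types = c("CC", "NoGo", "Go"),
                          seed = 42 + a, spacing = 45)
  cfg <- sim_config(session_duration = 600, sequence_script = script,
                    seed = 42 + a)
  sim <- simulate_trajectory(cfg)
  pm  <- simulate_photometry(cfg, sim$truth, animal = paste0("m", a))

  fx <- frame_features(sim$track, geom)
  fx$centroid_x <- sim$track$centroid_x
  fx$centroid_y <- sim$track$centroid_y
  seqs <- detect_sequences(fx, sim$events, geom)
  all_counts <- all_counts + counts_by_type(seqs)

  trace <- preprocess_photometry(pm)
  all_units[[a]] <- align_events(trace, seqs)
}
print(all_counts)
risk_assessment_index(all_counts)

units <- bind_units(all_units)
fit <- fit_gee(build_design(units))
wald_joint(fit, "interaction")
bands <- bootstrap_timecourse(units, n_resamples = 1000, seed = 7)
one_sample_significance(bands, level = "99")
```

This prints:

```
  CC NoGo   Go   CO
  15   14   19    0
risk assessment index: 0.688
AR(1) rho: 0.907
time x type interaction: chi2(8) = 37.34, p = 0.00154
```

The counts echo the 48 scripted bouts exactly (15 + 14 + 19, no CO
scripted), and 33 of 48 sequences involve risk assessment, hence index
0.688. The fitted working correlation (0.907) reflects the strong
within-trace autocorrelation of smoothed calcium signals. The
interaction test rejects because the simulator injects different
peri-event transients per type (CC elevated, NoGo intermediate, Go
suppressed), and the significance intervals from the 99% bootstrap bands
bracket the post-event window for each type — e.g. CC significant over
roughly [0.03, 1.10] s and Go over [−0.10, 1.17] s after its
risk-assessment onset (with four animals the bands are narrow-sample
percentile bands, so isolated short pre-event runs can appear; see the
methods vignette).

A command-line interface mirrors the pipeline:
`simulate`, `segment`, `preprocess`, `align`, `fit`, `report` — see
`?riskseq_cli`.

## Layout

- `R/` — geometry/zoning, pose I/O and features, event tables, sequence
  engine, photometry DSP, peri-event alignment, GEE, bootstrap,
  group-level statistics, simulator, CLI.
- `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code).
- `vignettes/riskseq-methods.Rmd` — models, parameter choices, numerical
  conventions, design decisions, known limitations.
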