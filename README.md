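# eegmicrostates

Resting-state EEG microstate and spectral-power analysis for small
clinical cohorts, written for studies of the kind where a handful of
eyes-closed recordings (here: an 18-channel legacy 10–20 montage at
200 Hz) must be preprocessed, summarized into band powers and microstate
statistics, and compared across small groups with exact and
covariate-adjusted tests. A synthetic EEG generator with known microstate
structure makes every stage testable without any clinical data.

## What it computes

**Microstates.** Resting EEG is parsed into brief (~50–120 ms)
quasi-stable scalp topographies. With the average-referenced potential
vector `v(t)` over `C` electrodes, global field power is the spatial
standard deviation

    GFP(t) = sqrt( (1/C) * sum_c v_c(t)^2 ).

Topographies at GFP peaks (≥ 10 ms apart; first 2500 per subject; GFP
outliers above mean + 2·SD excluded) are pooled over subjects and
clustered by a polarity-invariant *modified K-means* (K = 4, 300
restarts): a sample `u` joins the prototype maximizing the squared
spatial projection `(u·M_k)^2`, and each prototype is updated as the
dominant eigenvector of its cluster's outer-product sum. The four group
maps are assigned the archetype labels A–D against analytic templates,
back-fitted to every sample (polarity ignored), segments shorter than
30 ms are absorbed by their neighbours, and per-map statistics are
reported: mean duration (ms), occurrence (s⁻¹), coverage (%), and global
explained variance

    GEV_k = 100 * sum_{t: L(t)=k} GFP(t)^2 * corr^2(v(t), M_k) / sum_t GFP(t)^2.

**Spectral power.** Welch PSD (Hamming windows of one sampling-rate
length, 50 % overlap, averaged over 3-s epochs), relative power in
delta [1, 4), theta [4, 8), alpha [8, 13), beta [13, 30) Hz — the four
bands partition the 1–30 Hz total — and its unweighted channel average
(global relative power).

**Preprocessing.** Kaiser-window linear-phase FIR filters (1–70 Hz
band-pass, 45–55 Hz band-stop, 40 Hz low-pass before microstate
analysis; maximum pass/stopband deviation 0.001), zero-net-delay
application, 3-s epoching, Perrin spherical-spline interpolation of bad
channels, and common-average referencing.

**Group statistics.** Exact Fisher tests for 2×m contingency tables by
full enumeration, Kruskal–Wallis and exact Wilcoxon rank-sum tests,
ANCOVA (full-vs-reduced F with age and gender covariates) on
log-transformed features, Cohen's d, and descriptive (test-free)
summaries for strata too small to test.

## Worked example

Simulate one subject's eyes-closed EEG with known microstate dynamics
(mean dwell times 80/90/100/110 ms, SNR 2), then recover maps and
statistics:

```r
library(eegmicrostates)

sp  <- sim_spec(mean_durations_ms = c(80, 90, 100, 110), snr = 2,
                n_epochs = 50, seed = 1)
sim <- simulate_microstate_eeg(sp)

g     <- gfp(sim$epochs)
peaks <- find_gfp_peaks(g, min_distance_ms = 10)
U     <- select_peak_maps(sim$epochs, peaks, n_max = 2500, sd_mult = 2)
km    <- modified_kmeans(U, K = 4, restarts = 50, seed = 1)
maps  <- order_maps(km$maps, template_maps())
seg   <- reject_short_segments(backfit(sim$epochs, maps), min_dur_ms = 30)
compute_features(seg, g)
```

which prints

```
  label duration_ms occurrence_hz coverage_pct gev_pct
1     A        83.0          2.65         22.0    18.7
2     B        88.8          2.55         22.6    19.2
3     C       101.9          2.52         25.7    20.2
4     D       110.8          2.68         29.7    23.7
```

The estimated durations sit within a few ms of the generating 80–110 ms,
occurrences near the implied ~2.6 s⁻¹, coverage grows with dwell time as
it must, and all four recovered maps correlate > 0.99 with the
generating templates (`attr(maps, "template_corr")`). An exact test on a
small gender-by-group table:

```r
fisher_exact(rbind(c(3, 3, 2), c(3, 2, 3)))
#> <ms_test> Fisher exact (2 x 3, enumeration): p=1
```

The full pipeline (filtering → epoching → referencing → spectral and
microstate branches → feature table → group statistics) runs through
`run_pipeline()` or the CLI (`inst/cli/eegms`): subcommands `simulate`,
`preprocess`, `spectral`, `microstates fit`, `microstates backfit`,
`features`, `stats`, `run-all`, all driven by a JSON config whose
defaults are the study parameters above.

## Data formats

EDF/EDF+ (read), a plain-text delimited matrix format for
signals (`# fs=<Hz>` header, channel-name row, one row per sample),
TSV feature tables, TSV+JSON-sidecar microstate maps, and TSV
segmentations. See `vignettes/eeg-microstates-methods.Rmd` for the
modelling choices and their rationale.
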