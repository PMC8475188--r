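---
title: "Resting-state EEG microstates: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG microstates: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmicrostates)
```

This vignette documents the scientific model behind the package, the
parameters that matter and why they default to the values they do, what
the synthetic generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made. It states no
empirical result that the test suite does not itself compute.

## The microstate model

Multichannel resting EEG, average-referenced, can be described for most
of the time by one of a small number of quasi-stable scalp topographies
("microstates"), each lasting tens of milliseconds. The analysis has
four stages.

**1. Moment selection.** The topographic signal-to-noise is highest at
peaks of the global field power, the spatial standard deviation of the
average-referenced potential (population normalization, `1/C`; the
topography is zero-mean by construction, so this equals the spatial
RMS). Strict local maxima at least 10 ms apart are kept — among closer
peaks the larger wins, eliminated greedily from the largest — and, per
subject, the chronologically first 2500 peak topographies enter
clustering after excluding those whose GFP exceeds the mean + 2 SD of
the selected set (one-sided: only implausibly large, artifact-like maps
are removed).

**2. Polarity-invariant clustering.** Oscillatory generators reverse
sign within a state, so a topography and its negative are the same
microstate. The modified K-means treats map space as a set of axes
rather than directions: assignment maximizes the squared spatial
projection `(u · M_k)²` and the prototype update is the dominant
eigenvector of the cluster scatter `Σ u uᵀ` — the axis maximizing
explained topographic variance. Each restart draws K distinct samples
as initial prototypes (restart `r` uses `seed + r`, making the whole
procedure a pure function of the seed); empty clusters are reseeded from
the worst-fitted sample; iteration stops when the relative change of
explained variance falls below 1e-6 or after 100 iterations; the best of
the restarts by training GEV wins. K = 4 is the field's convention and
the default. Clustering is group-level only: all subjects' retained peak
maps are pooled and clustered once; no individual-subject maps are
estimated (the per-subject route exists but is not the default).

**3. Back-fitting and smoothing.** Every sample of the 40 Hz low-passed,
average-referenced EEG is labeled with the map of highest squared
spatial correlation, polarity ignored; there is no GFP floor, so labels
partition the recording and coverages sum to 100 %. Segments shorter
than 30 ms are treated as noise and absorbed: shortest first, each
interior short run is split at the cut that maximizes the summed squared
correlation of its samples with the two flanking maps, so each sample
joins the neighbour that fits it better. This formulation is a
deterministic variant of edge-peeling reassignment with two useful
invariants — it never invents a label and never increases the number of
runs. Runs touching an epoch boundary are exempt (they may be
truncations of longer runs), and runs never span epochs.

**4. Features.** Per map: duration = mean length of its maximal runs
(boundary-truncated runs included — a small downward bias at 3-s epochs,
noted below), occurrence = runs per second, coverage = percent of
samples, and GEV — the GFP²-weighted share of topographic variance the
map explains. GEV decomposes additively over maps.

### Archetype templates

The A–D labels are conventional. To make them reproducible without
empirical grand-average maps, the package builds analytic stand-ins on
the electrode positions: A and B are mirror-image diagonal gradients
(left-occipital→right-frontal and right-occipital→left-frontal, with the
lateral component weighted 1.2 : 0.8 against the anterior one so the
diagonals stay distinguishable from the axial map), C is the
occipital-to-frontal axial gradient, and D a fronto-central Gaussian
focal maximum (centre tilted 0.3 toward the nasion, width 0.5 in
unit-sphere chord distance — chosen so the pairwise absolute spatial
correlation of all four templates stays ≤ 0.7). Estimated maps are
matched to templates by the best of the 4! assignments under total
absolute correlation, and signs are flipped to correlate positively.
These are synthetic templates: labels are comparable within analyses
using this package, not literally identical to any published map set.

## Preprocessing

* **Filters.** Kaiser-window linear-phase FIRs: band-pass 1–70 Hz and
  band-stop 45–55 Hz on the continuous recording, 40 Hz low-pass on
  epochs entering the microstate branch. Maximum pass/stopband deviation
  0.001 (≙ 60 dB), the binding constraint; band edges are −6 dB
  (half-amplitude) cutoffs, the windowed-FIR convention; default
  transition widths 1 Hz at the band-pass low edge and 2 Hz elsewhere.
  Two details depart from the naive textbook design, both verified by
  FFT in the tests: each edge of a two-edge design is designed for half
  the requested ripple (the two edges' deviations superpose — near DC a
  1–70 Hz band-pass otherwise misses 0.001 by ~30 %), and a 0.5 dB
  margin is added to the design attenuation because Kaiser's published
  equations predict realized ripple only to ~0.4 dB. With
  `margin_db = 0` the textbook beta (5.653 at 60 dB) is reproduced.
  Filtering is one-pass with group-delay compensation and reflective
  edge padding, so output equals input length with zero net delay.
* **Interpolation.** Perrin spherical splines, order m = 4, Legendre
  series truncated at 7 terms, ridge 1e-5 on the spline matrix —
  standard parameters. More than 3 interpolated channels (of 18) warns.
* **Referencing.** Common average, applied after interpolation and again
  after the 40 Hz low-pass (idempotent; guards the zero-mean invariant
  every microstate computation relies on).
* **Epoching.** 3-s non-overlapping epochs; a trailing partial epoch is
  dropped. When a recording carries condition annotations (eyes-closed
  selection), each annotated interval is epoched separately and the
  epochs pooled, so no epoch spans a splice point — the continuous-time
  operations never see a discontinuity.
* **Out of scope.** ICA-based ocular/ECG artifact removal is a manual,
  visually-guided step and is deliberately not reimplemented; users of
  real data are expected to supply pre-cleaned recordings, and the
  synthetic data contains no such artifacts.

## Spectral analysis

Welch PSD with Hamming windows of exactly one sampling rate's worth of
samples (1 Hz resolution at 200 Hz), 50 % overlap within each 3-s epoch
(five windows per epoch), averaged over windows and epochs. Relative
power uses half-open bands delta [1, 4), theta [4, 8), alpha [8, 13),
beta [13, 30): at 1 Hz resolution the printed ".99" upper edges mean
"the next band's lower bin excluded". The total-power denominator is the
union of the four bands (1–30 Hz), not 0–Nyquist — the four relative
powers then partition 1, matching how such tables are reported; this is
a convention choice the source description leaves open, and it is the
one place a user comparing absolute scales should check.

## Group statistics

Fisher's exact test enumerates all 2×m tables with the observed margins
(multivariate hypergeometric; two-sided by summing probabilities ≤ the
observed one, with a 1e-12 slack for floating-point ties). The 2×3
variant is the default for a three-group gender table; pairwise 2×2
tests are available by subsetting. Kruskal–Wallis uses mid-ranks with
the tie correction and a chi-square reference. The Wilcoxon rank-sum
test is exact by enumeration for combined n ≤ 12 without ties (covering
the cohort sizes this package targets) and a tie- and
continuity-corrected normal approximation otherwise; two-sided p is
twice the smaller tail, capped at 1. The group comparison adjusted for
age and gender is the full-vs-reduced least-squares F
(`F = [(RSS_r − RSS_f)/(g−1)] / [RSS_f/(n−g−2)]`, gender coded 0/1,
computed from explicit design matrices via QR; a rank-deficient design
names the collinear columns). Features are natural-log transformed
first; zeros (a microstate that never occurred) are a structural
condition the caller must handle — no offset is silently added. Cohen's
d uses the (n−1)-weighted pooled SD, first argument minus second. No
multiple-testing correction is applied by default (none is described in
the source analysis); Holm adjustment is available to users via
`stats::p.adjust` on the returned table. Disease-duration strata (onset
< 1 year vs > 2 years) are summarized descriptively only — with n = 2
and n = 3 a test would be noise, so `stratified_summary()` deliberately
emits no statistics for them.

## The synthetic generator

`simulate_microstate_eeg()` draws, per 3-s epoch, a semi-Markov state
sequence — dwell times Gamma(shape 4) with per-state means, rounded to
samples with a 2-sample floor; uniform switching by default — and emits
`signal(t) = a(t) · M_{L(t)}` plus spatially white Gaussian noise scaled
to the requested signal-RMS/noise-RMS, then average-references. Default
dwell means (78/77/83/92 ms) and the implied occurrences (~2.5–3 s⁻¹)
sit in the range reported for eyes-closed adult EEG; default SNR 2.

The amplitude carrier `a(t)` deserves its paragraph. It is band-limited
noise around 10 Hz with a sign-preserving amplitude floor:
`a = depth·b + (1−depth)·sign(b)`, unit RMS, `depth = 0.8`. Three
failure modes forced this form, found empirically while validating the
full filter chain on noiseless data: (i) a strictly positive envelope
(rectified noise) concentrates its energy at DC and below ~2 Hz, which
the 1 Hz high-pass edge removes — the chain then subtracts a
slowly-varying mixture topography comparable to the signal itself and
back-fit accuracy collapses; (ii) a plain Gaussian carrier spends ~8 %
of samples near zero amplitude, where the small out-of-band residue of
the modulation decides the label; (iii) a constant amplitude has no GFP
peaks to select. The signed floor keeps the instantaneous amplitude away
from zero while the polarity reversals — unobservable to every
polarity-blind stage downstream — keep the signal oscillatory and inside
the filters' passband. The filter-chain stability test uses 200 ms
dwells: it is a test of spectral fidelity, and at ~85 ms dwells a ±1
sample blur in boundary localization per state switch alone costs
several percent accuracy regardless of the filters.

What the generator does **not** emulate: 1/f background spectra,
spatially correlated or non-stationary noise, ocular/muscle artifacts,
volume-conduction forward physics, and any dependence between dwell time
and amplitude. A green recovery test therefore establishes that the
estimator chain is correct under a fair idealization, not that it is
robust to every property of clinical EEG.

`simulate_band_signal()` builds each channel as an independent sum of
four FIR-band-passed noise components normalized to exact variance
fractions. The component filters are inset half a transition width
inside each nominal band: with shared band edges, any energy generated
on the edge itself would be attributed half to the neighbouring band by
a binned estimator, making "the prescribed fraction" ill-defined.

`simulate_cohort()` reproduces the target study design (6 controls, 5
presymptomatic carriers, 5 patients split 2 early / 3 late by symptom
duration) with group-level feature means and SDs taken from the reported
group statistics, ages and gender ratios likewise; the early/late split
carries a qualitative biphasic pattern on microstate D (early +15 %,
late −10 % — the source figure is qualitative, these factors are a fixed
choice). Features are drawn as truncated normals; optionally a
per-subject EEG is simulated instead, with group-specific dwell means.

## Numerical and API conventions

* Time is 0-based in samples; annotation intervals are half-open
  `[onset, onset + duration)` seconds.
* Every stochastic operation takes an explicit integer seed; K-means
  restart `r` uses `seed + r`. Same seed, same data ⇒ bit-identical
  output.
* Ties in assignment break to the lowest map index; `order_maps` ties
  (exactly equal permutation scores) resolve to the first permutation in
  lexicographic order.
* Degenerate inputs fail loudly: zero-GFP samples get fit 0 and the
  first label rather than NaN; a constant topography cannot be
  normalized into a map; empty strata are reported with n = 0 and
  missing moments.
* Boundary-truncated runs are *included* in duration means. With 3-s
  epochs and ~85 ms states this biases durations slightly downward
  (~2 runs per epoch touch a boundary); excluding them would bias
  occurrence/coverage consistency instead. The recovery tests bound the
  net effect.
* EDF channel labels are matched case-insensitively after stripping an
  `"EEG "` prefix and reference suffixes; the montage uses the legacy
  names T3/T4/T5/T6. How eyes-open/closed periods are marked in raw
  files is not standardized; this package expects EDF+ annotations (or
  matrix-format annotation headers) whose label is the configured
  condition string.

## Known limitations

* Group-level maps only by default; subject-level map variability is
  not modelled.
* The GEV of real cohorts is expected well below the synthetic values
  (group maps fitted to individual EEGs, plus real noise); no claim
  about absolute GEV levels is tested.
* Microstate syntax (transition probabilities) and model selection over
  K are out of scope.
* The exact Fisher enumeration is exponential in m and intended for the
  2–3 column tables of small-cohort demographics.
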