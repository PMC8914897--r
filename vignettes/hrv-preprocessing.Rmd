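---
title: "Physiologically constrained preprocessing of RR-interval series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiologically constrained preprocessing of RR-interval series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Ambulatory heart-rate-variability (HRV) recordings — RR intervals derived
from wearable ECG or PPG — arrive with two characteristic defects: *ectopic*
intervals (mostly spurious extra peak detections, occasionally missed beats)
and *gaps* where the sensor lost contact. Standard practice deletes the
non-physiological intervals and interpolates across the holes, which silently
breaks the defining property of a tachogram: each interval equals the
difference of its two beat timestamps. This package implements a
preprocessing approach that keeps that equality intact end to end, plus the
standard interpolation baselines, HRV feature extraction, and a
degradation/reconstruction harness for comparing the approaches by their
effect on a downstream classifier.

## The data model

An `rr_series` is a tibble with `time` (seconds since recording start,
strictly increasing; the instant of the beat *ending* the interval) and `rr`
(the interval, seconds). On clean data `rr[i] == time[i] - time[i-1]`
everywhere; `check_consistency()` reports the positions where that fails
while the timestamp difference still fits inside one physiological beat, and
`detect_gaps()` reports the adjacencies where it exceeds the longest
physiological interval. The two diagnostics partition all departures from
full consistency. All computation is in seconds; readers accept
`units = "ms"` and rescale on ingest.

`physio_bounds()` carries the four tunables:

* `rr_min = 0.3` s and `rr_max = 1.3` s — the physiological interval range
  (200 down to 46 beats/min). Anything outside is an artefact by definition.
* `max_deviation = 0.4` — the ceiling on the local beat-to-beat relative
  variation budget (twice the largest difference seen between successive
  normal intervals).
* `lookback = 10` — how many preceding intervals feed every local statistic
  (deviation budget, Gaussian fit, gap beat-count estimate).

The *deviation budget* at a beat is the mean absolute successive relative
difference of the `lookback` interval pairs immediately before it, capped at
`max_deviation`; with no preceding pairs the cap itself is used. A repair is
acceptable when it deviates from its neighbours no more than the signal
already varied locally.

## Ectopic filtering

Intervals above `rr_max` are deleted with their timestamps — a missed beat
cannot be reconstructed locally, so the hole is left for imputation.
Intervals below `rr_min` are treated as a spurious extra detection splitting
one true interval in two, and repaired by *merging*: a right merge adds the
short interval to its successor and places the sum at the successor's
timestamp; a left merge adds it to its predecessor and places the sum at the
short beat's own timestamp. Both conserve the spanned time exactly, so
consistency survives by construction — and when the ectopic really is a split
peak, the right merge restores the original interval bit for bit.

A merge is validated by three conditions: the merged value lies strictly
inside the bounds, and its deviations from the post-merge successor
(relative to the merged value) and predecessor (relative to that
predecessor) fit within the deviation budget. The branch order is: right
merge with all three conditions; else left merge with all three; else, if
both merged values exceed `rr_max`, delete the short beat and its successor;
if exactly one is within `rr_max`, force that merge through (the bounds
condition alone guarantees convergence); if both are within `rr_max`, the
deviation conditions are dropped in the same try-right-first order as long
as the deviations stay under the 40% ceiling, and only when both sides blow
past 40% does the smaller total error decide (ties go right).

Decisions that the procedure leaves open, resolved here:

* **Neighbour eligibility.** A merge partner must be an in-bounds interval
  whose adjacency with the short beat is itself consistent. A neighbour
  across a gap or a timestamp mismatch is treated as missing; merging across
  it would fabricate a value unrelated to the elapsed time. A short beat
  with no usable partner on either side is deleted
  (`delete_unmergeable` in the report).
* **Cascades.** Processing is a left-to-right pass over current positions; a
  merge's output is only re-examined on a subsequent full pass. Passes
  repeat to a fixpoint, at most five (two passes are rarely exceeded in
  practice).
* **Edges.** At the first/last beat only one side exists; if its sole
  candidate exceeds `rr_max` the beat is deleted (with its successor when
  the right candidate was the offender, mirroring the delete-pair branch).

Every action is logged in a `FilterReport` (`tidy()` on the result):
pass, position, timestamp, action, interval before and after. The test suite
cross-checks the whole decision table against an independently coded oracle
on every series of length at most six over a six-value interval grid
(about 56,000 cases).

## Gap imputation

Each gap is filled *backwards*. The first insertion point is
`t_end - rr_end` (the interval recorded at the gap's far side is trusted
data); every inserted interval is drawn from a Gaussian fitted to the up-to-
ten intervals ending at the gap's start (sample mean and n−1 standard
deviation), accepted only if it is in bounds and within the deviation budget
of its already-inserted successor (the predecessor does not exist yet while
filling backwards). When the remaining span to `t_start` drops below
`rr_max`, the closing interval is set to that residual — making the fill
tile the gap exactly — and validated against the bounds and both
neighbours; on failure the last two insertions are discarded and resampled,
and after every four failed closings the deviation budget is raised by 5
percentage points (read as +0.05 absolute, consistent with the other
percentages being absolute fractions), which guarantees termination.

Numerical and degenerate-input choices:

* Rejection sampling caps at 1000 draws per beat, then clamps into the
  intersection of the bounds and `mu ± 2 sigma`.
* With `sigma = 0` the sampler is deterministic, so a closing failure would
  recur forever; after the first closing failure a working sigma of at
  least 0.01 s is used. The zero-sigma happy path (constant fill plus exact
  residual) never hits a failure and stays exactly deterministic.
* The deviation budget for a gap is frozen from the pre-gap data;
  recomputing it from self-generated beats would be circular.
* A gap at the very start of a series fits its Gaussian on the intervals
  *after* the gap; with no data on either side the documented defaults
  `mu = 0.8` s, `sigma = 0.05` s apply.
* A pathological gap whose residual `span - rr_end` is below `rr_min`
  cannot be tiled within bounds at all (the inserted intervals' sum is
  fixed); the closing value is inserted anyway and flagged `forced` in the
  fill log. Beat deletion on in-bounds data can never produce one.
* Each gap consumes its own substream (`rng_seed + gap ordinal`), so fills
  are order-insensitive and a seed fully determines the output.

**Mismatch adjacencies.** Degradation can leave adjacencies whose timestamp
difference is at most `rr_max` yet disagrees with the recorded interval — a
deleted beat whose span still fits inside one physiological interval. These
are not gaps under the `rr_max` criterion, but `impute_dvc()` repairs them
with the same backward fill whenever the residual beyond the recorded
interval can hold a physiological beat; because the recorded interval at the
right edge is true data, a single deleted beat is restored *exactly*. Only
when the residual is too small for any beat is the interval reset to the
timestamp difference (the timestamps being the trusted observable). Without
this, no amount of gap filling could return a degraded series to full
consistency, and the repair measurably removes the largest artefacts
(intervals near `rr_max` written into much faster contexts).

## Interpolation baselines

The comparison methods deliberately reproduce standard practice: delete all
out-of-bounds intervals, estimate each gap's beat count as
`floor(gap duration / mean of the last ten intervals)` (a 1e-9 guard keeps
exact quotients on their floor), lay that many placeholders at *equally
spaced* timestamps (the estimate fixes the count, not the placement), and
fill their values from a 1-D interpolant of interval versus timestamp
fitted to all valid beats. `linear` uses straight segments, `pchip` the
shape-preserving piecewise cubic, `spline` a cubic spline with not-a-knot
end conditions (the common default in numerical libraries; implemented
in-package since no installed interpolator offers it, and verified against
an independent computation). No consistency repair is performed and
out-of-bounds spline excursions are kept, only flagged in the log: breaking
the timestamp–interval dependence is precisely the behaviour being compared
against. `deletion` stops after the deletion step.

## HRV features

Features are computed per sliding window — 5-min windows advanced by 1 min,
the usual compromise between stationarity and temporal resolution.
Conventions that vary across the literature, fixed here:

* SDNN is the n−1 standard deviation of the window's intervals, in ms,
  computed without re-filtering (artefacts introduced by a reconstruction
  method are deliberately left in — they are what the comparison measures).
* RMSSD uses the mean over the N−1 successive differences.
* NN50/pNN50 count successive differences strictly greater than 50 ms, as a
  percentage of N−1.
* Spectral powers: the tachogram is resampled at 8 Hz by cubic
  interpolation, mean-detrended only, and a Welch periodogram (Hann
  windows of up to 2 min, 50% overlap) is integrated over LF
  (0.04–0.15 Hz) and HF (0.15–0.4 Hz), in ms². LF needs 2 min of signal,
  HF 1 min; below that the feature is `NA`. ULF and VLF need recordings far
  longer than a sliding window and are not computed.
* Poincaré SD1/SD2 use the rotation identities
  `SD1² = Var(ΔRR)/2`, `SD2² = 2 Var(RR) − Var(ΔRR)/2`, so
  `SD1² + SD2² = 2 Var(RR)` holds identically; a negative SD2 radicand is
  clamped to zero.

`engineer_features()` appends, for every unordered pair of base features,
one product and one ratio column (zero denominators yield `NA`, never
infinities): `k` base features become `k²` columns. Not every engineered
column has a physiological reading; feature selection is left to the
classifier.

## Synthetic data and degradation

The generator lays beats down sequentially — so the output is consistent by
construction — with the instantaneous interval equal to a mean plus an LF
(default 0.1 Hz) and an HF (default 0.25 Hz) sinusoid plus white Gaussian
jitter scaled so the overall SDNN hits its target (a sinusoid of amplitude
`a` contributes `a²/2` of variance), plus an optional slow mean drift
(minutes-scale sinusoid, random phase) emulating within-recording
nonstationarity. Two presets encode the canonical autonomic signatures:
`relax` (mean RR 0.9 s, HF-dominant) and `stress` (mean RR 0.7 s,
LF-dominant, damped HF). `simulate_corpus()` emulates a multi-subject study
by drawing each series' physiology from per-condition ranges that overlap
the way real cohorts do — relaxed mean RR 0.70–0.98 s versus stressed
0.62–0.92 s, overlapping LF/HF amplitude ranges with shifted centres,
jitter 25–45 ms, drift amplitude 20–60 ms over a 4–10-min period. Without
heterogeneity and drift a classifier learns razor-thin per-recording
clusters (clean-data F1 pins at 1.0, where a realistic cohort sits well
below); with them the clean-data F1 lands around 0.9, leaving headroom for
degradation effects to show.

`degrade()` applies the benchmark protocol with ground truth retained:

* *Deletion*: `round(pct/100 · n)` beat-wise uniform deletions (timestamp
  and interval removed; survivors untouched). Uniform deletion yields
  geometric-length gap runs; `burst = TRUE` deletes contiguous runs
  instead, emulating bursty sensor dropouts. Percentages are of beat count,
  not recording time.
* *Ectopic injection*: a disjoint set of beats has its interval replaced by
  an ectopic pair — a spurious extra peak at the predecessor timestamp plus
  a uniform draw from [0.1 s, `rr_min`), with the true beat's interval
  shrunk to the remainder. This is the false-detection mechanism the merge
  filter is designed to undo, it keeps both adjacencies consistent, and it
  leaves exactly one sub-`rr_min` interval per injection. Only beats with
  at least `rr_min + 0.15` s of interval host an injection, so the
  remainder stays physiological.

The plan records deleted rows and original ectopic values, so the deletion
part is exactly invertible (`restore_deletions()`).

## The comparison harness

`run_grid()` reproduces the validation design: extract (engineered) features
from the original corpus; split the windows 80/20 stratified by label; train
a random forest on the training windows only; then, per missing-percentage,
degrade each series once and reconstruct it with *every* method from the
same degraded signal, re-featurise on the original window grid, and evaluate
the unchanged model on the same validation windows throughout — methods
differ only in how they repaired the signal, and the model is never
retrained on degraded data. F1 (stress positive) is
`TP / (TP + (FP + FN)/2)`.

The classifier is deliberately off-the-shelf (`ranger`). The shipped preset
maps the tuned scikit-learn configuration onto ranger's vocabulary: 500
trees, `mtry = ceiling(0.6 p)` for "max features 0.6", minimal node size 3
for "min samples split 3"; ranger offers no entropy split criterion, so the
Gini default is used. `tune_rf()` re-runs the 10-fold cross-validated grid
search when wanted. Engineered columns undefined in more than 20% of
training windows are dropped; remaining `NA`s are filled with training-set
medians (the harness must never peek at validation rows).

## What the tests do and do not show

The suite verifies the machinery: exhaustive agreement of the filter with an
independent decision-table oracle; zero out-of-bounds intervals and zero
consistency violations after filter+impute across a thousand fuzzed
degradations; exact span tiling; recovery of the fill distribution's mean;
the feature identities and spectral band placement; and, on the synthetic
corpus (ten subjects per condition, 10-minute recordings, ten seeds — sizes
chosen to exercise every gap-length regime while keeping the suite quick),
that reconstruction by the physiologically constrained method sustains
downstream classification at high missing-data rates at least as well as
linear interpolation.

Synthetic data cannot certify behaviour on real recordings: the generator
has no respiratory sinus arrhythmia coupling, no non-stationary drift, no
true arrhythmic beats (its "ectopics" are detection artefacts, per the
method's own hypothesis), and Gaussian short-term variability where real
tachograms are heavier-tailed. The Gaussian fill also whitens the spectrum
inside long gaps — inserted beats carry no LF/HF rhythm — so
frequency-domain features inflate with the missing fraction; this is a
property of the method itself, visible in the fill log and the
reconstruction-error tables, not an implementation artefact.
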