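# hrvdvc

Preprocessing of ambulatory heart-rate-variability (HRV) recordings given as
RR-interval time series, for researchers working with wearable ECG/PPG data
where ectopic detections and signal dropouts are the norm rather than the
exception.

A tachogram has a defining redundancy: each interval equals the difference of
its two beat timestamps, `RRᵢ = Tᵢ − Tᵢ₋₁`. Standard cleaning — delete
non-physiological intervals, interpolate across the holes — silently destroys
it. This package implements a preprocessing method that preserves it end to
end:

* **Filtering.** Intervals above 1.3 s are deleted (missed beats leave a gap
  for imputation). Intervals below 0.3 s are treated as spurious extra peak
  detections and *merged* into a neighbour — right merge `RRʳ = RRᵢ + RRᵢ₊₁`
  at `Tᵢ₊₁`, left merge `RRˡ = RRᵢ + RRᵢ₋₁` at `Tᵢ` — validated against
  physiological bounds and a local deviation budget `E₁₀` (the capped mean
  absolute successive relative difference of the preceding ten intervals).
  Merges conserve the spanned time exactly; when the ectopic really is a
  split peak, the right merge restores the true interval exactly.
* **Imputation.** Gaps are filled *backwards* from `T₁ = T_end − RR_end`
  with intervals sampled from `N(μ, σ²)` fitted to the ten intervals before
  the gap, each draw constrained by the bounds and the deviation budget; the
  closing interval is set to the residual span so the fill tiles the gap
  exactly, with a deterministic retry/relaxation rule that guarantees
  termination.
* **Baselines and features.** Linear / shape-preserving cubic (pchip) /
  cubic-spline interpolation with the gap beat count estimated as
  `floor(gap duration / mean RR)`; sliding-window HRV features (SDNN, RMSSD,
  NN50/pNN50, Welch LF and HF power, Poincaré SD1/SD2); pairwise
  product/ratio feature engineering.
* **Benchmark harness.** A seeded degradation protocol (random beat deletion
  plus ectopic injection, ground truth retained) and a comparison harness
  that scores each reconstruction method by the F1 of a random-forest stress
  classifier trained on clean data only.

## A worked example

```r
library(hrvdvc)

s <- simulate_preset("stress", duration_s = 600, seed = 5)   # 857 beats
d <- degrade(s, missing_pct = 20, ectopic_pct = 5, seed = 9) # 729 beats left

f <- filter_ectopics(d)
glance(f)
#>   n_beats n_actions n_deleted_long n_merged n_deleted_short n_passes
#> 1     686        43              0       43               0        1

imp <- impute_dvc(f, rng_seed = 3)
length(check_consistency(imp))       # 0: timestamp-interval equality restored
#> [1] 0
range(imp$rr)                        # all intervals physiological
#> [1] 0.5662399 1.2558927
nrow(imp)                            # beat count tracks the original (857)
#> [1] 855

hrv_features(imp)[1:2, 1:6]
#>      t0 n_beats  sdnn rmssd  nn50 pnn50
#> 1     0     429  46.4  52.4   145  33.9
#> 2    60     429  53.7  67.5   150  35.0
```

All 43 injected ectopics were resolved by merges (most of them exact
inverses of the injection), the 171 deleted beats were re-imputed from the
local Gaussian, and the window features sit close to the clean series
(SDNN ≈ 46 ms, RMSSD ≈ 52 ms before degradation; the excess RMSSD in later
windows is the uncorrelated-sample noise of the Gaussian fill, discussed in
the vignette).

Compare reconstruction methods by their downstream effect:

```r
corpus <- simulate_corpus(10, duration_s = 600, seed = 1)  # 10 subjects/class
g <- run_grid(corpus, eval_grid(missing_pcts = c(5, 20, 35),
                                methods = c("dvc", "linear", "pchip"),
                                seed = 1))
g
#> HRV reconstruction comparison: F1 = 0.889 on original data
#>   missing_pct   dvc linear pchip
#> 1           5 0.889  0.471 0.375
#> 2          20 0.889  0.696 0.636
#> 3          35 0.533  0.690 0.714
autoplot(g)
```

Single runs are noisy (a validation fold is ~24 windows, so F1 moves in
steps of several hundredths); averaged over ten seeds the comparison gives
DVC 0.88/0.83/0.73 at 5/20/35% missing versus 0.59/0.58/0.59 for linear
interpolation — the acceptance script and test suite recompute these.

A thin command-line wrapper over the same functions ships in
`inst/cli/hrvdvc.R` (`simulate`, `degrade`, `filter`, `impute`, `features`
subcommands).

## Documentation

The methods vignette (`vignettes/hrv-preprocessing.Rmd`) documents the model
and its assumptions, every tunable with units and defaults, the numerical
edge-case policies (degenerate sampler, unclosable residuals, cap
escalation), what the synthetic generator does and does not emulate, and the
design decisions taken where the procedure leaves choices open.
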