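# replicascan

Measures how reproducibly a nucleus-detection pipeline behaves across
technical replicate scans of the same histology slide.

Whole-slide images (WSIs) scanned twice under identical settings yield
slightly different nucleus segmentations: detections appear, vanish, or move
by fractions of a micron, and per-nucleus measurements (area, median
hematoxylin/eosin) fluctuate. `replicascan` quantifies this inter-scan
variability from the per-nucleus detection tables alone:

* **Alignment** — an iterative median-shift estimator corrects the small
  tissue placement offset between two scans (a least-squares affine fit is
  available for cross-setting ROI alignment).
* **Matching** — nuclei of the two scans are paired one-to-one by a
  two-round conflict-resolving nearest-neighbour procedure: each nucleus
  proposes to its Euclidean-nearest counterpart within a 10 µm × 10 µm
  window; when two nuclei want the same partner the smaller distance wins
  and losers are reconsidered in a second round. Leftover nuclei outside
  the overlap of the two aligned ROIs are *edged-out*; the rest are
  *unmatched*. Pooled percentages

  `matched% = 100 · 2·|pairs| / (n_A + n_B)`

  (plus unmatched% and edged-out%, summing to 100) summarise each pairwise
  comparison.
* **Agreement** — matched measurements are compared on the ratio scale:
  with `d_i = ln v_A − ln v_B`, the median and the 2.5%/97.5% quantiles of
  the `d_i` are back-transformed as `100·exp(·)`, giving a median ratio and
  limits of agreement (LOAs) in percent, with bootstrap percentile
  confidence intervals. 100% is perfect agreement; if the `d_i` are
  N(0, s²) the LOAs approach `100·exp(±1.96 s)`.
* **Synthesis** — a seeded generator (hard-core point process, positional
  jitter, global shift, drop-out, spurious small detections, multiplicative
  measurement noise, resolution emulation) produces realistic replicate
  detection tables so the whole pipeline can be exercised, benchmarked and
  power-analysed without any image data.
* **Orchestration** — `run_study()` runs a full multi-setting replicate
  design (all within-setting pairs, optional reference-standard and manual
  benchmark comparisons) and `render_report()` writes TSV/JSON reports.
  A thin CLI (`inst/cli/replicascan`) exposes `simulate`, `match`, `agree`,
  `summarize` and `run-study` subcommands.

## Worked example

```r
library(replicascan)

# three replicate "scans" of one synthetic ROI (220 x 220 um, ~1800 nuclei)
cfg <- synthetic_scan_config(seed = 42)
sim <- simulate_replicates(cfg, n_replicates = 3)
A <- sim$replicates[[1]]$detections
B <- sim$replicates[[2]]$detections
A
#> Detection set 'scan1' (ROI 'roi'): 1839 nuclei
#>   ROI [0, 220] x [0, 220] um, pixel size 0.11 um/px
#>   area: median 11.79 um^2, range 1.58-53.97

m <- match_patterns(A, B)     # align, then two-round matching
summary(m)
#> Nucleus match scan1 vs scan2: 1714 pairs (n_A = 1839, n_B = 1823)
#>   alignment shift applied to B: (-0.003, 0.011) um
#>   matched 93.61%, unmatched 6.39%, edged-out 0.00% (pooled)
#>   pair distance: median 0.516 um, 95th pct 1.147 um
#>   rounds: round 1: 1690, round 2: 24

fp <- matched_feature_pairs(m, A, B, "area_um2")
log_ratio_agreement(fp$v_A, fp$v_B, agreement_config(seed = 1),
                    feature = "area_um2")
#> Ratio-scale agreement of area_um2 (1714 matched pairs)
#>   median ratio 99.74% (95% CI 99.35-100.16)
#>   LOA 85.66% (CI 84.26-86.87) to 116.87% (CI 115.53-118.64)
```

Reading: 93.61% of the nuclei of this replicate pair found a one-to-one
partner within the search window; between matched partners, half the area
ratios lie within a hair of 100% (no systematic drift), and 95% of them
between ~86% and ~117% — exactly the spread implied by the generator's 5%
multiplicative measurement noise per scan (`100·exp(±1.96·√2·0.05)` ≈
87–115%). Unmatched nuclei are dominated by drop-out and spurious
detections; edged-out nuclei appear once a real inter-scan shift pushes ROI
borders out of overlap.

For a whole study (several settings × three replicates, reference scan,
manual benchmark), see `?run_study` and the package vignette.

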