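# numerotune

Numerosity — the number of discrete items in a view — is encoded by tuned
neural populations in a network of topographic cortical maps (NPC1–3, NTO,
NPO, and frontal NF). A central question is whether these populations,
localized with artificial dot displays, also respond selectively to the
number of *objects in natural scenes*. `numerotune` implements the full
computational chain needed to ask that question with fMRI, together with a
synthetic multi-subject data generator so the entire pipeline is testable
end to end without scanner data:

- **Stimulus generation** — non-overlapping dot arrays under constant
  total-area or constant dot-size control; the numerosity-sweep localizer
  timeline (1–7 dots ascending/descending around a 20-dot baseline, 3.9 s
  per numerosity) and the six-category block design (15 s blocks, 15 s
  rest, 30 items per block at 300 ms on / 200 ms off); synthetic
  natural-image fixtures with 1/f amplitude spectra and exact object-count
  annotations (high-numerosity counts on 10–42 with mean 19.42, SD 8.8).
- **BOLD simulation** — ground-truth voxel populations (numerosity-tuned,
  scenery-responsive, untuned-visual, null) pushed through a double-gamma
  HRF at TR = 1.5 s with AR(1) noise and drift; 256 volumes acquired, the
  first 8 discarded.
- **pRF estimation** — log-Gaussian numerosity population receptive
  fields. A voxel presented `n` items responds

  `r(n) = a · exp( −(ln n − ln μ)² / (2σ²) )`

  with preferred numerosity `μ` and tuning width `σ` (natural-log units),
  fitted per voxel by grid search plus optional continuous refinement, and
  selection of the populations preferring numerosity 1–3 at a
  variance-explained threshold.
- **Block-design GLM** — per-category responses in percent signal change,
  contrast t maps, and the scenery-based exclusion rule (voxels with
  t < 1.96 for scenery-vs-rest are dropped; an unmasked parallel table is
  always produced).
- **ROI inference** — subject × ROI × category response tables; exact
  one-sided Wilcoxon signed-rank tests (full enumeration of the null for
  small n) with Benjamini–Hochberg FDR correction; the headline
  low-vs-high numerosity comparison across maps.

## Worked example

```r
library(numerotune)

cfg <- numerotune_config(seed = 1, cohort = cohort_config(voxels_per_roi = 60))
report <- run_pipeline(cfg)
print(report)
#> numerotune pipeline report
#>   seed 1, config 8acbe2ee
#>   subjects: 7; voxels/subject: 540; selected tuned voxels: 78/87/92/87/80/79/77
#>   scenery exclusions per subject: 74/80/71/85/70/73/71
#>   low vs high numerosity (natural images), per map:
#>     NPC1  n=7  p=0.007812  p_adj=0.007812 *
#>     NPC2  n=7  p=0.007812  p_adj=0.007812 *
#>     NPC3  n=7  p=0.007812  p_adj=0.007812 *
#>     NPO   n=7  p=0.007812  p_adj=0.007812 *
#>     NTO   n=7  p=0.007812  p_adj=0.007812 *
```

Seven simulated subjects are generated; localizer runs are fitted with the
log-Gaussian pRF model; the populations preferring numerosity 1–3 are
selected; block-design GLMs yield per-category percent-signal responses;
and after scenery masking every non-frontal numerosity map shows
significantly higher responses to low- than to high-numerosity natural
images (paired one-sided Wilcoxon signed-rank across the 7 subjects:
p = 1/128 = 0.0078, the smallest attainable value, surviving FDR
correction across the five maps).

Individual stages are ordinary functions over tibbles:

```r
sample_high_numerosity(5, seed = 1)
#> [1] 12 14 19 34 11

sp <- amplitude_spectrum(fixture_image(3, size = 128, seed = 2))
print(sp)
#> Radially averaged amplitude spectrum (16 bins)
#>   log-log slope: -1.105 (SE 0.027)

fit <- fit_prf_grid(run)          # one localizer BoldRun (or a list)
tidy(fit)                         # per-voxel mu, sigma, amplitude, VE
select_tuned_voxels(fit, range = c(1, 3), ve_min = 0.3)
autoplot(sp); plot_roi_responses(report$roi_table)
```

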