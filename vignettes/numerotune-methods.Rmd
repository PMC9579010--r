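---
title: "Methods: models, synthetic data and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, synthetic data and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, what the synthetic data emulate (and deliberately do not), and
every numerical choice a maintainer might want to revisit.

## The question and the pipeline

Numerosity-tuned neural populations are classically localized with
artificial dot displays swept over 1–7 items. The pipeline asks whether
those same populations respond selectively to the number of *objects in
natural images*: it generates the two experimental timelines, simulates
multi-subject BOLD data with known ground truth, estimates per-voxel
numerosity tuning from the sweep runs, selects the populations preferring
numerosity 1–3, fits a block-design GLM to the six-category natural-image
experiment, applies a scenery-based voxel exclusion, and tests — per
numerosity map, across subjects — whether low-numerosity natural images
evoke larger responses than high-numerosity ones.

## The tuning model

A voxel's aggregate numerosity preference is modeled as a log-Gaussian
population receptive field (pRF): presented `n` items, the neural response
is

$$ r(n) = a \, \exp\!\left( - \frac{(\ln n - \ln \mu)^2}{2 \sigma^2} \right) $$

with preferred numerosity $\mu$ (stimulus counts) and tuning width
$\sigma$ (natural-log numerosity units). The log-Gaussian is symmetric on
a logarithmic numerosity axis — responses at $\mu k$ and $\mu / k$ are
equal — which matches the compressive scaling of numerosity perception.
The 20-dot baseline epochs of the sweep enter the model as ordinary
numerosity-20 events rather than as a separate regressor; this is the
simplest reading of the sweep protocol and makes every event carry a
numerosity.

## The shared forward model

Both the simulator and the fitter express a voxel's noiseless
percent-signal time course identically: the event train of each
(label, numerosity) group is sampled at 50 ms, convolved with a
double-gamma HRF (peak 6 s, undershoot 16 s, dispersions 1 s, undershoot
ratio 1/6, 32 s support, peak-normalized), averaged within each 1.5 s TR
window, and scaled so that a sustained 15 s stimulus of unit neural
amplitude peaks at 1. The 50 ms resolution avoids onset aliasing at the
650 ms and 500 ms stimulus asynchronies. Because the code path is shared,
the fitter's prediction reproduces a noiseless simulated voxel exactly —
a property the tests assert bitwise.

Amplitudes are therefore expressed in "sustained-response" units: a
tuned voxel's localizer modulation is substantially smaller than its
nominal amplitude because a 3.9 s epoch at a 46% duty cycle never reaches
the sustained plateau.

## What the synthetic cohort emulates

The default cohort mirrors the study design: 7 subjects; six numerosity
maps (NPC1–3, NTO, NPO, NF) with NF present in only 4 subjects; control
regions V1, LO and PPA; 4 localizer runs and 7 block runs per subject;
256 volumes acquired per block run at TR 1.5 s with the first 8 discarded
(248 retained; the 360 s task is followed by 12 s of trailing rest).
Voxel populations per ROI (200 voxels each by default): numerosity maps
mix 50% tuned, 20% scenery-responsive, 20% untuned-visual and 10% null
voxels; V1/LO are mostly untuned-visual; PPA mostly scenery-responsive.
Tuned voxels draw $\mu$ log-uniformly on [1, 7] and
$\sigma = 0.25 + 0.1\mu + \mathcal{N}(0, 0.05)$ (floored at 0.1),
reflecting the widely reported broadening of tuning with preferred
numerosity.

Noise is AR(1) with marginal SD 1.0% signal and lag-1 coefficient 0.3,
plus a per-voxel linear drift up to ±0.5% per run. Parameterizing the
*marginal* SD (innovations scaled by $\sqrt{1-\phi^2}$) makes the
empirical temporal SD of a null voxel equal the configured value by
construction.

Three generator choices deserve explanation:

- **Tuned amplitudes** (median 5% sustained units, log-normal spread
  0.25): real response amplitudes are only shown graphically in this
  literature, so they are free parameters. The default was chosen so that
  selection at variance explained ≥ 0.3 operates above 90%
  sensitivity/specificity against ground truth — the operating point at
  which the selection rule is meaningful. Given the duty-cycle attenuation
  above, this corresponds to roughly 2% peak-to-baseline localizer
  modulation, a realistic 7T figure.
- **Scenery responses of tuned voxels**: scenery images carry no
  numerosity, but tuned voxels in visual cortex are not silent to them. A
  tuned voxel responds its `scenery_gain` — drawn as
  amplitude × U(0, 0.5) — to a natural-image event without a numerosity.
  Without this, the scenery-based exclusion would remove the entire tuned
  selection, the opposite of the empirical observation that the exclusion
  *raises* the retained natural-image means. Making the gain proportional
  to the voxel's own amplitude reproduces that observation mechanically:
  the excluded voxels are preferentially weak responders. Only an event
  with neither a numerosity nor a recognized category label is an error
  for a tuned voxel.
- **High-numerosity object counts**: only the empirical moments
  (mean 19.42, SD 8.8 on 10–42) are known. A discretized log-normal
  truncated to [10, 42] cannot reach that SD at that mean (its attainable
  SD tops out near 8.67), so the sampler uses a discretized Beta scaled to
  [10, 42], with both shape parameters solved numerically by two-moment
  matching (residual below 1e-12). The interpretation "similar frequency"
  is thus read as moment-matched, not histogram-matched.

Synthetic natural images are random-phase 1/f-amplitude backgrounds with
`n` Gaussian-profile bright blobs standing in for objects (scenery is
blob-free texture). Blob contrast (0.25 image units at 2–4.5% image-width
SD) is modest so the inserted objects perturb the radially averaged
amplitude spectrum by less than the slope-fit tolerance; the acceptance
script verifies the mean absolute spectral exponent of generator output
stays at 1.0.

What the generator does **not** emulate: spatial structure (voxels are
exchangeable within an ROI; no topographic gradient, no smoothing, no
surface geometry), motion or physiological artifacts, between-run
registration error, HRF variability across subjects, and the semantic
richness of real natural images. Passing tests therefore demonstrate the
*computational chain* — estimation, selection, exclusion and inference
behave correctly where ground truth is known — not that real cortical
data would show these effects.

## Estimation and inference choices

- **pRF grid**: 25 log-spaced $\mu$ on [1, 10] × 20 log-spaced $\sigma$
  on [0.05, 3]. Per voxel, amplitude and baseline are profiled out by
  OLS, amplitude constrained non-negative (tuned responses are
  excitatory): candidates whose best amplitude would be negative get
  variance explained 0. VE = 1 − RSS/TSS, clipped to [0, 1]; constant
  voxel series are flagged invalid with VE 0. Argmax ties break to the
  first grid point (lowest $\mu$, then narrowest $\sigma$).
- **Refinement**: bounded L-BFGS-B over $(\ln\mu, \ln\sigma)$ from the
  grid optimum, never allowed to decrease VE (optimizer failures fall
  back to the grid fit with a warning). The pipeline default skips it:
  the $\mu$ grid step is ~4.6%, well inside the 10% recovery tolerance
  the package tests, and both $\mu$ and $\sigma$ are fitted freely (no
  width-versus-preferred linkage is imposed during fitting even though
  the generator uses one).
- **Selection**: preferred numerosity in the *closed* interval [1, 3] and
  VE ≥ 0.3. The VE default is configurable; an empty selection is a valid
  result (warned, propagated as missing means downstream).
- **GLM**: one regressor per category built from the actual 300 ms event
  train (not an idealized 15 s boxcar) so the noiseless identity with the
  simulator is exact; constant plus linear drift per run; runs combined
  by concatenation with per-run nuisance columns (simpler degrees-of-
  freedom bookkeeping than run averaging). Betas are rescaled to percent
  signal change as 100 × beta / (mean fitted run constant). No
  prewhitening by default — the tests document the one-sided type-I rate
  at t ≥ 1.96 (2.5% under white noise, inflated under AR(1) noise); an
  AR(1) variance-inflation correction `(1+φ̂)/(1−φ̂)` is available behind
  a flag.
- **Scenery exclusion**: voxels with scenery-vs-rest t < 1.96 are
  excluded from numerosity-map averaging; a voxel at exactly 1.96 is
  retained (the rule excludes strictly below). The cut is applied
  one-directionally as stated, although 1.96 is the two-sided 5% normal
  quantile. Control ROIs are never masked, and an unmasked table is
  always produced alongside.
- **Wilcoxon signed-rank**: zero differences are dropped (counted), ties
  share midranks. For n ≤ 25 the one-sided p is exact — the null
  distribution of the positive-rank sum over all 2ⁿ sign assignments of
  the observed ranks, computed by subset-sum dynamic programming on
  doubled midranks (identical to full enumeration, which the tests verify
  exhaustively for n ≤ 10). Above 25, a normal approximation with
  continuity and tie correction. With 7 subjects the smallest attainable
  one-sided p is 1/128 ≈ 0.0078; with 4 (the frontal maps) it is 1/16 =
  0.0625 — above 0.05, so frontal cells can never reach significance at
  this cohort size, which is why NF is excluded from the low-vs-high
  family.
- **FDR families**: per figure-analysis — one BH family over all
  ROI × category cells of a positivity analysis, one over the maps of the
  low-vs-high analysis (the dot-category analogue is its own family). A
  global family is available by passing the combined table.
- **Subjects are the experimental unit**: responses are averaged across
  runs and voxels within subject before testing; map responses average
  across hemispheres implicitly (the simulator does not distinguish
  them).

## Reproducibility

Every stage takes an explicit integer seed; the pipeline derives
per-stage, per-subject child seeds from one master seed, so stages are
independently re-runnable and two runs with the same configuration are
bitwise identical. The configuration hash is embedded in the report.

## Problem sizes

The package's own test suite exercises the full chain at reduced scale
(2–7 subjects, 16–60 voxels per ROI) and the acceptance script runs the
complete default configuration (7 subjects, 200 voxels per ROI, 9 ROIs,
11 runs each); both complete in minutes on one CPU. Matrix-form grid
search (all grid predictions against all voxels at once) is what keeps
the pRF stage cheap.

## Known limitations

- No spatial modeling: the scenery exclusion and selection operate per
  voxel, not on cortical surfaces or clusters; map delineation itself is
  out of scope (ROIs are given).
- The HRF is fixed and shared across subjects and voxels.
- The exact Wilcoxon path is quadratic in the rank sum and intended for
  the small cohort sizes of this design, not for hundreds of
  observations.
- The untuned-visual voxel model responds identically to every stimulus;
  it has no contrast- or category-dependent modulation, so it is a
  conservative null for numerosity selectivity but not a realistic V1
  model.
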