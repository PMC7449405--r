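---
title: "Adipocyte phenotyping from histology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adipocyte phenotyping from histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adipoquant)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. Nothing here states an empirical number that the
test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

Adipocytes in H&E sections are white lipid vacuoles enclosed by thin
eosin-stained membranes. The package treats cell-size measurement as a
four-stage inverse problem:

* **Tiling.** Slides are scanned with a fixed window (default 1024×1024 px,
  stride = window). Coordinates are 0-based, top-left origin, half-open
  windows `[x, x+T) × [y, y+T)`. Partial edge windows are *dropped*, not
  padded: padding would synthesize border content and bias area statistics at
  slide edges, and a fixed-size window contract keeps every downstream shape
  static. This edge rule is a package decision; nothing forces it at the
  level of the measurement model, and callers who must not lose edge tissue
  can pre-pad their rasters.
* **Triage.** A convolutional trunk, spatial average pooling, and one
  fully-connected 3-way softmax head classify tiles as adipocyte /
  non-adipocyte / empty. Only tiles whose adipocyte posterior strictly
  exceeds `posterior_threshold` (default 0.9) are segmented. The strictness
  matters: at the default threshold a posterior of exactly 0.90 is rejected.
  The intent of such a high cutoff is asymmetric error: contaminating the
  area distribution with vessels or smooth muscle (false positives) is worse
  than discarding usable tiles (false negatives), because tiles are abundant.
* **Segmentation.** A U-Net maps RGB tiles to per-pixel adipocyte
  probabilities. The loss is the equal-weight sum of pixelwise binary
  cross-entropy and a Dice loss `1 − softDice`, where
  `softDice = (2Σpg + s)/(Σp + Σg + s)` with smoothing `s = 1`. On binary
  inputs with `s = 0` the soft Dice equals the hard Dice coefficient
  (`soft_dice()` exposes this identity; the suite tests it). `Dice` of two
  empty masks is defined as 1 — agreement on absence — since the formula is
  0/0 there.
* **Quantification.** Maps are thresholded (`prob > t`, default `t = 0.5`;
  the threshold value is a package default, exposed in `qc_config()`),
  connected components are labeled (8-connectivity by default — the standard
  choice for blob-like objects; 4-connectivity is available for comparison),
  and pixel areas are calibrated by `area_um2 = area_px × mpp²`. The QC
  window keeps the *closed* interval [200, 16000] µm²: removal is strictly
  "less than 200" / "greater than 16000", so boundary areas are retained.
  Areas below the window are typically debris; above it, merged cells from
  failed staining. Border-touching cells are kept by default (the QC window
  already removes most fragments); `exclude_border` is available since
  clipped cells under-measure area.

Per sample and depot, the phenotype is the mean and SD of `n_cells = 500`
distinct cells drawn uniformly without replacement under a recorded seed;
mean, SD and variance are all computed on the same draw and all three are
emitted (study conventions differ on whether "size variability" means SD or
variance, so both columns exist). Samples with fewer than 500 detected cells
are excluded with a warning by default (`min_cells` overrides).
`monte_carlo_stability()` justifies the rule: for each subsample size *k* it
repeats the draw and reports the SD of the subsample means; the smallest *k*
whose dispersion falls below 5% of the full-sample SD is recommended. The 5%
criterion is this package's operationalization of "stable, low-variance
estimate" — the stability analysis itself fixes no unique cutoff.

## The built-in network engine

No deep-learning framework is part of the package's dependency set; instead
`src/nn.cpp` implements the two architectures directly in RcppArmadillo:
im2col-based 3×3 convolutions, 2×2 max pooling, nearest-neighbour
upsampling, ReLU, softmax/sigmoid heads, SGD with Nesterov momentum, Adam,
and the dice+BCE loss. Arithmetic is single precision; all randomness
(weight init, shuffling) flows from one integer seed through a self-contained
mt19937/Box–Muller generator, so a fixed seed reproduces training exactly
under single-threaded BLAS.

**Triage.** The reduced trunk (default) is three conv/pool blocks with
8-16-32 channels; `backbone_scale = "full"` provides a deeper/wider trunk
(16-32-64-64-96) behind the identical head and prediction interface. The
full trunk is randomly initialised — it is *not* a pretrained transfer
backbone, and the package deliberately does not bundle pretrained weights.
Training uses SGD with Nesterov momentum 0.9 and learning rate 1e-4, an
80:20 stratified train:validation split, 20 epochs of batch 16 (reduced
defaults). Inputs are fed at raw 0–255 pixel scale centred at 128; with the
softmax head initialised at zero this makes the head's effective gradient
scale compatible with the 1e-4 learning rate (an untrained model therefore
returns exactly uniform posteriors). A global gradient-norm guard (`clip_norm`)
exists purely as a blow-up safety net.

**U-Net.** Encoder of `depth` levels (default 4) with one 3×3 conv + ReLU
per level, channels doubling from `base_filters` (default 16) and capped at
4× base; bottleneck conv; decoder mirrors with nearest-neighbour upsampling
and skip concatenation; final 1×1 conv + sigmoid. The single-conv blocks and
the channel cap keep desk-scale CPU training tractable; `base_filters = 64`
and 1024² crops reproduce a full-scale setting. The optimizer is Adam at
1e-3 (the optimizer for this stage is a package choice; it is exposed in
`unet_config()`), 30 epochs of batch 4 by default. Training crops are
sampled at seeded uniform offsets from tile/mask pairs after the *source
tiles* are partitioned into train and validation sets, so no tile ever feeds
both; the reported validation Dice is the pooled (micro-averaged) hard Dice
over held-out crops at threshold 0.5. Inputs whose sides are not divisible
by `2^depth` are reflect-padded and the output cropped back.

## The synthetic data and what it can show

`simulate_adipose_tile()` renders cells as an additively weighted Voronoi
tessellation: target areas are drawn log-normal in µm² (strictly positive
and right-skewed, like real adipocyte area distributions; defaults centre
near 2800 µm² with log-SD 0.25 at mpp 0.4942, a common whole-slide scan
calibration), seeds are placed by dart throwing, each cell is limited to
1.25× its target radius, and a membrane of `membrane_width_px` is carved
along region boundaries. The returned per-cell areas are measured *from the
rendered mask itself*, so mask and area list are exactly consistent by
construction — the property the quantification tests exploit. Packing
failures (too many cells for the tile) raise an error; cells are never
silently dropped. The colour model is a fixed palette (white lumen, pink
membrane, pale background, dark nuclei for the dense class) with small
Gaussian jitter — enough contrast for triage and segmentation without
modelling stain physics.

`simulate_triage_tiles()` draws the three classes so that they are separable
by construction (empty tiles' mean intensity sits above a documented
brightness floor of 0.92; adipocyte tiles sit below it).
`simulate_cohort_phenotypes()` generates `mean_area` as a linear model in
the visceral-depot indicator, female indicator and standardized BMI plus
Gaussian noise. Default planted coefficients are −0.55 (depot), 0.45 (BMI
per SD) and −0.34 (female), matching effect sizes reported for adipocyte
area in SD units, and the default residual SD (0.83) makes the marginal
variance of the response approximately 1 so that recovered coefficients read
directly in SD units. `simulate_genotypes()` draws Hardy–Weinberg
genotypes at frequencies from `maf_range` and plants a phenotype effect per
SD of the risk score; linkage disequilibrium is deliberately not modelled.

What passing tests on these fixtures show: that the pipeline's *mechanics* —
contracts, calibration arithmetic, loss behaviour, splits, filters,
estimators — are correct, and that the networks can learn a segmentation
task of this geometry from small data. What they do not show: performance on
real H&E, which has stain variability, ischemic degradation, ruptured and
merged cells, out-of-focus regions and touching-cell ambiguity that the
generator intentionally omits.

## Statistical choices

* **RINT.** `qnorm((rank − 3/8)/(n + 1/4))` — the Blom offset, with average
  ranks for ties; the offset variant is a package choice among the standard
  family. Constant input is an error rather than a silent zero vector.
* **Meta-analysis.** Fixed effects: inverse-variance weights, normal-theory
  p-values. Random effects: DerSimonian–Laird — `Q` on fixed-effects
  weights, `tau² = max(0, (Q − (k−1))/(Σw − Σw²/Σw))`, re-weighting by
  `1/(se² + tau²)`. DL is the classical moment estimator and the default of
  the standard meta-analysis tooling; REML-type estimators are out of scope.
  `I² = max(0, (Q − df)/Q) × 100`, truncated at 0. The test suite checks the
  implementation against an independently written transcription of these
  formulas (agreement 1e-10) and against `metafor`.
* **HWE.** The exact conditional test (summing probabilities of heterozygote
  counts no more likely than the observed one), chosen over chi-square for
  robustness at low counts; applied to best-guess genotypes (dosages rounded
  to the nearest integer), since the filter is defined on imputed genotype
  data. Verified exhaustively against brute-force enumeration for all totals
  up to 200.
* **Variant QC order.** info → missingness → HWE → MAF → duplicate-position
  removal, each exclusion logged with its reason; filtering is idempotent.
* **GRS.** Dosages are aligned so the coded allele is the trait-increasing
  allele (flip `d → 2−d` when coded by the other allele; mismatching
  variants dropped with a warning; strand-ambiguous A/T and C/G variants
  flagged but retained by default, since resolving them needs frequency
  heuristics that can silently misalign). Missing dosages are mean-imputed
  per variant inside scoring — the standard behaviour of GWAS scoring tools —
  and the imputation count is reported.

## Numerical and degenerate-input conventions

* Selection, thresholding and QC comparisons are all *strict* where the
  defining wording is strict: posterior `> 0.9`, probability `> t`, QC keeps
  `[min, max]` inclusive.
* Ties in the triage argmax break by the fixed class order adipocyte <
  non_adipocyte < empty.
* `dice(∅, ∅) = 1`; `hwe_exact_p` of a monomorphic site is 1; `I²` and
  `tau²` truncate at 0; an intercept-only linear model returns the sample
  mean.
* Every generator and trainer takes an explicit integer seed and leaves the
  caller's RNG state untouched; derived sub-seeds are drawn deterministically
  from the parent seed.

## Problem sizes used by the checks

The shipped checks run at sizes a laptop core handles in minutes, chosen as
the smallest scales at which the respective behaviours are stable: the
segmentation surrogate trains the reduced U-Net (depth 4, base 16) on ~80
crops of 128² from 20 synthetic tiles and evaluates pooled Dice on ~9
held-out crops; the triage surrogate trains on 300 tiles (100 per class) at
64²; parameter-recovery checks use 3 cohorts × 500 samples and 500-replicate
null calibrations; the HWE oracle comparison enumerates all genotype
configurations up to total 200.

## Known limitations

* The networks are CPU-bound reimplementations at reduced scale; they share
  the architecture *family* and training contract with full-scale GPU
  pipelines, not their capacity.
* The synthetic renderer draws convex-ish, non-touching cells; watershed
  splitting of merged cells and shape descriptors beyond area are out of
  scope.
* Random-effects inference uses normal approximations; with very few
  cohorts (k ≈ 2–3) heterogeneity estimates are noisy, which is inherent to
  DL at small k.
* Proprietary pyramidal slide formats are not parsed; callers pre-convert
  to PNG/TIFF.
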