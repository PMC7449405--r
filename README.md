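# adipoquant

Adipocyte histology phenotyping in R: from whole-slide rasters to per-sample
cell-size phenotypes and cohort-level statistics.

## The problem

Adipose (fat) tissue grows either by making more adipocytes (hyperplasia) or
by enlarging the ones it has (hypertrophy), and adipocyte size tracks
cardiometabolic risk factors such as BMI. Measuring cell size at scale means
processing thousands of H&E histology slides, where adipocytes appear as
white lipid lumina bounded by thin eosin-stained membranes. `adipoquant`
implements that measurement pipeline end to end:

1. **Tiling** — slides are cut by a sliding window (default 1024×1024 px)
   into calibrated tiles; each tile carries its offsets and the slide's
   microns-per-pixel (mpp) factor.
2. **Triage** — a convolutional classifier assigns each tile a posterior over
   three classes (*adipocyte*, *non-adipocyte*, *empty*); only tiles with
   adipocyte posterior strictly above 0.9 go forward, trading false negatives
   for a very low false-positive rate.
3. **Segmentation** — a U-Net maps each retained tile to a per-pixel
   adipocyte probability map, trained with a dice + binary cross-entropy loss
   on seeded random crops whose train/validation splits never share a source
   tile. Performance is scored with the Dice overlap
   `Dice(A,B) = 2|A∩B| / (|A|+|B|)`.
4. **Quantification** — probability maps are thresholded (default 0.5),
   connected components become cells, pixel counts become areas via
   `area_um2 = area_px × mpp²`, and a QC window keeps areas in the closed
   interval [200, 16000] µm². Per sample and depot, the phenotype is the
   mean and SD of 500 cells drawn without replacement (a Monte-Carlo
   stability helper justifies the 500-cell rule).
5. **Statistics** — rank inverse normal transformation (Blom), per-cohort
   linear models, inverse-variance fixed-effects and DerSimonian–Laird
   random-effects meta-analysis with `I² = max(0, (Q − df)/Q)·100`, Bonferroni
   thresholds, and weighted genetic risk scores
   (`GRS_j = Σ_i w_i · dosage_ij`) with exact Hardy–Weinberg QC filtering and
   allele alignment.

Because real cohort slides are access-controlled, the package ships a
synthetic-data module that renders adipose-like tiles (weighted Voronoi
bubble tessellations with exact ground-truth masks and areas), cohort tables
with planted depot/sex/BMI effects, and genotype dosages with planted GRS
effects — so every stage is testable offline. The two networks run on a
compact built-in convolutional engine (RcppArmadillo) with SGD/Nesterov and
Adam optimizers; the reduced configurations train in minutes on one CPU core.

## Worked example

```r
library(adipoquant)

# 1. simulate calibrated tiles with exact ground truth
sim <- simulate_adipose_tile(tile_spec(seed = 7))
length(sim$areas_um2)         # [1] 5
round(sim$areas_um2)          # [1] 6656 2745 2488 1740 1408   (um^2)

# 2. triage: 300 labeled tiles, SGD + Nesterov momentum, 80:20 split
tt  <- simulate_triage_tiles(100, seed = 1)
fit <- train_triage(build_triage_model(triage_config(seed = 1)),
                    tt$tiles, tt$labels)
fit
#> <triage_fit> train accuracy 1.000, validation accuracy 1.000 (n_train 240, n_val 60)

# 3. segmentation: 80 seeded 128x128 crops, dice + BCE loss
seeds <- 1:20
sims  <- lapply(seeds, function(s) simulate_adipose_tile(tile_spec(seed = s)))
crops <- make_training_crops(lapply(sims, `[[`, "image"),
                             lapply(sims, `[[`, "mask"), 128, 80, seed = 1)
unet  <- train_unet(unet_config(seed = 1), crops)
unet$final_validation_dice    # ~1.00 on held-out crops (threshold 0.5)

# 4. quantify one tile
pm  <- predict_probability_map(unet, sim$image)
reg <- cell_region_table(pm, mpp = sim$spec$mpp, tile_id = "demo")
qc_filter_areas(reg, qc_config())   # areas within [200, 16000] um^2

# 5. cohort statistics: recover a planted depot contrast by random-effects meta
tabs <- lapply(1:3, function(i)
  simulate_cohort_phenotypes(cohort_spec(n_samples = 500, seed = i,
                                         cohort = paste0("c", i))))
res <- meta_association(do.call(rbind, tabs), "mean_area", "depotvisc",
                        covariates = c("sex", "age", "BMI"))
res$meta
#> <meta_result> random-effects over 3 studies
#>   beta -0.5208 (se 0.0309), p = 1.49e-63
#>   Q = 1.597, tau^2 = 0.0000, I^2 = 0.0%
```

The pooled visceral-vs-subcutaneous contrast recovers the planted −0.55
within sampling error, with no between-cohort heterogeneity — exactly what a
shared data-generating process should give.

`bonferroni_threshold()` reproduces the usual multiple-testing cutoffs, e.g.
`0.05/19 = 2.6e-3` (19 clinical phenotypes), `5e-8/2 = 2.5e-8` (two depots)
and `0.05/(3×2) = 0.008` (three risk scores × two depots).

A thin command-line front end (`inst/cli/adipoquant`) exposes the stages as
subcommands (`simulate`, `tile`, `triage-train`, `triage-classify`,
`triage-select`, `seg-train`, `seg-predict`, `quantify`, `phenotype`,
`stability`, `meta`, `grs-score`, `grs-assoc`, `run`), and
`run_pipeline()` wires them together with a YAML config, structured logging
of per-stage counts, and a provenance JSON recording seeds and thresholds.

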