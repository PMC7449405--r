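# Shared fixture builders. Everything is generated in code at test time;
# heavier objects are built once per session and memoised in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A quick, deliberately small triage fit (separable classes, so accuracy is
# high even at this scale).
tiny_triage_fit <- function() {
  cached("tiny_triage", function() {
    tt <- simulate_triage_tiles(20, seed = 42)
    cfg <- triage_config(epochs = 10L, seed = 42L)
    list(fit = train_triage(build_triage_model(cfg), tt$tiles, tt$labels, cfg),
         tiles = tt)
  })
}

# A tiny U-Net (depth 2) memorisation-scale fit on dense synthetic tiles.
tiny_unet_fit <- function() {
  cached("tiny_unet", function() {
    seeds <- adipoquant:::derive_seeds(7, 5)
    spec_for <- function(i, s) {       # dense, sparse and empty tiles
      n <- c(12L, 12L, 12L, 4L, 0L)[i]
      tile_spec(width_px = 128L, height_px = 128L, mpp = 2.0, n_cells = n,
                membrane_width_px = 3L, seed = s)
    }
    sims <- Map(function(i, s) simulate_adipose_tile(spec_for(i, s)),
                seq_along(seeds), seeds)
    crops <- make_training_crops(lapply(sims, `[[`, "image"),
                                 lapply(sims, `[[`, "mask"),
                                 64L, 15L, seed = 7, val_fraction = 0.2)
    cfg <- unet_config(depth = 3L, base_filters = 8L, crop_size_px = 64L,
                       epochs = 80L, seed = 7L)
    list(fit = train_unet(cfg, crops), crops = crops, sims = sims)
  })
}

# Synthetic "slides" (dense adipose rasters at mpp 2) plus a manifest TSV,
# written under a session temp dir; used by the pipeline tests.
synthetic_slide_set <- function() {
  cached("slides", function() {
    dir <- file.path(tempdir(), "aq_slides")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    seeds <- adipoquant:::derive_seeds(11, 4)
    rows <- list()
    for (i in seq_along(seeds)) {
      sim <- simulate_adipose_tile(tile_spec(width_px = 256L, height_px = 256L,
                                             mpp = 2.0, n_cells = 40L,
                                             membrane_width_px = 3L,
                                             seed = seeds[i]))
      path <- file.path(dir, sprintf("slide_%d.png", i))
      png::writePNG(unclass(sim$image), path)
      rows[[i]] <- data.frame(slide_id = sprintf("s%d", i), image_path = path,
                              mpp = 2.0, cohort = "synthetic",
                              depot = c("subq", "visc")[1 + (i - 1) %% 2],
                              sample_id = sprintf("sample_%d", ceiling(i / 2)))
    }
    manifest_path <- file.path(dir, "manifest.tsv")
    write.table(do.call(rbind, rows), manifest_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(dir = dir, manifest_path = manifest_path)
  })
}

# Models matched to the synthetic slides (trained at the same scale).
pipeline_models <- function() {
  cached("pipeline_models", function() {
    tt <- simulate_triage_tiles(20, seed = 5)
    tri_cfg <- triage_config(epochs = 12L, seed = 5L)
    tri <- train_triage(build_triage_model(tri_cfg), tt$tiles, tt$labels, tri_cfg)

    seeds <- adipoquant:::derive_seeds(6, 6)
    n_cells <- c(12L, 12L, 12L, 12L, 4L, 0L)
    sims <- Map(function(n, s)
      simulate_adipose_tile(tile_spec(width_px = 128L, height_px = 128L,
                                      mpp = 2.0, n_cells = n,
                                      membrane_width_px = 3L, seed = s)),
      n_cells, seeds)
    crops <- make_training_crops(lapply(sims, `[[`, "image"),
                                 lapply(sims, `[[`, "mask"),
                                 64L, 24L, seed = 6, val_fraction = 0.2)
    un <- train_unet(unet_config(depth = 2L, base_filters = 8L,
                                 crop_size_px = 64L, epochs = 20L, seed = 6L),
                     crops)
    list(triage = tri, unet = un)
  })
}

random_binary_mask <- function(h, w, p = 0.4, seed = 1) {
  adipoquant:::with_seed(seed, matrix(as.integer(runif(h * w) < p), h, w))
}
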