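# Pipeline orchestration: plain-text (YAML) configuration with strict
# validation, the tile -> triage -> segment -> quantify -> phenotype run, and
# a provenance record (seeds, thresholds, per-stage counts) for every run.

run_config_schema <- function() {
  list(
    seed = 1L,
    output_dir = "adipoquant_run",
    tile_size_px = 1024L,
    stride_px = NULL,            # defaults to tile_size_px
    n_cells = 500L,
    min_cells = NULL,            # defaults to n_cells
    triage = list(posterior_threshold = 0.9, learning_rate = 1e-4,
                  momentum = 0.9, train_fraction = 0.8,
                  backbone_scale = "reduced", epochs = 20L, batch_size = 16L),
    unet = list(depth = 4L, base_filters = 16L, crop_size_px = 128L,
                val_fraction = 0.10, epochs = 30L, batch_size = 4L,
                learning_rate = 1e-3),
    qc = list(min_area_um2 = 200, max_area_um2 = 16000, prob_threshold = 0.5,
              connectivity = 8L, exclude_border = FALSE))
}

merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s) in `", section, "`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  defaults[names(user)] <- user
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys, fills defaults
#' — QC bounds (200, 16000) um^2, posterior threshold 0.9, 500 cells per
#' sample — and checks every threshold's range via the stage config
#' constructors. The fully resolved configuration is echoed into the
#' provenance record of any run that uses it.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  schema <- run_config_schema()
  top <- merge_section(schema, config, "top level")
  for (s in c("triage", "unet", "qc"))
    top[[s]] <- merge_section(schema[[s]], config[[s]], s)
  if (is.null(top$stride_px)) top$stride_px <- top$tile_size_px
  if (is.null(top$min_cells)) top$min_cells <- top$n_cells

  top$seed <- assert_count(top$seed, "seed", min = 0L)
  top$tile_size_px <- assert_count(top$tile_size_px, "tile_size_px", min = 1L)
  top$stride_px <- assert_count(top$stride_px, "stride_px", min = 1L)
  top$n_cells <- assert_count(top$n_cells, "n_cells", min = 2L)
  top$min_cells <- assert_count(top$min_cells, "min_cells", min = 2L)

  # range checks delegated to the stage constructors (they name the key)
  tri <- top$triage
  top$triage_config <- triage_config(
    posterior_threshold = tri$posterior_threshold,
    learning_rate = tri$learning_rate, momentum = tri$momentum,
    train_fraction = tri$train_fraction, backbone_scale = tri$backbone_scale,
    epochs = tri$epochs, batch_size = tri$batch_size, seed = top$seed)
  un <- top$unet
  top$unet_config <- unet_config(
    depth = un$depth, base_filters = un$base_filters,
    crop_size_px = un$crop_size_px, val_fraction = un$val_fraction,
    epochs = un$epochs, batch_size = un$batch_size,
    learning_rate = un$learning_rate, seed = top$seed)
  qc <- top$qc
  top$qc_config <- qc_config(
    min_area_um2 = qc$min_area_um2, max_area_um2 = qc$max_area_um2,
    prob_threshold = qc$prob_threshold, connectivity = qc$connectivity,
    exclude_border = qc$exclude_border)

  class(top) <- "run_config"
  top
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> seed %d, tiles %d px (stride %d), QC [%g, %g] um^2, posterior > %g, %d cells/sample\n",
              x$seed, x$tile_size_px, x$stride_px, x$qc$min_area_um2,
              x$qc$max_area_um2, x$triage$posterior_threshold, x$n_cells))
  invisible(x)
}

read_slide_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Run the full phenotyping pipeline
#'
#' Executes tile -> triage -> segment -> quantify -> phenotype over every
#' slide in the manifest, writes each intermediate table under the output
#' directory, and records provenance (configuration echo and hash, seeds, and
#' in/out counts per stage) as JSON. Identical configuration and seed
#' reproduce byte-identical outputs. Any stage error aborts with the stage
#' name and the offending item.
#'
#' @param config A [validate_config()] result (or path/list accepted by it).
#' @param manifest A [read_slide_manifest()] result.
#' @param triage_model A trained `triage_fit` (or `triage_model`).
#' @param unet_model A trained `adipocyte_unet`.
#' @param out_dir Output directory (default from the config).
#' @return A list with `phenotypes`, `regions`, `posteriors`, `provenance`
#'   (all also written to `out_dir`).
#' @export
run_pipeline <- function(config, manifest, triage_model, unet_model,
                         out_dir = config$output_dir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  stopifnot(inherits(manifest, "slide_manifest") || is.data.frame(manifest))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  counts <- list(slides = nrow(manifest), tiles = 0L, classified = 0L,
                 selected = 0L, regions = 0L, regions_after_qc = 0L,
                 phenotype_rows = 0L)
  all_post <- list()
  all_regions <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    img <- stage("read", read_slide_image(row$image_path))
    tiles <- stage(paste0("tile[", row$slide_id, "]"),
                   tile_image_grid(img, config$tile_size_px, config$stride_px,
                                   mpp = row$mpp, slide_id = row$slide_id))
    counts$tiles <- counts$tiles + length(tiles)
    if (!length(tiles)) next

    ids <- vapply(tiles, function(t)
      sprintf("%s_%d_%d", row$slide_id, attr(t, "x_offset_px"),
              attr(t, "y_offset_px")), character(1))
    post <- stage(paste0("triage[", row$slide_id, "]"),
                  classify_tiles(triage_model, tiles, tile_id = ids))
    counts$classified <- counts$classified + nrow(post)
    post$slide_id <- row$slide_id
    all_post[[length(all_post) + 1L]] <- post

    sel <- select_adipocyte_tiles(post, config$triage$posterior_threshold)
    counts$selected <- counts$selected + length(sel)
    for (j in which(ids %in% sel)) {
      pm <- stage(paste0("segment[", ids[j], "]"),
                  predict_probability_map(unet_model, tiles[[j]]))
      reg <- stage(paste0("quantify[", ids[j], "]"),
                   cell_region_table(pm, mpp = row$mpp, tile_id = ids[j],
                                     sample_id = row$sample_id,
                                     depot = row$depot,
                                     config = config$qc_config))
      counts$regions <- counts$regions + nrow(reg)
      all_regions[[length(all_regions) + 1L]] <- reg
    }
  }

  posteriors <- if (length(all_post)) do.call(rbind, all_post) else
    data.frame(tile_id = character(0), p_adipocyte = numeric(0),
               p_non_adipocyte = numeric(0), p_empty = numeric(0),
               argmax = character(0), slide_id = character(0))
  regions <- if (length(all_regions)) do.call(rbind, all_regions) else
    data.frame(sample_id = character(0), depot = character(0),
               tile_id = character(0), region_id = integer(0),
               area_px = integer(0), area_um2 = numeric(0),
               touches_border = logical(0))

  regions_qc <- stage("qc_filter", qc_filter_areas(regions, config$qc_config))
  counts$regions_after_qc <- nrow(regions_qc)

  phenotypes <- if (nrow(regions_qc)) {
    stage("phenotype",
          suppressWarnings(phenotype_table(regions_qc, n_cells = config$n_cells,
                                           seed = config$seed,
                                           min_cells = config$min_cells)))
  } else {
    data.frame(sample_id = character(0), depot = character(0),
               n_cells_detected = integer(0), n_cells_used = integer(0),
               mean_area_um2 = numeric(0), sd_area_um2 = numeric(0),
               var_area_um2 = numeric(0), sufficient = logical(0),
               seed = integer(0))
  }
  counts$phenotype_rows <- nrow(phenotypes)

  # provenance: echoed config, its hash, seeds and the stage ledger
  cfg_plain <- unclass(config)
  cfg_plain$triage_config <- NULL
  cfg_plain$unet_config <- NULL
  cfg_plain$qc_config <- NULL
  cfg_file <- file.path(out_dir, "config_echo.yaml")
  yaml::write_yaml(cfg_plain, cfg_file)
  provenance <- list(config = cfg_plain,
                     config_md5 = unname(tools::md5sum(cfg_file)),
                     seed = config$seed,
                     counts = counts)

  write.table(posteriors, file.path(out_dir, "tile_posteriors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(regions_qc, file.path(out_dir, "cell_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(phenotypes, file.path(out_dir, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(phenotypes = phenotypes, regions = regions_qc,
                 posteriors = posteriors, provenance = provenance))
}
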