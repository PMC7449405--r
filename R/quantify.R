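# From probability maps to QC-filtered cell areas and per-sample phenotypes.
#
# Areas are measured as connected-component pixel counts and calibrated to
# um^2 with area_um2 = area_px * mpp^2. The QC window keeps the closed
# interval [min_area_um2, max_area_um2]: the removal rule is strictly
# "less than" / "greater than", so boundary areas are retained.

#' Quantification / QC configuration
#'
#' @param min_area_um2,max_area_um2 QC window in um^2 (defaults 200 and
#'   16000); areas exactly on a boundary are kept.
#' @param prob_threshold Probability-map threshold in (0, 1), default 0.5.
#' @param connectivity Foreground connectivity, 4 or 8 (default 8).
#' @param exclude_border Drop regions touching the tile border (default FALSE).
#' @param fill_holes Reserved switch for hole filling before measurement;
#'   off by default and not applied unless set.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(min_area_um2 = 200, max_area_um2 = 16000,
                      prob_threshold = 0.5, connectivity = 8L,
                      exclude_border = FALSE, fill_holes = FALSE) {
  assert_scalar_number(min_area_um2, "min_area_um2", 0, strict_lower = TRUE)
  assert_scalar_number(max_area_um2, "max_area_um2", 0, strict_lower = TRUE)
  if (min_area_um2 >= max_area_um2)
    stop("min_area_um2 must be smaller than max_area_um2", call. = FALSE)
  assert_scalar_number(prob_threshold, "prob_threshold", 0, 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 prob_threshold = prob_threshold,
                 connectivity = as.integer(connectivity),
                 exclude_border = isTRUE(exclude_border),
                 fill_holes = isTRUE(fill_holes)),
            class = "qc_config")
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability strictly exceeds `t`.
#'
#' @param prob_map Numeric matrix in \[0, 1\] (a `probability_map`).
#' @param t Threshold in (0, 1).
#' @return A `segmentation_mask` (integer 0/1 matrix).
#' @export
threshold_map <- function(prob_map, t = 0.5) {
  assert_scalar_number(t, "t", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  m <- unclass(prob_map)
  if (!is.matrix(m) || !is.numeric(m))
    stop("`prob_map` must be a numeric matrix", call. = FALSE)
  structure(matrix(as.integer(m > t), nrow(m), ncol(m)),
            class = "segmentation_mask")
}

#' Label connected foreground regions and measure pixel areas
#'
#' Each maximal connected foreground component (4- or 8-connectivity) is one
#' region; `area_px` is its pixel count and `touches_border` is set iff any of
#' its pixels lies on the first/last row or column.
#'
#' @param mask Binary 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return A data.frame (region_id, area_px, touches_border).
#' @export
label_regions <- function(mask, connectivity = 8L) {
  m <- check_binary_mask(mask, "mask")
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  lab <- cpp_label_regions(matrix(as.integer(m), nrow(m), ncol(m)),
                           as.integer(connectivity))
  k <- max(lab)
  if (k == 0L)
    return(data.frame(region_id = integer(0), area_px = integer(0),
                      touches_border = logical(0)))
  areas <- tabulate(lab[lab > 0L], nbins = k)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  data.frame(region_id = seq_len(k), area_px = areas,
             touches_border = seq_len(k) %in% border_labels)
}

#' Convert a pixel area to square microns
#'
#' @param area_px Pixel count (vectorized, non-negative).
#' @param mpp Microns per pixel (positive).
#' @return `area_px * mpp^2`.
#' @export
pixels_to_um2 <- function(area_px, mpp) {
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop("`mpp` must be a single positive number", call. = FALSE)
  if (any(area_px < 0)) stop("`area_px` must be non-negative", call. = FALSE)
  area_px * mpp^2
}

#' Build a cell-region table for one tile
#'
#' Thresholds the probability map (if given a map rather than a mask), labels
#' regions, converts areas to um^2 and attaches tile/sample metadata.
#'
#' @param x A `probability_map` or binary mask.
#' @param mpp Microns per pixel.
#' @param tile_id,sample_id,depot Metadata carried into the table.
#' @param config A [qc_config()] (controls threshold and connectivity; the
#'   area filter itself is applied separately by [qc_filter_areas()]).
#' @return A data.frame (sample_id, depot, tile_id, region_id, area_px,
#'   area_um2, touches_border).
#' @export
cell_region_table <- function(x, mpp, tile_id = NA_character_,
                              sample_id = NA_character_, depot = NA_character_,
                              config = qc_config()) {
  mask <- if (is_binary_matrix(unclass(x))) unclass(x)
          else unclass(threshold_map(x, config$prob_threshold))
  reg <- label_regions(mask, config$connectivity)
  data.frame(sample_id = sample_id, depot = depot, tile_id = tile_id,
             region_id = reg$region_id, area_px = reg$area_px,
             area_um2 = pixels_to_um2(reg$area_px, mpp),
             touches_border = reg$touches_border,
             stringsAsFactors = FALSE)
}

#' QC-filter a cell-region table
#'
#' Rows are kept iff `min_area_um2 <= area_um2 <= max_area_um2` (strict
#' removal below/above, boundaries kept). With `exclude_border`,
#' border-touching regions are also removed. Idempotent.
#'
#' @param table A cell-region table with at least `area_um2` (and
#'   `touches_border` if `exclude_border` is set).
#' @param config A [qc_config()].
#' @return The filtered table (row count never exceeds the input's).
#' @export
qc_filter_areas <- function(table, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"), "area_um2" %in% names(table))
  keep <- !(table$area_um2 < config$min_area_um2) &
          !(table$area_um2 > config$max_area_um2)
  if (config$exclude_border) {
    stopifnot("touches_border" %in% names(table))
    keep <- keep & !table$touches_border
  }
  table[keep, , drop = FALSE]
}

#' Per-sample phenotype from QC-filtered areas
#'
#' Draws `n_cells` distinct cells uniformly without replacement (seeded) and
#' computes the mean, SD and variance of their areas on that same draw. If
#' fewer than `n_cells` areas are available the sample is flagged
#' (`sufficient = FALSE`); by default such samples are excluded from the
#' phenotype table assembled by [phenotype_table()].
#'
#' @param areas Numeric vector of QC-filtered areas (um^2).
#' @param n_cells Cells to draw (default 500; at least 2).
#' @param seed Integer seed recorded in the output.
#' @param sample_id,depot Metadata.
#' @return A one-row data.frame (sample_id, depot, n_cells_detected,
#'   n_cells_used, mean_area_um2, sd_area_um2, var_area_um2, sufficient, seed).
#' @export
sample_phenotype <- function(areas, n_cells = 500L, seed = 1L,
                             sample_id = NA_character_, depot = NA_character_) {
  n_cells <- assert_count(n_cells, "n_cells", min = 2L)
  seed <- assert_count(seed, "seed", min = 0L)
  n_det <- length(areas)
  if (n_det >= n_cells) {
    used <- with_seed(seed, areas[sample.int(length(areas), n_cells)])
    sufficient <- TRUE
  } else {
    used <- areas
    sufficient <- FALSE
  }
  data.frame(sample_id = sample_id, depot = depot,
             n_cells_detected = n_det, n_cells_used = length(used),
             mean_area_um2 = if (length(used)) mean(used) else NA_real_,
             sd_area_um2 = if (length(used) > 1L) sd(used) else NA_real_,
             var_area_um2 = if (length(used) > 1L) var(used) else NA_real_,
             sufficient = sufficient, seed = seed,
             stringsAsFactors = FALSE)
}

#' Assemble a phenotype table across samples
#'
#' @param region_table QC-filtered cell-region table covering all samples.
#' @param n_cells Cells per sample x depot (default 500).
#' @param seed Base seed; each sample x depot gets a derived seed.
#' @param min_cells Minimum detected cells required to report a row; defaults
#'   to `n_cells` (the under-`n_cells` samples are dropped with a warning).
#' @return Data.frame with one row per sample x depot that passed the rule.
#' @export
phenotype_table <- function(region_table, n_cells = 500L, seed = 1L,
                            min_cells = n_cells) {
  key <- interaction(region_table$sample_id, region_table$depot, drop = TRUE)
  groups <- split(region_table, key)
  seeds <- derive_seeds(seed, length(groups))
  rows <- Map(function(g, s) {
    sample_phenotype(g$area_um2, n_cells = n_cells, seed = s,
                     sample_id = g$sample_id[1], depot = g$depot[1])
  }, groups, seeds)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dropped <- out$n_cells_detected < min_cells
  if (any(dropped))
    warning(sum(dropped), " sample-depot group(s) had fewer than ", min_cells,
            " cells and were excluded", call. = FALSE)
  out[!dropped, , drop = FALSE]
}

#' Monte-Carlo stability of the subsampled mean
#'
#' For each subsample size `k`, repeats the phenotype draw `n_reps` times with
#' distinct derived seeds and reports the dispersion (SD) of the subsample
#' means. The attribute `recommended_k` is the smallest `k` whose dispersion
#' falls below `frac` (default 5%) of the full-sample SD — the rule this
#' package uses to operationalize "how many cells are enough".
#'
#' @param areas Numeric vector of cell areas.
#' @param k_grid Increasing vector of subsample sizes (each <= length(areas)).
#' @param n_reps Replicates per k (>= 2).
#' @param seed Base seed.
#' @param frac Stability criterion as a fraction of the full-sample SD.
#' @return Data.frame (k, sd_of_subsample_means) with attribute
#'   `recommended_k` (NA when no k qualifies).
#' @export
monte_carlo_stability <- function(areas, k_grid, n_reps = 100L, seed = 1L,
                                  frac = 0.05) {
  n_reps <- assert_count(n_reps, "n_reps", min = 2L)
  if (any(k_grid > length(areas)))
    stop("every k must be at most the number of available cells", call. = FALSE)
  if (any(k_grid < 1L)) stop("k must be positive", call. = FALSE)
  seeds <- derive_seeds(seed, length(k_grid) * n_reps)
  sds <- vapply(seq_along(k_grid), function(i) {
    k <- k_grid[i]
    means <- vapply(seq_len(n_reps), function(r) {
      s <- seeds[(i - 1L) * n_reps + r]
      mean(with_seed(s, areas[sample.int(length(areas), k)]))
    }, numeric(1))
    sd(means)
  }, numeric(1))
  out <- data.frame(k = k_grid, sd_of_subsample_means = sds)
  full_sd <- sd(areas)
  ok <- which(sds <= frac * full_sd)
  attr(out, "recommended_k") <- if (length(ok)) k_grid[min(ok)] else NA_integer_
  attr(out, "criterion") <- frac
  out
}
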