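# Probability-map thresholding, region labeling, calibration, QC filtering,
# phenotype subsampling and Monte-Carlo stability.

test_that("threshold_map is strict, idempotent and monotone", {
  m <- matrix(c(0.4, 0.6, 0.5, 0.9), 2, 2)
  out <- threshold_map(m, 0.5)
  expect_identical(unclass(out), matrix(c(0L, 1L, 0L, 1L), 2, 2))  # 0.5 -> 0

  bin <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_identical(unclass(threshold_map(bin, 0.5)), matrix(as.integer(bin), 2, 2))

  pm <- matrix(runif(400), 20, 20)
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8),
                  function(t) sum(unclass(threshold_map(pm, t))), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(threshold_map(m, 0), "t")
  expect_error(threshold_map(m, 1), "t")
})

test_that("label_regions counts components per connectivity definition", {
  m <- matrix(0L, 8, 8)
  m[2:3, 2:3] <- 1L
  m[6:7, 6:7] <- 1L
  reg <- label_regions(m, 8L)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$area_px, c(4L, 4L))
  expect_false(any(reg$touches_border))

  # two pixels touching only diagonally
  d <- matrix(0L, 4, 4); d[2, 2] <- 1L; d[3, 3] <- 1L
  expect_equal(nrow(label_regions(d, 8L)), 1L)
  expect_equal(nrow(label_regions(d, 4L)), 2L)

  expect_equal(nrow(label_regions(matrix(0L, 5, 5))), 0L)
  expect_error(label_regions(matrix(0.3, 3, 3)), "binary")

  # border flag
  b <- matrix(0L, 5, 5); b[1, 3] <- 1L; b[3, 3] <- 1L
  reg_b <- label_regions(b, 4L)
  expect_equal(reg_b$touches_border, c(TRUE, FALSE))
})

test_that("labeling agrees with an independent flood fill on random masks", {
  for (s in 1:6) {
    m <- random_binary_mask(36, 30, p = 0.42, seed = s)
    for (conn in c(4L, 8L)) {
      mine <- label_regions(m, conn)
      oracle <- oracle_label_flood(m, conn)
      expect_equal(nrow(mine), max(oracle))
      expect_equal(sort(mine$area_px),
                   sort(as.integer(table(oracle[oracle > 0]))))
    }
    # pixel conservation: region areas sum to the foreground count
    expect_equal(sum(label_regions(m, 8L)$area_px), sum(m))
  }
})

test_that("pixel-to-micron conversion is exact and quadratic in mpp", {
  expect_equal(pixels_to_um2(100, 1), 100)
  expect_equal(pixels_to_um2(100, 0.4942), 100 * 0.4942^2)  # 24.4234 um^2
  expect_equal(pixels_to_um2(100, 0.4942), 24.42336, tolerance = 1e-6)
  expect_equal(pixels_to_um2(1, 0.193), 0.037249)
  expect_equal(pixels_to_um2(37, 2 * 0.7), 4 * pixels_to_um2(37, 0.7))
  expect_error(pixels_to_um2(10, 0), "mpp")
  expect_error(pixels_to_um2(-1, 1), "non-negative")
})

test_that("QC keeps the closed [min, max] interval and is idempotent/monotone", {
  tab <- data.frame(area_um2 = c(150, 200, 5000, 16000, 16500),
                    touches_border = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  kept <- qc_filter_areas(tab, qc_config())
  expect_equal(kept$area_um2, c(200, 5000, 16000))     # boundaries kept
  expect_identical(qc_filter_areas(kept, qc_config()), kept)

  expect_equal(nrow(qc_filter_areas(tab[0, ], qc_config())), 0L)

  # widening the window never removes kept rows
  wide <- qc_filter_areas(tab, qc_config(min_area_um2 = 100,
                                         max_area_um2 = 20000))
  expect_true(all(kept$area_um2 %in% wide$area_um2))

  # border exclusion removes the flagged row
  noborder <- qc_filter_areas(tab, qc_config(exclude_border = TRUE))
  expect_equal(noborder$area_um2, c(5000, 16000))

  expect_error(qc_config(min_area_um2 = 300, max_area_um2 = 200), "min_area")
})

test_that("cell_region_table ties labeling, calibration and metadata together", {
  sim <- simulate_adipose_tile(tile_spec(seed = 17L))
  tab <- cell_region_table(sim$mask, mpp = sim$spec$mpp, tile_id = "t1",
                           sample_id = "s1", depot = "subq",
                           config = qc_config(connectivity = 4L))
  expect_equal(sort(tab$area_um2), sort(sim$areas_um2))
  expect_equal(tab$area_um2, tab$area_px * sim$spec$mpp^2)
  expect_true(all(tab$sample_id == "s1"))
  expect_lte(sum(tab$area_px), prod(dim(sim$mask)))
})

test_that("sample_phenotype draws without replacement, seeded, unbiased", {
  expect_error(sample_phenotype(1:10, n_cells = 1L), "n_cells")

  const <- rep(42, 600)
  ph <- sample_phenotype(const, n_cells = 500L, seed = 3L)
  expect_equal(ph$mean_area_um2, 42)
  expect_equal(ph$sd_area_um2, 0)
  expect_equal(ph$n_cells_used, 500L)
  expect_true(ph$sufficient)

  areas <- adipoquant:::with_seed(5, rlnorm(80, log(2500), 0.4))
  p1 <- sample_phenotype(areas, n_cells = 20L, seed = 9L)
  p2 <- sample_phenotype(areas, n_cells = 20L, seed = 9L)
  expect_identical(p1, p2)

  # insufficient cells are flagged
  small <- sample_phenotype(areas[1:10], n_cells = 20L, seed = 1L)
  expect_false(small$sufficient)
  expect_equal(small$n_cells_used, 10L)

  # unbiasedness: the average of subsample means over many seeds approaches
  # the full mean within 3x the Monte-Carlo standard error
  means <- vapply(1:1000, function(s)
    sample_phenotype(areas, n_cells = 20L, seed = s)$mean_area_um2, numeric(1))
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - mean(areas)), 3 * mc_se)
})

test_that("phenotype_table applies the minimum-cell rule per sample x depot", {
  reg <- data.frame(sample_id = rep(c("a", "a", "b"), times = c(30, 25, 4)),
                    depot = rep(c("subq", "visc", "subq"), times = c(30, 25, 4)),
                    area_um2 = rlnorm(59, log(2000), 0.3))
  expect_warning(ph <- phenotype_table(reg, n_cells = 10L, seed = 1L),
                 "fewer than")
  expect_equal(nrow(ph), 2L)   # sample b dropped
  expect_true(all(ph$n_cells_used == 10L))
  ph2 <- suppressWarnings(phenotype_table(reg, n_cells = 10L, seed = 1L))
  expect_identical(ph, ph2)
  # override keeps the small group
  ph3 <- phenotype_table(reg, n_cells = 10L, seed = 1L, min_cells = 3L)
  expect_equal(nrow(ph3), 3L)
})

test_that("Monte-Carlo stability dispersion shrinks with k and hits 0 at k = n", {
  areas <- adipoquant:::with_seed(21, rlnorm(400, log(3000), 0.5))
  st <- monte_carlo_stability(areas, k_grid = c(10L, 50L, 200L, 400L),
                              n_reps = 60L, seed = 2L)
  expect_equal(st$sd_of_subsample_means[4], 0)   # full population draw
  expect_true(all(diff(st$sd_of_subsample_means) <= 1e-12 + 0))

  const <- rep(7, 100)
  st0 <- monte_carlo_stability(const, k_grid = c(5L, 50L), n_reps = 10L, seed = 1L)
  expect_true(all(st0$sd_of_subsample_means == 0))
  expect_equal(attr(st0, "recommended_k"), 5L)

  expect_error(monte_carlo_stability(areas, k_grid = c(10L, 500L), n_reps = 5L),
               "at most")
})
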