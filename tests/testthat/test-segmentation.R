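# Dice coefficient, crop sampling, U-Net training and prediction.

test_that("dice coefficient matches hand pixel counts and handles edge cases", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L       # |A| = 4
  expect_equal(dice_coefficient(a, a), 1)

  b <- matrix(0L, 4, 4); b[3:4, 3:4] <- 1L       # disjoint
  expect_equal(dice_coefficient(a, b), 0)

  # |A| = 4, |B| = 4, overlap 2 -> 2*2/(4+4) = 0.5
  c <- matrix(0L, 4, 4); c[2:3, 1:2] <- 1L
  expect_equal(dice_coefficient(a, c), 0.5)

  # both empty: defined as 1
  z <- matrix(0L, 4, 4)
  expect_equal(dice_coefficient(z, z), 1)

  expect_error(dice_coefficient(a, matrix(0L, 3, 3)), "identical dimensions")
  expect_error(dice_coefficient(a, matrix(0.5, 4, 4)), "binary")
})

test_that("dice is symmetric, bounded, and 1 iff masks are equal", {
  for (s in 1:5) {
    a <- random_binary_mask(20, 20, p = 0.4, seed = s)
    b <- random_binary_mask(20, 20, p = 0.4, seed = s + 100)
    d_ab <- dice_coefficient(a, b)
    expect_equal(d_ab, dice_coefficient(b, a))
    expect_gte(d_ab, 0); expect_lte(d_ab, 1)
    if (d_ab == 1) expect_identical(a, b)
  }
})

test_that("soft dice on binary inputs equals the hard dice coefficient", {
  for (s in 1:3) {
    a <- random_binary_mask(16, 16, seed = s)
    b <- random_binary_mask(16, 16, seed = s + 50)
    expect_equal(soft_dice(a, b, smooth = 0), dice_coefficient(a, b))
  }
})

test_that("crops are aligned, binary, and train/validation sources are disjoint", {
  res <- tiny_unet_fit()
  crops <- res$crops
  train_src <- vapply(crops$train, `[[`, integer(1), "source")
  val_src <- vapply(crops$validation, `[[`, integer(1), "source")
  expect_length(intersect(train_src, val_src), 0L)

  for (cr in c(crops$train, crops$validation)) {
    expect_equal(dim(cr$image)[1:2], dim(cr$mask))
    expect_true(all(cr$mask %in% c(0L, 1L)))
    # mask content matches the source tile's mask at the same window
    src_mask <- unclass(res$sims[[cr$source]]$mask)
    found <- FALSE
    for (dy in 0:(nrow(src_mask) - nrow(cr$mask)))
      if (!found) for (dx in 0:(ncol(src_mask) - ncol(cr$mask)))
        if (identical(src_mask[(dy + 1):(dy + 64), (dx + 1):(dx + 64)],
                      cr$mask)) { found <- TRUE; break }
    expect_true(found)
  }
})

test_that("crop size equal to tile size returns whole tiles; oversizes error", {
  sims <- lapply(1:3, function(s)
    simulate_adipose_tile(tile_spec(width_px = 64L, height_px = 64L, mpp = 2,
                                    n_cells = 4L, seed = s)))
  tiles <- lapply(sims, `[[`, "image"); masks <- lapply(sims, `[[`, "mask")
  crops <- make_training_crops(tiles, masks, 64L, 4L, seed = 1, val_fraction = 0.34)
  for (cr in crops$train)
    expect_identical(cr$mask, unclass(unclass(masks[[cr$source]])))
  expect_error(make_training_crops(tiles, masks, 128L, 4L), "crop size")
})

test_that("a small U-Net memorizes dense fixtures (loss falls, train dice high)", {
  seeds <- adipoquant:::derive_seeds(17, 3)
  sims <- lapply(seeds, function(s)
    simulate_adipose_tile(tile_spec(width_px = 128L, height_px = 128L,
                                    mpp = 2.0, n_cells = 12L,
                                    membrane_width_px = 3L, seed = s)))
  crops <- make_training_crops(lapply(sims, `[[`, "image"),
                               lapply(sims, `[[`, "mask"),
                               64L, 12L, seed = 17, val_fraction = 0.34)
  fit <- train_unet(unet_config(depth = 3L, base_filters = 8L,
                                crop_size_px = 64L, epochs = 60L, seed = 17L),
                    crops)
  expect_gt(fit$train_dice, 0.95)
  expect_lt(fit$loss[length(fit$loss)], fit$loss[1])
  # broadly decreasing: the last stretch is below the first on average
  n <- length(fit$loss)
  expect_lt(mean(fit$loss[(n - 2):n]), mean(fit$loss[1:3]))
})

test_that("training reports a seeded, reproducible validation dice", {
  sims <- lapply(4:7, function(s)
    simulate_adipose_tile(tile_spec(width_px = 64L, height_px = 64L, mpp = 2,
                                    n_cells = 4L, seed = s)))
  crops <- make_training_crops(lapply(sims, `[[`, "image"),
                               lapply(sims, `[[`, "mask"),
                               32L, 12L, seed = 2, val_fraction = 0.25)
  cfg <- unet_config(depth = 2L, base_filters = 4L, crop_size_px = 32L,
                     epochs = 2L, seed = 11L)
  f1 <- train_unet(cfg, crops)
  f2 <- train_unet(cfg, crops)
  expect_identical(f1$final_validation_dice, f2$final_validation_dice)
  expect_identical(f1$weights, f2$weights)
  expect_error(train_unet(cfg, list(train = crops$train[1:4],
                                    validation = crops$validation)),
               "at least 10")
  expect_error(train_unet(cfg, list(train = crops$train, validation = list())),
               "validation split is empty")
})

test_that("probability maps are in [0,1], sized like the input, deterministic", {
  fit <- tiny_unet_fit()$fit
  sim <- simulate_adipose_tile(tile_spec(width_px = 128L, height_px = 128L,
                                         mpp = 2, n_cells = 12L, seed = 31L))
  p1 <- predict_probability_map(fit, sim$image)
  p2 <- predict_probability_map(fit, sim$image)
  expect_identical(unclass(p1), unclass(p2))
  expect_equal(dim(p1), dim(sim$mask))
  expect_true(all(p1 >= 0 & p1 <= 1))

  # non-divisible input is reflect-padded then cropped back
  odd <- unclass(sim$image)[1:97, 1:90, , drop = FALSE]
  p_odd <- predict_probability_map(fit, odd)
  expect_equal(dim(p_odd), c(97L, 90L))

  expect_error(predict_probability_map(fit, matrix(0, 64, 64)), "RGB")
})

test_that("a trained model scores background low and lumen high", {
  fit <- tiny_unet_fit()$fit
  # all-background tile: no cells at all
  bg <- simulate_adipose_tile(tile_spec(width_px = 64L, height_px = 64L,
                                        mpp = 2, n_cells = 0L, seed = 5L))
  expect_lt(mean(predict_probability_map(fit, bg$image)), 0.5)

  sim <- simulate_adipose_tile(tile_spec(width_px = 64L, height_px = 64L,
                                         mpp = 2, n_cells = 4L, seed = 6L))
  p <- predict_probability_map(fit, sim$image)
  expect_gt(dice_coefficient(unclass(threshold_map(p, 0.5)), unclass(sim$mask)),
            0.8)
})
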