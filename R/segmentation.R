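# Adipocyte U-Net: crop sampling, training with a dice + binary cross-entropy
# loss, probability-map prediction, and the Dice overlap score.

#' U-Net configuration
#'
#' @param depth Number of pooling levels (default 4); crop size must be
#'   divisible by `2^depth`.
#' @param base_filters Channels of the first encoder level (default 16 for the
#'   reduced CPU-friendly setting; 64 mirrors a full-scale configuration).
#'   Channels double per level, capped at `4 * base_filters`.
#' @param crop_size_px Side of the square training crops (default 128 reduced,
#'   1024 full-scale).
#' @param val_fraction Held-out fraction of source tiles (default 0.10).
#' @param epochs,batch_size Training schedule (defaults 30 epochs, batch 4).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param dice_weight,bce_weight Loss mixing weights; the default 1:1 sums the
#'   Dice term (1 - soft Dice) and pixelwise binary cross-entropy equally.
#' @param dice_smooth Smoothing constant of the soft Dice term.
#' @param seed Integer seed.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_filters = 16L, crop_size_px = 128L,
                        val_fraction = 0.10, epochs = 30L, batch_size = 4L,
                        learning_rate = 1e-3, dice_weight = 1, bce_weight = 1,
                        dice_smooth = 1, seed = 1L) {
  depth <- assert_count(depth, "depth", min = 1L)
  base_filters <- assert_count(base_filters, "base_filters", min = 1L)
  crop_size_px <- assert_count(crop_size_px, "crop_size_px", min = 2L^depth)
  if (crop_size_px %% 2L^depth != 0L)
    stop("`crop_size_px` must be divisible by 2^depth = ", 2L^depth, call. = FALSE)
  assert_scalar_number(val_fraction, "val_fraction", 0, 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  epochs <- assert_count(epochs, "epochs", min = 1L)
  batch_size <- assert_count(batch_size, "batch_size", min = 1L)
  assert_scalar_number(learning_rate, "learning_rate", 0, strict_lower = TRUE)
  seed <- assert_count(seed, "seed", min = 0L)
  structure(list(depth = depth, base_filters = base_filters,
                 crop_size_px = crop_size_px, val_fraction = val_fraction,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, dice_weight = dice_weight,
                 bce_weight = bce_weight, dice_smooth = dice_smooth,
                 loss = "dice + binary cross-entropy", seed = seed),
            class = "unet_config")
}

check_binary_mask <- function(m, name) {
  if (inherits(m, "segmentation_mask")) m <- unclass(m)
  if (!is.matrix(m) || !all(m %in% c(0, 1)))
    stop("`", name, "` must be a binary (0/1) matrix", call. = FALSE)
  m
}

#' Dice overlap between two binary masks
#'
#' `Dice(A, B) = 2|A n B| / (|A| + |B|)`: 1 for identical non-empty masks, 0
#' for disjoint ones. When both masks are empty the formula is 0/0; this is
#' defined as 1 (perfect agreement on absence).
#'
#' @param mask_a,mask_b Binary matrices of identical shape.
#' @return A number in \[0, 1\].
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  a <- check_binary_mask(mask_a, "mask_a")
  b <- check_binary_mask(mask_b, "mask_b")
  if (!all(dim(a) == dim(b)))
    stop("masks must have identical dimensions", call. = FALSE)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a * b) / denom
}

#' Soft Dice between a probability map and a binary target
#'
#' `(2 * sum(p*t) + smooth) / (sum(p) + sum(t) + smooth)`: the differentiable
#' Dice used inside the training loss (as `1 - soft_dice`). With `smooth = 0`
#' and a binary `p` it equals [dice_coefficient()] exactly.
#'
#' @param p Numeric matrix of probabilities in \[0, 1\].
#' @param target Binary matrix of the same shape.
#' @param smooth Smoothing constant (the training default is 1).
#' @return A number in \[0, 1\].
#' @export
soft_dice <- function(p, target, smooth = 0) {
  target <- check_binary_mask(target, "target")
  p <- unclass(p)
  if (!all(dim(p) == dim(target)))
    stop("`p` and `target` must have identical dimensions", call. = FALSE)
  denom <- sum(p) + sum(target) + smooth
  if (denom == 0) return(1)
  (2 * sum(p * target) + smooth) / denom
}

#' Sample aligned training crops from tile/mask pairs
#'
#' Crops are sampled at seeded uniform-random offsets, image and mask cut with
#' the same window. Source tiles are first partitioned into training and
#' validation sets, so no tile ever contributes crops to both.
#'
#' @param tiles List of RGB tiles (arrays or `tile_image`).
#' @param masks List of aligned binary masks of identical spatial shape.
#' @param crop_size_px Crop side length.
#' @param n_crops Total number of training crops to draw.
#' @param seed Integer seed.
#' @param val_fraction Fraction of source tiles held out (default 0.10); their
#'   crops (one per validation tile per `n_crops/ n tiles`, at least 1) form
#'   the validation set.
#' @return A list with `train` and `validation`, each a list of crops
#'   `(image, mask, source)` where `source` indexes the originating tile.
#' @export
make_training_crops <- function(tiles, masks, crop_size_px, n_crops, seed = 1L,
                                val_fraction = 0.10) {
  stopifnot(length(tiles) == length(masks), length(tiles) >= 2L)
  n_crops <- assert_count(n_crops, "n_crops", min = 1L)
  for (i in seq_along(tiles)) {
    d <- dim(tiles[[i]])
    dm <- dim(masks[[i]])
    if (!all(d[1:2] == dm))
      stop("tile ", i, " and its mask have different shapes", call. = FALSE)
    if (d[1] < crop_size_px || d[2] < crop_size_px)
      stop("crop size ", crop_size_px, " exceeds tile ", i, " (",
           d[1], " x ", d[2], ")", call. = FALSE)
  }
  with_seed(seed, {
    n_tiles <- length(tiles)
    n_val_tiles <- max(1L, round(val_fraction * n_tiles))
    val_tiles <- sort(sample.int(n_tiles, n_val_tiles))
    train_tiles <- setdiff(seq_len(n_tiles), val_tiles)
    if (!length(train_tiles)) stop("no tiles left for training", call. = FALSE)

    draw <- function(src_pool, k) {
      lapply(seq_len(k), function(j) {
        src <- src_pool[((j - 1L) %% length(src_pool)) + 1L]
        d <- dim(tiles[[src]])
        y <- sample.int(d[1] - crop_size_px + 1L, 1L) - 1L
        x <- sample.int(d[2] - crop_size_px + 1L, 1L) - 1L
        img <- unclass(tiles[[src]])[(y + 1L):(y + crop_size_px),
                                     (x + 1L):(x + crop_size_px), , drop = FALSE]
        msk <- unclass(masks[[src]])[(y + 1L):(y + crop_size_px),
                                     (x + 1L):(x + crop_size_px), drop = FALSE]
        list(image = img, mask = msk, source = src)
      })
    }
    n_val_crops <- max(1L, round(n_crops * val_fraction / (1 - val_fraction)))
    list(train = draw(train_tiles, n_crops),
         validation = draw(val_tiles, n_val_crops))
  })
}

#' Train the adipocyte U-Net
#'
#' Optimizes the sum of a Dice loss (1 - soft Dice) and pixelwise binary
#' cross-entropy (equal weights by default) with Adam, and reports the pooled
#' hard Dice (threshold 0.5) on the held-out crops.
#'
#' @param config A [unet_config()].
#' @param crops Output of [make_training_crops()], or a plain list of
#'   `(image, mask)` crops (then `val_fraction` of them, by source, are held
#'   out).
#' @return An object of class `adipocyte_unet` with the trained weights,
#'   `final_validation_dice`, `train_dice` and the loss history.
#' @export
train_unet <- function(config, crops) {
  stopifnot(inherits(config, "unet_config"))
  if (is.null(crops$train)) crops <- list(train = crops, validation = list())
  n_tr <- length(crops$train)
  if (n_tr < 10L) stop("need at least 10 training crops", call. = FALSE)
  if (length(crops$validation) == 0L)
    stop("validation split is empty; use make_training_crops()", call. = FALSE)

  all_crops <- c(crops$train, crops$validation)
  imgs <- lapply(all_crops, function(cr) unclass(cr$image))
  msks <- lapply(all_crops, function(cr) {
    m <- check_binary_mask(cr$mask, "mask")
    array(as.numeric(m), dim = c(nrow(m), ncol(m), 1L))
  })
  for (im in imgs) {
    d <- dim(im)
    if (d[1] %% 2L^config$depth != 0L || d[2] %% 2L^config$depth != 0L)
      stop("crop dimensions must be divisible by 2^depth", call. = FALSE)
  }

  weights <- cpp_unet_init(config$depth, config$base_filters, 4L, config$seed)
  fit <- cpp_unet_train(weights, imgs, msks,
                        seq_len(n_tr) - 1L,
                        n_tr + seq_along(crops$validation) - 1L,
                        config$learning_rate, 0.9, 0.999, 1e-8,
                        config$epochs, config$batch_size,
                        config$dice_smooth, config$dice_weight,
                        config$bce_weight, config$seed)
  structure(list(weights = fit$weights, config = config,
                 final_validation_dice = fit$validation_dice,
                 train_dice = fit$train_dice, loss = fit$loss,
                 n_train_crops = n_tr,
                 n_validation_crops = length(crops$validation)),
            class = "adipocyte_unet")
}

#' @export
print.adipocyte_unet <- function(x, ...) {
  cat(sprintf("<adipocyte_unet> depth %d, base %d; validation Dice %.3f (%d train / %d val crops)\n",
              x$config$depth, x$config$base_filters,
              x$final_validation_dice, x$n_train_crops, x$n_validation_crops))
  invisible(x)
}

#' Predict a per-pixel adipocyte probability map
#'
#' Inputs whose dimensions are not divisible by `2^depth` are reflect-padded
#' to the next multiple and the output cropped back, so the map always matches
#' the input size. Prediction is deterministic.
#'
#' @param model An `adipocyte_unet`.
#' @param tile RGB tile (H x W x 3 array or `tile_image`).
#' @return A `probability_map`: numeric matrix in \[0, 1\] of the tile's size.
#' @export
predict_probability_map <- function(model, tile) {
  stopifnot(inherits(model, "adipocyte_unet"))
  img <- unclass(tile)
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    stop("tile must be an H x W x 3 RGB array (got ",
         paste(d, collapse = " x "), " channels)", call. = FALSE)
  need <- 2L^model$config$depth
  H <- d[1]; W <- d[2]
  Hp <- ceiling(H / need) * need
  Wp <- ceiling(W / need) * need
  if (Hp != H || Wp != W) {
    reflect_idx <- function(n, np) {     # 1..n, n..1, 1..n, ... up to np
      j <- (seq_len(np) - 1L) %% (2L * n)
      ifelse(j < n, j + 1L, 2L * n - j)
    }
    img <- img[reflect_idx(H, Hp), reflect_idx(W, Wp), , drop = FALSE]
  }
  p <- cpp_unet_predict(model$weights, img)
  p <- clip01(p[seq_len(H), seq_len(W), drop = FALSE])
  structure(p, class = "probability_map")
}

#' @rdname predict_probability_map
#' @param object,newdata,... Method arguments; `newdata` is a single tile or a
#'   list of tiles.
#' @export
predict.adipocyte_unet <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.array(newdata))
    lapply(newdata, predict_probability_map, model = object)
  else predict_probability_map(object, newdata)
}

#' Save / load a trained model
#'
#' Model objects (triage or U-Net) are plain lists of numeric weight matrices
#' plus their configuration, serialized with R's native RDS format.
#'
#' @param model A `triage_model`, `triage_fit` or `adipocyte_unet`.
#' @param path Destination file.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
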