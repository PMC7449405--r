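# Three-class tile triage: adipocyte / non_adipocyte / empty.
#
# The classifier is a convolutional trunk followed by spatial average pooling
# and a single fully connected 3-way softmax layer. The reduced trunk (three
# conv/pool blocks) is the default and is trainable on a desktop CPU; the
# "full" trunk is a deeper/wider stack with the identical head and prediction
# interface (it is randomly initialised, not pretrained).

TRIAGE_CLASSES <- c("adipocyte", "non_adipocyte", "empty")

#' Triage configuration
#'
#' @param posterior_threshold Posterior cutoff used by
#'   [select_adipocyte_tiles()]; selection is strict (`>`), default 0.9.
#' @param learning_rate SGD learning rate, default 1e-4.
#' @param momentum Nesterov momentum coefficient, default 0.9.
#' @param train_fraction Stratified train share of the labeled tiles,
#'   default 0.8 (an 80:20 train:validation split).
#' @param backbone_scale `"reduced"` (default) or `"full"`.
#' @param epochs,batch_size Training schedule (reduced defaults: 20 epochs,
#'   batch 16).
#' @param clip_norm Global gradient-norm guard against blow-ups.
#' @param seed Integer seed controlling weight init, the split and shuffling.
#' @return An object of class `triage_config`.
#' @export
triage_config <- function(posterior_threshold = 0.9, learning_rate = 1e-4,
                          momentum = 0.9, train_fraction = 0.8,
                          backbone_scale = c("reduced", "full"),
                          epochs = 20L, batch_size = 16L, clip_norm = 1e4,
                          seed = 1L) {
  assert_scalar_number(posterior_threshold, "posterior_threshold", 0, 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(learning_rate, "learning_rate", 0, strict_lower = TRUE)
  assert_scalar_number(momentum, "momentum", 0, 1, strict_upper = TRUE)
  assert_scalar_number(train_fraction, "train_fraction", 0, 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  backbone_scale <- match.arg(backbone_scale)
  epochs <- assert_count(epochs, "epochs", min = 1L)
  batch_size <- assert_count(batch_size, "batch_size", min = 1L)
  seed <- assert_count(seed, "seed", min = 0L)
  structure(list(n_classes = 3L, posterior_threshold = posterior_threshold,
                 learning_rate = learning_rate, momentum = momentum,
                 train_fraction = train_fraction,
                 backbone_scale = backbone_scale, epochs = epochs,
                 batch_size = batch_size, clip_norm = clip_norm, seed = seed),
            class = "triage_config")
}

triage_channels <- function(backbone_scale) {
  switch(backbone_scale,
         reduced = c(8L, 16L, 32L),
         full = c(16L, 32L, 64L, 64L, 96L))
}

#' Build a (untrained) triage model
#'
#' The head contract is fixed: spatial average pooling over the final feature
#' map, then one fully connected layer with a 3-way softmax. The softmax
#' weights start at zero, so an untrained model returns uniform posteriors.
#'
#' @param config A [triage_config()].
#' @return An object of class `triage_model`.
#' @export
build_triage_model <- function(config = triage_config()) {
  stopifnot(inherits(config, "triage_config"))
  ch <- triage_channels(config$backbone_scale)
  weights <- cpp_triage_init(ch, config$seed)
  structure(list(weights = weights, channels = ch, config = config,
                 classes = TRIAGE_CLASSES, trained = FALSE),
            class = "triage_model")
}

#' @export
print.triage_model <- function(x, ...) {
  cat(sprintf("<triage_model> %s backbone (%s), %s\n",
              x$config$backbone_scale, paste(x$channels, collapse = "-"),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

check_tile_dims <- function(tiles, n_blocks, what = "tile") {
  need <- 2L^n_blocks
  for (i in seq_along(tiles)) {
    d <- dim(tiles[[i]])
    if (length(d) != 3L || d[3] != 3L)
      stop(what, " ", i, ": expected an H x W x 3 RGB array", call. = FALSE)
    if (d[1] %% need != 0L || d[2] %% need != 0L || d[1] < need || d[2] < need)
      stop(what, " ", i, ": dimensions ", d[1], " x ", d[2],
           " are incompatible with the model (must be multiples of ", need, ")",
           call. = FALSE)
  }
  invisible(TRUE)
}

# stratified split by class; error if any class cannot appear in training
stratified_split <- function(labels, train_fraction, seed) {
  with_seed(seed, {
    train <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- round(length(idx) * train_fraction)
      if (n_tr < 1L || n_tr >= length(idx) + 1L)
        n_tr <- max(1L, min(length(idx), n_tr))
      train <- c(train, sort(sample(idx, n_tr)))
    }
    train <- sort(train)
    list(train = train, validation = setdiff(seq_along(labels), train))
  })
}

#' Train the triage classifier
#'
#' Stochastic gradient descent with Nesterov momentum on a stratified
#' train:validation split. Training is seeded and reproducible under
#' single-threaded execution.
#'
#' @param model A [build_triage_model()] result.
#' @param tiles List of RGB tiles (`tile_image` or plain arrays, values 0-1).
#' @param labels Factor or character vector over the three triage classes.
#' @param config Optional [triage_config()] overriding the model's.
#' @return An object of class `triage_fit`: the trained model plus
#'   `train_accuracy`, `validation_accuracy`, the split and loss history.
#' @export
train_triage <- function(model, tiles, labels, config = model$config) {
  stopifnot(inherits(model, "triage_model"))
  labels <- factor(as.character(labels), levels = TRIAGE_CLASSES)
  if (anyNA(labels))
    stop("labels must be in {", paste(TRIAGE_CLASSES, collapse = ", "), "}",
         call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("need at least 2 examples per class; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         call. = FALSE)
  check_tile_dims(tiles, length(model$channels))

  split <- stratified_split(labels, config$train_fraction, config$seed)
  if (length(intersect(split$train, split$validation)) > 0L)
    stop("internal error: train/validation overlap")  # contract
  if (length(unique(labels[split$train])) < 3L)
    stop("a class is absent from the training split; provide more examples",
         call. = FALSE)

  imgs <- lapply(tiles, function(t) unclass(t))
  fit <- cpp_triage_train(model$weights, imgs, as.integer(labels) - 1L,
                          split$train - 1L, split$validation - 1L,
                          config$learning_rate, config$momentum,
                          config$epochs, config$batch_size,
                          config$clip_norm, config$seed)
  model$weights <- fit$weights
  model$trained <- TRUE
  model$config <- config
  structure(list(model = model,
                 train_accuracy = fit$train_accuracy,
                 validation_accuracy = fit$validation_accuracy,
                 loss = fit$loss, split = split),
            class = "triage_fit")
}

#' @export
print.triage_fit <- function(x, ...) {
  cat(sprintf("<triage_fit> train accuracy %.3f, validation accuracy %.3f (n_train %d, n_val %d)\n",
              x$train_accuracy, x$validation_accuracy,
              length(x$split$train), length(x$split$validation)))
  invisible(x)
}

#' Classify tiles into the three triage classes
#'
#' @param model A `triage_model` or `triage_fit`.
#' @param tiles List of RGB tiles; order is preserved in the output.
#' @param tile_id Optional identifiers (default positional).
#' @return A data.frame (tile_id, p_adipocyte, p_non_adipocyte, p_empty,
#'   argmax); each row's probabilities sum to 1 within 1e-6. Ties in the
#'   argmax are broken by the fixed class order adipocyte < non_adipocyte <
#'   empty.
#' @export
classify_tiles <- function(model, tiles, tile_id = NULL) {
  if (inherits(model, "triage_fit")) model <- model$model
  stopifnot(inherits(model, "triage_model"))
  if (length(tiles) == 0L)
    return(data.frame(tile_id = character(0), p_adipocyte = numeric(0),
                      p_non_adipocyte = numeric(0), p_empty = numeric(0),
                      argmax = character(0), stringsAsFactors = FALSE))
  check_tile_dims(tiles, length(model$channels))
  if (is.null(tile_id)) tile_id <- sprintf("tile_%04d", seq_along(tiles))
  p <- cpp_triage_predict(model$weights, lapply(tiles, unclass))
  argmax <- TRIAGE_CLASSES[max.col(p, ties.method = "first")]
  data.frame(tile_id = tile_id, p_adipocyte = p[, 1], p_non_adipocyte = p[, 2],
             p_empty = p[, 3], argmax = argmax, stringsAsFactors = FALSE)
}

#' @rdname classify_tiles
#' @param object,... Method arguments.
#' @param newdata List of tiles.
#' @export
predict.triage_fit <- function(object, newdata, ...) {
  classify_tiles(object$model, newdata)
}

#' Select high-confidence adipocyte tiles
#'
#' A tile is retained iff its adipocyte-class posterior strictly exceeds the
#' threshold; selection depends only on that probability. At the default 0.9
#' a posterior of exactly 0.90 is NOT selected.
#'
#' @param posteriors Data.frame from [classify_tiles()].
#' @param threshold Posterior cutoff in (0, 1), default 0.9.
#' @return Character vector of selected tile ids.
#' @export
select_adipocyte_tiles <- function(posteriors, threshold = 0.9) {
  assert_scalar_number(threshold, "threshold", 0, 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  stopifnot(all(c("tile_id", "p_adipocyte") %in% names(posteriors)))
  posteriors$tile_id[posteriors$p_adipocyte > threshold]
}
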