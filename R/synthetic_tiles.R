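# Synthetic adipose-like tiles with exact ground truth.
#
# Adipose tissue in H&E sections looks like a bubble tessellation: white lipid
# lumina bounded by thin eosin-stained membranes. The generator renders an
# additively weighted Voronoi tessellation of seeded cell centres, carves a
# membrane of configurable width along region boundaries, and reads the ground
# truth (binary mask and per-cell pixel areas) straight off the rendering, so
# segmentation and quantification can be tested against exact answers.

#' Specification of a synthetic adipose tile
#'
#' @param width_px,height_px Tile dimensions in pixels (at least 64).
#' @param mpp Microns per pixel; cell areas in um^2 are pixel counts times
#'   `mpp^2`. The default matches a common whole-slide scan calibration
#'   (0.4942 um/pixel).
#' @param n_cells Number of adipocytes to render (0 gives an empty mask).
#' @param log_area_mean,log_area_sd Cell areas are drawn log-normal in um^2;
#'   defaults centre the distribution near 2800 um^2, a typical subcutaneous
#'   mean adipocyte area, with a right-skewed spread.
#' @param membrane_width_px Width in pixels of the stained membrane separating
#'   neighbouring cells.
#' @param seed Integer seed; identical specs (including seed) reproduce
#'   byte-identical outputs.
#' @return An object of class `tile_spec`.
#' @export
tile_spec <- function(width_px = 256L, height_px = 256L, mpp = 0.4942,
                      n_cells = 5L, log_area_mean = log(2800),
                      log_area_sd = 0.25, membrane_width_px = 3L, seed = 1L) {
  width_px <- assert_count(width_px, "width_px", min = 64L)
  height_px <- assert_count(height_px, "height_px", min = 64L)
  assert_scalar_number(mpp, "mpp", lower = 0, strict_lower = TRUE)
  n_cells <- assert_count(n_cells, "n_cells", min = 0L)
  assert_scalar_number(log_area_mean, "log_area_mean")
  assert_scalar_number(log_area_sd, "log_area_sd", lower = 0)
  membrane_width_px <- assert_count(membrane_width_px, "membrane_width_px", min = 1L)
  seed <- assert_count(seed, "seed", min = 0L)
  structure(list(width_px = width_px, height_px = height_px, mpp = mpp,
                 n_cells = n_cells, log_area_mean = log_area_mean,
                 log_area_sd = log_area_sd,
                 membrane_width_px = membrane_width_px, seed = seed),
            class = "tile_spec")
}

#' @export
print.tile_spec <- function(x, ...) {
  cat(sprintf("<tile_spec> %d x %d px @ %.4f um/px, %d cells, membrane %d px, seed %d\n",
              x$width_px, x$height_px, x$mpp, x$n_cells, x$membrane_width_px, x$seed))
  invisible(x)
}

# fixed H&E-like palette (see the methods vignette for the colour model)
.palette <- list(lumen = c(0.97, 0.96, 0.97),
                 membrane = c(0.75, 0.42, 0.60),
                 background = c(0.93, 0.90, 0.92),
                 eosin_dense = c(0.82, 0.48, 0.62),
                 nucleus = c(0.36, 0.22, 0.48),
                 empty = c(0.96, 0.95, 0.96))

# mean-intensity floor separating empty from adipocyte triage tiles
.brightness_floor <- 0.92

tile_image <- function(pixels, mpp, slide_id = NA_character_,
                       x_offset_px = 0L, y_offset_px = 0L) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  structure(pixels, mpp = mpp, slide_id = slide_id,
            x_offset_px = as.integer(x_offset_px),
            y_offset_px = as.integer(y_offset_px),
            class = "tile_image")
}

#' @export
print.tile_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<tile_image> %d x %d px, mpp %.4f, slide %s, offset (%d, %d)\n",
              d[1], d[2], attr(x, "mpp"), attr(x, "slide_id"),
              attr(x, "x_offset_px"), attr(x, "y_offset_px")))
  invisible(x)
}

# place cell centres by dart throwing so that no two are closer than
# 0.55 * (r_i + r_j); returns NULL when no layout is found
place_seeds <- function(W, H, r) {
  n <- length(r)
  sx <- numeric(n); sy <- numeric(n)
  margin <- pmin(pmin(W, H) / 2 - 1, r * 0.35)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(400L)) {
      x <- runif(1, margin[i], W - margin[i])
      y <- runif(1, margin[i], H - margin[i])
      if (i == 1L ||
          all(sqrt((sx[seq_len(i - 1)] - x)^2 + (sy[seq_len(i - 1)] - y)^2) >=
              0.55 * (r[seq_len(i - 1)] + r[i]))) {
        sx[i] <- x; sy[i] <- y; placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  list(x = sx, y = sy)
}

#' Simulate one adipose tile with exact ground truth
#'
#' Renders `n_cells` adipocytes as an additively weighted Voronoi tessellation
#' (weights from the drawn target areas), carves a membrane of
#' `membrane_width_px` along region boundaries, and returns the RGB image, the
#' binary mask, and the per-cell areas measured from the mask itself
#' (pixel count times `mpp^2`), so mask and area list are exactly consistent.
#'
#' @param spec A [tile_spec()].
#' @return A list of class `adipose_tile_sim` with elements `image`
#'   (a `tile_image`, values in 0-1), `mask` (integer matrix, 0/1,
#'   foreground = adipocyte, every cell a 4-connected component), and
#'   `areas_um2` (numeric, one entry per rendered cell, in mask label order).
#' @export
simulate_adipose_tile <- function(spec) {
  stopifnot(inherits(spec, "tile_spec"))
  with_seed(spec$seed, generate_adipose_tile(spec))
}

# does the actual work; assumes the RNG has been seeded by the caller
generate_adipose_tile <- function(spec) {
  W <- spec$width_px; H <- spec$height_px; m <- spec$membrane_width_px
  n <- spec$n_cells

  if (n == 0L) {
    mask <- matrix(0L, H, W)
    img <- render_tile(mask_fg = mask == 1L, mem = matrix(FALSE, H, W))
    return(structure(list(image = tile_image(img, spec$mpp),
                          mask = structure(mask, class = "segmentation_mask"),
                          areas_um2 = numeric(0), spec = spec),
                     class = "adipose_tile_sim"))
  }
  if (n * (2L * m + 2L)^2 > W * H)
    stop("impossible packing: n_cells too large for the tile at the requested membrane width",
         call. = FALSE)

  for (layout_try in seq_len(50L)) {
    areas_um2 <- rlnorm(n, spec$log_area_mean, spec$log_area_sd)
    areas_px <- areas_um2 / spec$mpp^2
    if (sum(areas_px) > 1.5 * W * H)
      stop("impossible packing: requested cell areas exceed the tile area",
           call. = FALSE)
    r <- sqrt(areas_px / pi)
    seeds <- place_seeds(W, H, r)
    if (is.null(seeds)) next

    # additively weighted Voronoi: pixel -> argmin_i (dist_i - r_i)
    gx <- rep(seq_len(W) - 0.5, each = H)
    gy <- rep(seq_len(H) - 0.5, times = W)
    best1 <- rep(Inf, W * H); best2 <- rep(Inf, W * H)
    own <- integer(W * H)
    for (i in seq_len(n)) {
      d <- sqrt((gx - seeds$x[i])^2 + (gy - seeds$y[i])^2) - r[i]
      u1 <- d < best1
      u2 <- !u1 & d < best2
      best2[u1] <- best1[u1]; best1[u1] <- d[u1]; own[u1] <- i
      best2[u2] <- d[u2]
    }
    bound <- 1.25 * r[own]              # cells stay near their target radius
    inside <- best1 <= bound
    fg <- inside & (best2 - best1 >= m) & (bound - best1 >= m / 2)
    mem <- !fg & (best1 <= bound + m / 2)

    mask <- matrix(as.integer(fg), H, W)
    lab <- cpp_label_regions(mask, 4L)
    k <- max(lab)
    if (k == n) {
      img <- render_tile(mask_fg = matrix(fg, H, W), mem = matrix(mem, H, W))
      areas_px_real <- tabulate(lab[lab > 0L], nbins = k)
      return(structure(list(image = tile_image(img, spec$mpp),
                            mask = structure(mask, class = "segmentation_mask"),
                            areas_um2 = areas_px_real * spec$mpp^2,
                            spec = spec),
                       class = "adipose_tile_sim"))
    }
  }
  stop("impossible packing: could not lay out ", n,
       " non-merging cells in the tile after 50 attempts", call. = FALSE)
}

# paint lumen / membrane / background with per-pixel Gaussian jitter
render_tile <- function(mask_fg, mem, jitter_sd = 0.015) {
  H <- nrow(mask_fg); W <- ncol(mask_fg)
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(.palette$background[ch], H, W)
    plane[mem] <- .palette$membrane[ch]
    plane[mask_fg] <- .palette$lumen[ch]
    img[, , ch] <- plane
  }
  img <- img + array(rnorm(H * W * 3, 0, jitter_sd), dim = c(H, W, 3))
  clip01(img)
}

#' @export
print.adipose_tile_sim <- function(x, ...) {
  cat(sprintf("<adipose_tile_sim> %d x %d px, %d cells, areas %s um^2\n",
              nrow(x$mask), ncol(x$mask), length(x$areas_um2),
              if (length(x$areas_um2)) paste0(round(min(x$areas_um2)), "-",
                                              round(max(x$areas_um2))) else "-"))
  invisible(x)
}

#' Simulate labeled tiles for triage training
#'
#' Generates `n_per_class` tiles for each of the three triage classes:
#' `adipocyte` (bubble tessellation of white lumina with stained membranes),
#' `non_adipocyte` (dense eosin-like texture with nuclei, no lumina), and
#' `empty` (uniform pale background). The classes are separable by
#' construction: empty tiles have mean intensity above the documented
#' brightness floor (`attr(, "brightness_floor")`, 0.92) and adipocyte tiles
#' fall below it.
#'
#' @param n_per_class Number of tiles per class (at least 1).
#' @param seed Integer seed; fixes tile content and the label sequence.
#' @param tile_px Side length of the square tiles (default 64).
#' @return A list with `tiles` (list of `tile_image`), `labels` (factor with
#'   levels adipocyte, non_adipocyte, empty), and `tile_id`.
#' @export
simulate_triage_tiles <- function(n_per_class, seed = 1L, tile_px = 64L) {
  n_per_class <- assert_count(n_per_class, "n_per_class", min = 1L)
  tile_px <- assert_count(tile_px, "tile_px", min = 64L)
  seed <- assert_count(seed, "seed", min = 0L)
  classes <- c("adipocyte", "non_adipocyte", "empty")

  with_seed(seed, {
    n <- 3L * n_per_class
    labels <- factor(rep(classes, each = n_per_class), levels = classes)
    ord <- sample.int(n)
    labels <- labels[ord]
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)

    tiles <- vector("list", n)
    for (i in seq_len(n)) {
      tiles[[i]] <- switch(as.character(labels[i]),
        adipocyte = {
          sp <- tile_spec(width_px = tile_px, height_px = tile_px, mpp = 2.0,
                          n_cells = 5L, log_area_mean = log(2800),
                          log_area_sd = 0.3, membrane_width_px = 3L,
                          seed = sub_seeds[i])
          simulate_adipose_tile(sp)$image
        },
        non_adipocyte = render_dense_tile(tile_px, sub_seeds[i]),
        empty = render_empty_tile(tile_px, sub_seeds[i]))
    }
    structure(list(tiles = tiles, labels = labels,
                   tile_id = sprintf("triage_%04d", seq_len(n))),
              brightness_floor = .brightness_floor)
  })
}

render_dense_tile <- function(px, seed) {
  with_seed(seed, {
    img <- array(rep(.palette$eosin_dense, each = px * px), dim = c(px, px, 3))
    img <- img + array(rnorm(px * px * 3, 0, 0.05), dim = c(px, px, 3))
    # scatter dark nuclei
    n_nuc <- round(px * px / 90)
    cx <- runif(n_nuc, 2, px - 1); cy <- runif(n_nuc, 2, px - 1)
    rad <- runif(n_nuc, 1, 2.2)
    for (k in seq_len(n_nuc)) {
      i0 <- max(1, floor(cy[k] - rad[k])); i1 <- min(px, ceiling(cy[k] + rad[k]))
      j0 <- max(1, floor(cx[k] - rad[k])); j1 <- min(px, ceiling(cx[k] + rad[k]))
      for (j in j0:j1) for (i in i0:i1)
        if ((i - cy[k])^2 + (j - cx[k])^2 <= rad[k]^2)
          img[i, j, ] <- .palette$nucleus
    }
    tile_image(clip01(img), mpp = 2.0)
  })
}

render_empty_tile <- function(px, seed) {
  with_seed(seed, {
    img <- array(rep(.palette$empty, each = px * px), dim = c(px, px, 3))
    img <- img + array(rnorm(px * px * 3, 0, 0.01), dim = c(px, px, 3))
    tile_image(clip01(img), mpp = 2.0)
  })
}

#' Write a tile and mask set to disk as plain fixtures
#'
#' Tiles go out as 8-bit RGB PNG, masks as single-channel PNG with values
#' {0, 255}, and the per-cell ground-truth areas as a tab-separated table.
#'
#' @param sims List of `adipose_tile_sim` objects.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, a data.frame indexing the written files.
#' @export
write_tile_fixtures <- function(sims, dir, prefix = "tile") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(sims))
  area_rows <- list()
  for (i in seq_along(sims)) {
    s <- sims[[i]]
    id <- sprintf("%s_%03d", prefix, i)
    img_path <- file.path(dir, paste0(id, ".png"))
    mask_path <- file.path(dir, paste0(id, "_mask.png"))
    png::writePNG(unclass(s$image), img_path)
    png::writePNG(matrix(as.numeric(s$mask), nrow(s$mask), ncol(s$mask)), mask_path)
    rows[[i]] <- data.frame(tile_id = id, image = img_path, mask = mask_path,
                            mpp = s$spec$mpp, n_cells = length(s$areas_um2))
    if (length(s$areas_um2))
      area_rows[[length(area_rows) + 1L]] <-
        data.frame(tile_id = id, cell = seq_along(s$areas_um2),
                   area_um2 = s$areas_um2)
  }
  index <- do.call(rbind, rows)
  write.table(index, file.path(dir, paste0(prefix, "_index.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(area_rows))
    write.table(do.call(rbind, area_rows),
                file.path(dir, paste0(prefix, "_areas.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(index)
}
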