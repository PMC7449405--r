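# Slide-to-tile conversion and slide metadata.
#
# Conventions (used everywhere): 0-based, top-left origin; a tile at offset
# (x, y) covers the half-open pixel window [x, x + T) x [y, y + T). Windows
# that do not fit entirely inside the image are dropped, not padded.

#' Read and validate a slide manifest
#'
#' The manifest is a TSV with header columns slide_id, image_path, mpp,
#' cohort, depot, sample_id. Every row is validated: `slide_id` must be
#' unique, `mpp` present and strictly positive (there is no default
#' calibration), and `image_path` readable.
#'
#' @param path Path to the manifest file.
#' @param check_paths Verify that each `image_path` exists (default TRUE).
#' @return A data.frame of class `slide_manifest`.
#' @export
read_slide_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  man <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("slide_id", "image_path", "mpp", "cohort", "depot", "sample_id")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dup <- man$slide_id[duplicated(man$slide_id)]
  if (length(dup))
    stop("duplicate slide_id in manifest: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad_mpp <- which(!is.finite(man$mpp) | man$mpp <= 0)
  if (length(bad_mpp))
    stop("row ", bad_mpp[1], " (slide_id ", man$slide_id[bad_mpp[1]],
         "): mpp must be a positive number, got ", man$mpp[bad_mpp[1]],
         call. = FALSE)
  if (check_paths) {
    bad_path <- which(!file.exists(man$image_path))
    if (length(bad_path))
      stop("row ", bad_path[1], " (slide_id ", man$slide_id[bad_path[1]],
           "): image path not readable: ", man$image_path[bad_path[1]],
           call. = FALSE)
  }
  class(man) <- c("slide_manifest", "data.frame")
  man
}

#' Cut an image into fixed-size calibrated tiles
#'
#' Slides are scanned with a sliding window of `tile_size_px` pixels moved by
#' `stride_px`; tiles are enumerated row-major from the top-left and only
#' windows lying fully inside the image are emitted, so an image smaller than
#' the window yields no tiles. Each tile carries its offsets and the slide's
#' microns-per-pixel calibration.
#'
#' @param image An RGB array (H x W x 3) or `tile_image`.
#' @param tile_size_px Window side length in pixels (default 1024).
#' @param stride_px Window step in pixels (default: `tile_size_px`,
#'   non-overlapping).
#' @param mpp Microns per pixel of the source image (taken from the image
#'   attribute if present).
#' @param slide_id Identifier carried onto the tiles.
#' @return A list of `tile_image` objects (possibly empty).
#' @export
tile_image_grid <- function(image, tile_size_px = 1024L, stride_px = tile_size_px,
                            mpp = attr(image, "mpp"), slide_id = attr(image, "slide_id")) {
  tile_size_px <- assert_count(tile_size_px, "tile_size_px", min = 1L)
  stride_px <- assert_count(stride_px, "stride_px", min = 1L)
  if (is.null(mpp) || !is.finite(mpp) || mpp <= 0)
    stop("`mpp` must be supplied and positive", call. = FALSE)
  if (is.null(slide_id)) slide_id <- NA_character_
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("`image` must be an H x W x 3 RGB array")
  H <- d[1]; W <- d[2]; T <- tile_size_px; S <- stride_px

  if (W < T || H < T) return(list())
  xs <- seq(0L, W - T, by = S)
  ys <- seq(0L, H - T, by = S)
  out <- vector("list", length(xs) * length(ys))
  k <- 0L
  for (y in ys) {       # row-major from the top-left
    for (x in xs) {
      k <- k + 1L
      out[[k]] <- tile_image(unclass(image)[(y + 1L):(y + T), (x + 1L):(x + T), , drop = FALSE],
                             mpp = mpp, slide_id = slide_id,
                             x_offset_px = x, y_offset_px = y)
    }
  }
  out
}

#' Number of full tiles a window scan yields
#' @param width_px,height_px Image dimensions.
#' @param tile_size_px,stride_px Window size and step.
#' @return Integer tile count: `(floor((W-T)/S)+1) * (floor((H-T)/S)+1)` when
#'   both dimensions admit a window, else 0.
#' @export
tile_count <- function(width_px, height_px, tile_size_px = 1024L,
                       stride_px = tile_size_px) {
  if (width_px < tile_size_px || height_px < tile_size_px) return(0L)
  as.integer((floor((width_px - tile_size_px) / stride_px) + 1) *
             (floor((height_px - tile_size_px) / stride_px) + 1))
}

#' Write tiles as PNG plus an index TSV
#'
#' Files are named `{slide_id}_{x}_{y}.png` by tile offset.
#'
#' @param tiles List of `tile_image` objects.
#' @param dir Output directory.
#' @return Invisibly, the index data.frame.
#' @export
write_tiles <- function(tiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(tiles, function(t) {
    fn <- sprintf("%s_%d_%d.png", attr(t, "slide_id"),
                  attr(t, "x_offset_px"), attr(t, "y_offset_px"))
    png::writePNG(unclass(t), file.path(dir, fn))
    data.frame(slide_id = attr(t, "slide_id"), file = fn,
               x_offset_px = attr(t, "x_offset_px"),
               y_offset_px = attr(t, "y_offset_px"), mpp = attr(t, "mpp"))
  })
  index <- do.call(rbind, rows)
  write.table(index, file.path(dir, "tile_index.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(index)
}
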