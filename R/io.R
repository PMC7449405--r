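# Reading and writing the pipeline's raster interchange formats: binary masks
# as single-channel PNG with {0, 255}, probability maps as 32-bit float TIFF.

#' Read / write binary segmentation masks as PNG
#'
#' Masks are stored as single-channel PNG where foreground is 255 and
#' background 0.
#'
#' @param mask Binary 0/1 matrix.
#' @param path File path.
#' @return `read_mask_png` returns a `segmentation_mask` (integer 0/1 matrix).
#' @export
write_mask_png <- function(mask, path) {
  m <- check_binary_mask(mask, "mask")
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  structure(matrix(as.integer(img > 0.5), nrow(img), ncol(img)),
            class = "segmentation_mask")
}

#' Read / write probability maps as float TIFF
#'
#' @param prob_map Numeric matrix in \[0, 1\].
#' @param path File path.
#' @return `read_probability_map` returns a `probability_map` matrix.
#' @export
write_probability_map <- function(prob_map, path) {
  p <- unclass(prob_map)
  stopifnot(is.matrix(p), all(p >= 0 & p <= 1))
  tiff::writeTIFF(p, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_probability_map
#' @export
read_probability_map <- function(path) {
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  structure(p, class = "probability_map")
}
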