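#' Absorption-image TIFF I/O
#'
#' Absorption images are written as single-channel 32-bit float TIFF. The
#' underlying TIFF writer stores samples on a \[0, 1\] scale, so values are
#' divided by a fixed scale factor (`DEXA_TIFF_SCALE = 16`) on write and
#' multiplied back on read; absorption rates above 16 correspond to
#' transmitted fractions below `exp(-16)`, far beyond any measurable signal.
#' Use the paired reader so the scale cancels exactly.
#'
#' @param x Numeric matrix of absorption rates (or any nonnegative image).
#' @param path Output file path.
#' @return `write_absorption_tiff()`: the path, invisibly;
#'   `read_absorption_tiff()`: a numeric matrix.
#' @export
write_absorption_tiff <- function(x, path) {
  stopifnot(is.matrix(x))
  if (any(!is.finite(x))) stop("image contains non-finite values")
  if (max(x) > DEXA_TIFF_SCALE)
    warning("values above the TIFF scale factor will be clipped")
  tiff::writeTIFF(pmin(pmax(x / DEXA_TIFF_SCALE, 0), 1), path,
                  bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_absorption_tiff
#' @export
read_absorption_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x * DEXA_TIFF_SCALE
}

#' @rdname write_absorption_tiff
#' @export
DEXA_TIFF_SCALE <- 16

#' Binary-mask PNG I/O
#'
#' Masks are stored as 8-bit single-channel PNG with values 0/255.
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @return `write_mask_png()`: the path, invisibly; `read_mask_png()`: a
#'   logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}
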