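#' Construct an OCT-A en-face image object
#'
#' An `octa_image` bundles an 8-bit grayscale intensity matrix with the scan
#' metadata the pipeline uses: physical scan width (en-face OCT-A scans are
#' nominally 3 x 3 mm) and the device-reported signal quality index (0-10;
#' scans below 7 are conventionally excluded).
#'
#' @param pixels integer or numeric matrix, values in 0-255, indexed
#'   `[row, col]` with origin top-left.
#' @param scan_width_mm physical width of the scan in millimetres.
#' @param quality_index integer signal quality score in 0-10, or `NA` if
#'   unknown.
#' @param source_id opaque identifier for provenance (defaults to "").
#' @return An object of class `octa_image`.
#' @examples
#' img <- octa_image(matrix(120L, 32, 32))
#' dim(img)
#' @export
octa_image <- function(pixels, scan_width_mm = 3, quality_index = NA_integer_,
                       source_id = "") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1x1")
  px <- pixels
  storage.mode(px) <- "double"
  if (anyNA(px)) stop("image contains NA pixels")
  if (min(px) < 0 || max(px) > 255) stop("intensities must lie in [0, 255]")
  px <- round(px)
  storage.mode(px) <- "integer"
  if (!is.na(quality_index)) {
    quality_index <- as.integer(quality_index)
    if (quality_index < 0L || quality_index > 10L)
      stop("quality_index must be in 0-10")
  }
  structure(
    list(pixels = px, scan_width_mm = as.numeric(scan_width_mm),
         quality_index = quality_index, source_id = as.character(source_id)),
    class = "octa_image"
  )
}

#' @export
dim.octa_image <- function(x) dim(x$pixels)

#' @export
print.octa_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<octa_image> %d x %d px, %.1f mm scan, quality %s%s\n",
              d[1], d[2], x$scan_width_mm,
              ifelse(is.na(x$quality_index), "NA", x$quality_index),
              if (nzchar(x$source_id)) paste0(", id=", x$source_id) else ""))
  invisible(x)
}

#' Coerce to a binary segmentation mask
#'
#' Masks are plain logical matrices aligned pixel-for-pixel with their
#' companion image. Numeric input is accepted if every value is 0 or 1.
#'
#' @param x logical or 0/1 numeric matrix.
#' @return logical matrix.
#' @export
as_seg_mask <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) stop("mask must be a matrix")
  if (is.logical(x)) return(x)
  if (!all(x %in% c(0, 1))) stop("mask values must be 0/1")
  matrix(as.logical(x), nrow(x), ncol(x))
}

# internal: pull the pixel matrix out of an octa_image or accept a raw matrix
img_pixels <- function(image) {
  if (inherits(image, "octa_image")) image$pixels else {
    if (!is.matrix(image)) stop("expected an octa_image or a matrix")
    image
  }
}

check_same_dim <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("dimension mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

# Run `expr` with a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic steps in the package route through this so that identical
# (params, seed) give bit-identical output regardless of ambient RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
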