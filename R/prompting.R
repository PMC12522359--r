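#' Euclidean distance transform of a mask
#'
#' For every foreground pixel, the exact Euclidean distance (in pixels) to
#' the nearest background pixel, with the frame border acting as background:
#' a mask touching the border still has finite interior distances, and a
#' full-frame mask has a well-defined most-interior point. Background pixels
#' are exactly 0. Computed with `EBImage::distmap` on a one-pixel
#' background-padded frame (the nearest out-of-frame source always lies in
#' the first padding ring).
#'
#' @param mask nonempty logical or 0/1 mask matrix.
#' @return numeric matrix of distances, same dimensions as `mask`.
#' @export
distance_transform <- function(mask) {
  mask <- as_seg_mask(mask)
  if (!any(mask)) stop("distance transform of an empty mask is undefined")
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(0, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  d <- EBImage::imageData(EBImage::distmap(padded, metric = "euclidean"))
  d[2:(h + 1L), 2:(w + 1L), drop = FALSE]
}

#' Place the foreground prompt point of a mask
#'
#' Returns the argmax of [distance_transform()] — the most interior pixel of
#' the mask, i.e. the natural seed for a promptable segmenter given a
#' reference FAZ annotation. Ties are broken by smallest row, then smallest
#' column (compared on exact squared distances), so the choice is
#' deterministic across platforms.
#'
#' @param mask nonempty logical or 0/1 mask matrix.
#' @return object of class `prompt_point`: list with integer `row`, `col`
#'   (1-based), `role = "foreground"` and the attained `distance`.
#' @export
place_prompt_point <- function(mask) {
  d <- distance_transform(mask)
  # compare on squared distances: integers, so ties are exact
  d2 <- round(d^2)
  cand <- which(d2 == max(d2), arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  prompt_point(cand[1, 1], cand[1, 2], distance = d[cand[1, 1], cand[1, 2]])
}

prompt_point <- function(row, col, distance = NA_real_) {
  structure(list(row = as.integer(row), col = as.integer(col),
                 role = "foreground", distance = distance),
            class = "prompt_point")
}

#' @export
print.prompt_point <- function(x, ...) {
  cat(sprintf("<prompt_point> (row %d, col %d)%s\n", x$row, x$col,
              if (!is.na(x$distance)) sprintf(", depth %.2f px", x$distance)
              else ""))
  invisible(x)
}

#' Serialize / deserialize a prompt point as a JSON record
#'
#' Records `{row, col, role, indexing: "1-based"}` for audit logs.
#' @param x a `prompt_point`.
#' @return JSON string.
#' @export
prompt_to_json <- function(x) {
  jsonlite::toJSON(list(row = x$row, col = x$col, role = x$role,
                        indexing = "1-based"), auto_unbox = TRUE)
}

#' @rdname prompt_to_json
#' @param json JSON string as produced by `prompt_to_json`.
#' @export
prompt_from_json <- function(json) {
  v <- jsonlite::fromJSON(json)
  prompt_point(v$row, v$col)
}

#' Reference-free prompt placement from a dark-region prior
#'
#' For inference without annotations: smooths the image (Gaussian,
#' `sigma` px), thresholds pixels at or below a quantile of the smoothed
#' intensities inside a central window (the FAZ sits near the macular centre
#' of a well-acquired scan), takes the largest dark connected component
#' there, and returns its [place_prompt_point()]. If no dark component is
#' found the image centre is returned with a warning.
#'
#' @param image an [octa_image] or intensity matrix.
#' @param quantile_dark quantile defining "dark" within the window
#'   (default 0.15).
#' @param window central-window fraction of each dimension (default 0.5).
#' @param sigma Gaussian smoothing sigma in pixels (default 2).
#' @return a `prompt_point` (always; degenerate inputs fall back to centre).
#' @export
place_prompt_from_prior <- function(image, quantile_dark = 0.15,
                                    window = 0.5, sigma = 2) {
  px <- img_pixels(image)
  h <- nrow(px); w <- ncol(px)
  sm <- smooth_image(px, sigma)
  r0 <- max(1L, floor(h / 2 - window * h / 2) + 1L)
  r1 <- min(h, ceiling(h / 2 + window * h / 2))
  c0 <- max(1L, floor(w / 2 - window * w / 2) + 1L)
  c1 <- min(w, ceiling(w / 2 + window * w / 2))
  win <- sm[r0:r1, c0:c1, drop = FALSE]
  thr <- stats::quantile(win, quantile_dark, names = FALSE)
  dark <- win <= thr
  # a flat window makes every pixel "dark"; treat as no usable component
  if (all(dark) || !any(dark)) {
    warning("no dark component found; falling back to image centre")
    return(prompt_point(round(h / 2), round(w / 2)))
  }
  lab <- EBImage::bwlabel(dark)
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  pt <- place_prompt_point(comp)
  prompt_point(pt$row + r0 - 1L, pt$col + c0 - 1L, distance = pt$distance)
}

# Gaussian smoothing via EBImage; sigma = 0 returns the input unchanged.
smooth_image <- function(px, sigma) {
  if (sigma <= 0) return(px)
  EBImage::imageData(EBImage::gblur(px, sigma = sigma))
}
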