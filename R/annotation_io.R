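#' Polygon annotation in LabelMe convention
#'
#' A labelled polygon with sub-pixel `(x, y)` vertices, origin at the
#' top-left image corner (the centre of pixel `(r, c)` in 1-based matrix
#' indexing is `(x, y) = (c - 0.5, r - 0.5)`).
#'
#' @param label label string (e.g. `"FAZ"`).
#' @param points numeric matrix with two columns `(x, y)`, at least 3 rows.
#' @param image_height,image_width canvas dimensions in pixels.
#' @return object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(label, points, image_height, image_width) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must have two columns (x, y)")
  if (nrow(points) < 3L) stop("polygon needs at least 3 points")
  storage.mode(points) <- "double"
  if (anyNA(points)) stop("polygon points contain NA")
  if (min(points[, 1]) < 0 || max(points[, 1]) > image_width ||
      min(points[, 2]) < 0 || max(points[, 2]) > image_height)
    stop("polygon points fall outside [0, width] x [0, height]")
  structure(list(label = as.character(label), points = unname(points),
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width)),
            class = "polygon_annotation")
}

#' Read LabelMe polygon annotations
#'
#' Parses a LabelMe-dialect JSON document (fields `shapes[].label`,
#' `shapes[].points`, `shapes[].shape_type`, `imageHeight`, `imageWidth`).
#' Only polygon-type shapes are returned; any other shape type is skipped
#' with a warning. A polygon shape with fewer than 3 points is an error that
#' names the offending shape index.
#'
#' @param document path to a JSON file, or a JSON string.
#' @param label optional label filter; if given, only annotations whose label
#'   matches exactly are returned. Default `NULL` keeps all.
#' @return list of [polygon_annotation] objects (possibly empty).
#' @export
read_labelme <- function(document, label = NULL) {
  txt <- if (length(document) == 1L && file.exists(document))
    paste(readLines(document, warn = FALSE), collapse = "\n") else document
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) stop("malformed LabelMe JSON: ",
                                           conditionMessage(e)))
  h <- doc$imageHeight; w <- doc$imageWidth
  if (is.null(h) || is.null(w))
    stop("LabelMe document lacks imageHeight/imageWidth")
  out <- list()
  for (i in seq_along(doc$shapes)) {
    sh <- doc$shapes[[i]]
    st <- if (is.null(sh$shape_type)) "polygon" else sh$shape_type
    if (!identical(st, "polygon")) {
      warning(sprintf("shape %d has type '%s'; skipped", i, st))
      next
    }
    if (length(sh$points) < 3L)
      stop(sprintf("shape %d: polygon has fewer than 3 points", i))
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    out[[length(out) + 1L]] <-
      polygon_annotation(sh$label, pts, image_height = h, image_width = w)
  }
  if (!is.null(label)) out <- Filter(function(a) a$label == label, out)
  out
}

#' Write LabelMe polygon annotations
#'
#' @param annotations list of [polygon_annotation] objects sharing one canvas.
#' @param path output JSON path.
#' @param image_path optional value for the `imagePath` field.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(annotations, path, image_path = "") {
  if (length(annotations) == 0L) stop("no annotations to write")
  h <- annotations[[1]]$image_height; w <- annotations[[1]]$image_width
  shapes <- lapply(annotations, function(a) {
    list(label = a$label,
         points = lapply(seq_len(nrow(a$points)),
                         function(i) as.list(unname(a$points[i, ]))),
         group_id = NULL, shape_type = "polygon", flags = list())
  })
  doc <- list(version = "5.0.1", flags = list(), shapes = shapes,
              imagePath = image_path, imageData = NULL,
              imageHeight = h, imageWidth = w)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                              digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' Rasterize a polygon annotation to a binary mask
#'
#' A pixel `(r, c)` is foreground iff its centre `(c - 0.5, r - 0.5)` lies
#' inside the polygon under the even-odd rule; centres that fall exactly on a
#' polygon edge are resolved as inside. Self-intersecting polygons are
#' handled by the even-odd rule with a warning.
#'
#' @param annotation a [polygon_annotation], or a plain two-column `(x, y)`
#'   matrix (then `height`/`width` are required).
#' @param height,width canvas dimensions; default from the annotation.
#' @return logical mask matrix `height x width`.
#' @export
rasterize_polygon <- function(annotation, height = NULL, width = NULL) {
  if (inherits(annotation, "polygon_annotation")) {
    pts <- annotation$points
    if (is.null(height)) height <- annotation$image_height
    if (is.null(width)) width <- annotation$image_width
  } else {
    pts <- as.matrix(annotation)
    if (is.null(height) || is.null(width))
      stop("height/width required for a bare point matrix")
  }
  if (nrow(pts) < 3L) stop("polygon needs at least 3 points")
  if (polygon_self_intersects(pts))
    warning("self-intersecting polygon; even-odd rule applied")
  mask <- matrix(FALSE, height, width)
  # restrict work to the polygon bounding box
  rmin <- max(1L, floor(min(pts[, 2]) + 0.5))
  rmax <- min(height, ceiling(max(pts[, 2]) + 0.5))
  cmin <- max(1L, floor(min(pts[, 1]) + 0.5))
  cmax <- min(width, ceiling(max(pts[, 1]) + 0.5))
  if (rmin > rmax || cmin > cmax) return(mask)
  rows <- rmin:rmax; cols <- cmin:cmax
  py <- matrix(rows - 0.5, length(rows), length(cols))         # y = r - 0.5
  px <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE)
  crossings <- matrix(0L, length(rows), length(cols))
  onedge <- matrix(FALSE, length(rows), length(cols))
  n <- nrow(pts)
  eps <- 1e-9
  for (e in seq_len(n)) {
    x1 <- pts[e, 1]; y1 <- pts[e, 2]
    j <- if (e == n) 1L else e + 1L
    x2 <- pts[j, 1]; y2 <- pts[j, 2]
    straddles <- (y1 > py) != (y2 > py)
    if (any(straddles)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      crossings <- crossings + (straddles & (px < xint))
    }
    # exact-on-edge test: squared distance from pixel centre to segment
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    if (L2 < eps) next
    t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
    d2 <- (px - x1 - t * dx)^2 + (py - y1 - t * dy)^2
    onedge <- onedge | (d2 <= eps)
  }
  mask[rows, cols] <- (crossings %% 2L == 1L) | onedge
  mask
}

# O(n^2) proper-crossing check over all non-adjacent edge pairs, vectorized
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  if (n < 4L) return(FALSE)
  nxt <- c(2:n, 1L)
  ij <- which(lower.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- ij[, 2]; j <- ij[, 1]                       # j > i
  keep <- (j > i + 1L) & !(i == 1L & j == n)       # skip adjacent edges
  i <- i[keep]; j <- j[keep]
  ax <- pts[i, 1]; ay <- pts[i, 2]; bx <- pts[nxt[i], 1]; by <- pts[nxt[i], 2]
  cx <- pts[j, 1]; cy <- pts[j, 2]; dx <- pts[nxt[j], 1]; dy <- pts[nxt[j], 2]
  o1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  o2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  o3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  o4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  any(o1 * o2 < 0 & o3 * o4 < 0)
}

# ---- PNG I/O -------------------------------------------------------------

# Minimal IHDR inspection so 16-bit / multi-channel inputs are rejected
# rather than silently rescaled (png::readPNG converts everything to [0,1]).
png_header <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 26L)
  if (length(hdr) < 26L ||
      !identical(hdr[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47,
                                    0x0d, 0x0a, 0x1a, 0x0a))))
    stop("not a PNG file: ", path)
  list(bit_depth = as.integer(hdr[25]), color_type = as.integer(hdr[26]))
}

#' Read a binary mask from an 8-bit grayscale PNG
#'
#' Foreground iff the stored 8-bit value is >= 128 (midpoint rule, so
#' anti-aliased 127 is background and 128 foreground). Multi-channel or
#' 16-bit PNGs are a format error.
#'
#' @param path PNG path.
#' @return logical mask matrix.
#' @export
read_mask_png <- function(path) {
  hd <- png_header(path)
  if (hd$color_type != 0L || hd$bit_depth != 8L)
    stop("mask PNG must be 8-bit single-channel grayscale: ", path)
  v <- png::readPNG(path)
  round(v * 255) >= 128
}

#' Write a binary mask as an 8-bit grayscale PNG (0 background, 255 fg)
#'
#' @param mask logical or 0/1 mask matrix.
#' @param path output path.
#' @return `path`, invisibly. Write-then-read is the identity.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_seg_mask(mask)
  png::writePNG(matrix(ifelse(mask, 1, 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Load an OCT-A image from PNG
#'
#' Accepts 8-bit single-channel grayscale or 8-bit RGB (converted by Rec. 601
#' luminance, 0.299 R + 0.587 G + 0.114 B, rounded). If a JSON sidecar
#' `<stem>.json` with fields `scan_width_mm` / `quality_index` / `source_id`
#' sits next to the PNG it populates the metadata.
#'
#' @param path PNG path.
#' @param scan_width_mm,quality_index,source_id metadata overrides; defaults
#'   come from the sidecar when present, else 3 mm / `NA` / the file stem.
#' @return an [octa_image].
#' @export
load_image <- function(path, scan_width_mm = NULL, quality_index = NULL,
                       source_id = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  hd <- png_header(path)
  if (hd$bit_depth != 8L || !(hd$color_type %in% c(0L, 2L)))
    stop("image PNG must be 8-bit grayscale or RGB: ", path)
  v <- png::readPNG(path)
  px <- if (length(dim(v)) == 3L) {
    round(255 * (0.299 * v[, , 1] + 0.587 * v[, , 2] + 0.114 * v[, , 3]))
  } else round(v * 255)
  meta <- list()
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  pick <- function(override, key, default)
    if (!is.null(override)) override
    else if (!is.null(meta[[key]])) meta[[key]] else default
  octa_image(px,
             scan_width_mm = pick(scan_width_mm, "scan_width_mm", 3),
             quality_index = pick(quality_index, "quality_index", NA_integer_),
             source_id = pick(source_id, "source_id",
                              tools::file_path_sans_ext(basename(path))))
}

#' Write an OCT-A image as an 8-bit grayscale PNG
#'
#' @param image an [octa_image] or 0-255 matrix.
#' @param path output path.
#' @param sidecar write a `<stem>.json` metadata sidecar (default TRUE for
#'   `octa_image` input).
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path, sidecar = inherits(image, "octa_image")) {
  px <- img_pixels(image)
  png::writePNG(px / 255, path)
  if (sidecar && inherits(image, "octa_image")) {
    meta <- list(scan_width_mm = image$scan_width_mm,
                 quality_index = image$quality_index,
                 source_id = image$source_id)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"),
               paste0(tools::file_path_sans_ext(path), ".json"))
  }
  invisible(path)
}
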