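# Independent brute-force oracles. These deliberately use naive scalar
# algorithms so they share no code path with the implementation they check.

# Point-in-polygon oracle: even-odd crossing count evaluated per pixel
# centre, with an explicit on-edge test (on-edge counts as inside).
oracle_rasterize <- function(pts, height, width) {
  n <- nrow(pts)
  inside_one <- function(x, y) {
    crossings <- 0L
    for (e in seq_len(n)) {
      x1 <- pts[e, 1]; y1 <- pts[e, 2]
      j <- if (e == n) 1L else e + 1L
      x2 <- pts[j, 1]; y2 <- pts[j, 2]
      # on-edge?
      dx <- x2 - x1; dy <- y2 - y1
      L2 <- dx^2 + dy^2
      if (L2 > 0) {
        t <- max(0, min(1, ((x - x1) * dx + (y - y1) * dy) / L2))
        if ((x - x1 - t * dx)^2 + (y - y1 - t * dy)^2 <= 1e-9) return(TRUE)
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
        if (x < xint) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }
  m <- matrix(FALSE, height, width)
  for (r in seq_len(height))
    for (c in seq_len(width))
      m[r, c] <- inside_one(c - 0.5, r - 0.5)
  m
}

# All-sources Euclidean distance oracle: for each foreground pixel, the
# minimum distance over every background pixel of the one-pixel padded grid.
oracle_edt <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  bg <- which(!padded, arr.ind = TRUE)
  d <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c])
      d[r, c] <- sqrt(min((bg[, 1] - (r + 1))^2 + (bg[, 2] - (c + 1))^2))
  }
  d
}

# Sort-and-interpolate quantile oracle (linear interpolation between
# closest ranks): h = (n - 1) p + 1, interpolate x_(floor(h)), x_(ceil(h)).
oracle_quantile <- function(x, p) {
  xs <- sort(x); n <- length(xs)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }, numeric(1))
}

# Pixel-enumeration confusion oracle
oracle_confusion <- function(pred, gt) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && gt[i]) tp <- tp + 1L
    else if (pred[i] && !gt[i]) fp <- fp + 1L
    else if (!pred[i] && gt[i]) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, fn = fn)
}

random_mask <- function(h, w, p = 0.5, nonempty = TRUE) {
  repeat {
    m <- matrix(stats::runif(h * w) < p, h, w)
    if (!nonempty || any(m)) return(m)
  }
}

# Random star-shaped polygon (radii about a centre): never self-intersects
random_star_polygon <- function(h, w, n_vertices = 12) {
  cx <- stats::runif(1, w * 0.3, w * 0.7)
  cy <- stats::runif(1, h * 0.3, h * 0.7)
  theta <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rmax <- 0.45 * min(cx, w - cx, cy, h - cy) * 2
  r <- stats::runif(n_vertices, 0.3 * rmax, rmax)
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}
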