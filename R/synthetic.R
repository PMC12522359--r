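#' Parameters of a synthetic OCT-A scene
#'
#' Describes one synthetic en-face OCT-A scene: a dark, irregular, roughly
#' central avascular region (the FAZ stand-in) surrounded by bright
#' curvilinear vessel strokes on a mid-gray background, with speckle-like
#' Gaussian noise and optional acquisition artifacts. The FAZ outline is a
#' radial-harmonic polygon r(theta) = R (1 + sum_k a_k sin(k theta + phi_k))
#' with coefficients drawn deterministically from `seed` and bounded so that
#' sum |a_k| <= `irregularity_amplitude`.
#'
#' Defaults place a ~0.44 mm^2 FAZ (radius 32 px) at the centre of a
#' 256 x 256 px, 3 x 3 mm scan — within the range reported for healthy eyes.
#'
#' @param height,width image dimensions in pixels.
#' @param faz_center `(row, col)` centre of the FAZ; default frame centre.
#' @param base_radius mean FAZ radius R in pixels (>= 3, < min(dim)/2).
#' @param irregularity_harmonics number of radial harmonics K.
#' @param irregularity_amplitude bound on the summed harmonic amplitudes,
#'   as a fraction of `base_radius`, in `[0, 0.5]`.
#' @param vessel_density stroke coverage control in `[0, 1]`.
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units, >= 0).
#' @param artifact_kind one of `"none"`, `"motion_stripe"` (bands of rows
#'   replaced by horizontally shifted, dimmed copies), `"decentered"` (FAZ
#'   displaced off-centre; applied consistently to image and ground truth).
#' @param quality_index scan quality 0-10; `NULL` derives a default from the
#'   artifact kind (none: 10, motion_stripe: 6, decentered: 7).
#' @param seed integer RNG seed for this scene.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(height = 256, width = 256, faz_center = NULL,
                         base_radius = 32, irregularity_harmonics = 4,
                         irregularity_amplitude = 0.25, vessel_density = 0.5,
                         noise_sd = 8,
                         artifact_kind = c("none", "motion_stripe", "decentered"),
                         quality_index = NULL, seed = 1) {
  artifact_kind <- match.arg(artifact_kind)
  if (is.null(faz_center)) faz_center <- c(round(height / 2), round(width / 2))
  if (base_radius < 3 || base_radius >= min(height, width) / 2)
    stop("base_radius must be >= 3 and < min(height, width)/2")
  if (irregularity_amplitude < 0 || irregularity_amplitude > 0.5)
    stop("irregularity_amplitude must lie in [0, 0.5]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (vessel_density < 0 || vessel_density > 1)
    stop("vessel_density must lie in [0, 1]")
  if (is.null(quality_index))
    quality_index <- switch(artifact_kind, none = 10L, motion_stripe = 6L,
                            decentered = 7L)
  structure(list(height = as.integer(height), width = as.integer(width),
                 faz_center = as.integer(round(faz_center)),
                 base_radius = base_radius,
                 irregularity_harmonics = as.integer(irregularity_harmonics),
                 irregularity_amplitude = irregularity_amplitude,
                 vessel_density = vessel_density, noise_sd = noise_sd,
                 artifact_kind = artifact_kind,
                 quality_index = as.integer(quality_index),
                 seed = as.integer(seed)),
            class = "scene_params")
}

# Radial-harmonic FAZ outline as a LabelMe-convention (x, y) polygon.
# Vertices at 1-degree steps; deterministic in params$seed.
faz_polygon <- function(params, n_vertices = 360L) {
  K <- params$irregularity_harmonics
  A <- params$irregularity_amplitude
  coef <- local_seed(params$seed + 101L, {
    list(a = if (K > 0) A * runif(K, -1, 1) / K else numeric(0),
         phi = if (K > 0) runif(K, 0, 2 * pi) else numeric(0))
  })
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- rep(params$base_radius, n_vertices)
  for (k in seq_len(K))
    r <- r + params$base_radius * coef$a[k] * sin(k * theta + coef$phi[k])
  cx <- params$faz_center[2] - 0.5      # pixel centre in (x, y)
  cy <- params$faz_center[1] - 0.5
  x <- cx + r * cos(theta)
  y <- cy + r * sin(theta)
  if (min(x) < 0 || max(x) > params$width || min(y) < 0 || max(y) > params$height)
    stop("FAZ radius/centre combination exits the image frame")
  cbind(x, y)
}

#' Generate the ground-truth FAZ mask for a synthetic scene
#'
#' Rasterizes the radial-harmonic outline (see [scene_params()]) with the
#' package's pixel-centre even-odd rule. The result is a single connected
#' component containing `faz_center`. The generating polygon is attached as
#' attribute `"polygon"` (a LabelMe-convention `(x, y)` matrix) so fixtures
#' can be exported as annotations.
#'
#' @param params a [scene_params] object.
#' @return logical mask matrix with attribute `"polygon"`.
#' @export
generate_faz_mask <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  poly <- faz_polygon(params)
  mask <- rasterize_polygon(poly, height = params$height, width = params$width)
  if (!mask[params$faz_center[1], params$faz_center[2]])
    stop("internal error: faz_center not inside generated mask")
  attr(mask, "polygon") <- poly
  mask
}

# Draw bright curvilinear strokes (vessel stand-ins) onto a canvas matrix.
# Each stroke is a correlated random walk; pixels are set to the stroke
# brightness. Runs inside the caller's RNG stream.
draw_vessel_strokes <- function(canvas, density) {
  h <- nrow(canvas); w <- ncol(canvas)
  n_strokes <- round(density * h * w / 600)
  for (s in seq_len(n_strokes)) {
    r <- runif(1, 1, h); c <- runif(1, 1, w)
    ang <- runif(1, 0, 2 * pi)
    len <- round(runif(1, 40, 120))
    bright <- runif(1, 170, 235)
    thick <- sample(1:2, 1)
    for (step in seq_len(len)) {
      ang <- ang + rnorm(1, 0, 0.15)
      r <- r + sin(ang); c <- c + cos(ang)
      ri <- round(r); ci <- round(c)
      if (ri < 1 || ri > h || ci < 1 || ci > w) break
      canvas[ri, ci] <- bright
      if (thick == 2L) {
        if (ri < h) canvas[ri + 1L, ci] <- bright
        if (ci < w) canvas[ri, ci + 1L] <- bright
      }
    }
  }
  canvas
}

# Motion-stripe artifact: two horizontal bands whose rows are replaced by a
# horizontally (circularly) shifted, dimmed copy of themselves. Band
# placement/shift drawn from the artifact stream (params$seed + 303).
apply_motion_stripe <- function(px, params) {
  h <- nrow(px)
  local_seed(params$seed + 303L, {
    for (b in 1:2) {
      bh <- sample(24:40, 1)
      top <- sample(seq_len(max(1L, h - bh)), 1)
      rows <- top:(top + bh - 1L)
      shift <- sample(8:20, 1) * sample(c(-1L, 1L), 1)
      band <- px[rows, , drop = FALSE]
      idx <- ((seq_len(ncol(px)) - 1L - shift) %% ncol(px)) + 1L
      px[rows, ] <- band[, idx, drop = FALSE] * 0.85
    }
  })
  px
}

#' Render a synthetic OCT-A image for a ground-truth mask
#'
#' Paints a mid-gray background (120), bright curvilinear vessel strokes at
#' the configured density, a dark (40) FAZ interior, then adds Gaussian noise
#' clipped to 0-255. `artifact_kind = "motion_stripe"` corrupts two row bands
#' (see [scene_params()]); `"decentered"` is realised at sample-generation
#' time by displacing `faz_center`, so rendering itself applies no further
#' change. Deterministic in `params$seed`.
#'
#' @param gt_mask logical mask matching `params` dimensions.
#' @param params a [scene_params] object.
#' @return an [octa_image].
#' @export
render_octa_image <- function(gt_mask, params) {
  stopifnot(inherits(params, "scene_params"))
  gt_mask <- as_seg_mask(gt_mask)
  if (!identical(dim(gt_mask), c(params$height, params$width)))
    stop("gt_mask dimensions do not match params")
  px <- local_seed(params$seed + 202L, {
    canvas <- matrix(120, params$height, params$width)
    canvas <- draw_vessel_strokes(canvas, params$vessel_density)
    canvas[gt_mask] <- 40
    if (params$noise_sd > 0)
      canvas <- canvas + rnorm(length(canvas), 0, params$noise_sd)
    canvas
  })
  if (params$artifact_kind == "motion_stripe")
    px <- apply_motion_stripe(px, params)
  px <- pmin(pmax(px, 0), 255)    # argument order keeps the matrix shape
  octa_image(px, scan_width_mm = 3, quality_index = params$quality_index,
             source_id = sprintf("synthetic_seed%d", params$seed))
}

#' Generate one synthetic sample (image + ground truth)
#'
#' For `artifact_kind = "decentered"` the FAZ centre is displaced by a seeded
#' offset (40-70 px per axis, clipped so the outline stays in frame) before
#' mask generation, so image and ground truth remain consistent and the
#' centre always lies inside the mask.
#'
#' @param params a [scene_params] object.
#' @return list with elements `image` ([octa_image]), `gt_mask` (logical
#'   matrix), `params`; class `faz_sample`.
#' @export
generate_sample <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  if (params$artifact_kind == "decentered") {
    off <- local_seed(params$seed + 303L, {
      c(sample(40:70, 1) * sample(c(-1L, 1L), 1),
        sample(40:70, 1) * sample(c(-1L, 1L), 1))
    })
    maxr <- ceiling(params$base_radius * (1 + params$irregularity_amplitude)) + 2L
    ctr <- params$faz_center + off
    ctr[1] <- min(max(ctr[1], maxr + 1L), params$height - maxr)
    ctr[2] <- min(max(ctr[2], maxr + 1L), params$width - maxr)
    params$faz_center <- as.integer(ctr)
  }
  gt <- generate_faz_mask(params)
  img <- render_octa_image(gt, params)
  structure(list(image = img, gt_mask = gt, params = params),
            class = "faz_sample")
}

#' @export
print.faz_sample <- function(x, ...) {
  cat(sprintf("<faz_sample> seed %d, %s artifact, FAZ area %d px (%.2f%%)\n",
              x$params$seed, x$params$artifact_kind, sum(x$gt_mask),
              100 * mean(x$gt_mask)))
  invisible(x)
}

#' Generate a seeded synthetic cohort
#'
#' Produces `n` samples with per-sample seeds `base_seed + index - 1`, so any
#' sample can be regenerated in isolation. Per-sample FAZ geometry (radius
#' jitter and centre jitter) is drawn from the per-sample seed. Exactly
#' `round(n * artifact_fraction)` samples — the last ones, alternating
#' motion_stripe / decentered — carry an artifact; their quality index is
#' drawn from a seeded range (motion_stripe 5-8, decentered 6-9) while clean
#' samples get 10, so a quality gate at 7 has both retained and excluded
#' artifact scans. Because geometry and artifact draws use separate RNG
#' streams, cohorts with the same `base_seed` but different
#' `artifact_fraction` share identical FAZ geometry sample-for-sample.
#'
#' @param n number of samples (>= 1).
#' @param base_seed integer base seed.
#' @param artifact_fraction fraction of samples carrying artifacts, in `[0,1]`.
#' @param height,width image dimensions.
#' @param vessel_density,noise_sd,irregularity_amplitude,irregularity_harmonics
#'   passed to [scene_params()].
#' @return list of `faz_sample` objects, length `n`.
#' @export
generate_cohort <- function(n, base_seed = 1, artifact_fraction = 0,
                            height = 256, width = 256, vessel_density = 0.5,
                            noise_sd = 8, irregularity_amplitude = 0.25,
                            irregularity_harmonics = 4) {
  if (n < 1) stop("n must be >= 1")
  if (artifact_fraction < 0 || artifact_fraction > 1)
    stop("artifact_fraction must lie in [0, 1]")
  k <- round(n * artifact_fraction)
  kinds <- rep("none", n)
  if (k > 0)
    kinds[(n - k + 1L):n] <- rep(c("motion_stripe", "decentered"),
                                 length.out = k)
  lapply(seq_len(n), function(i) {
    seed_i <- as.integer(base_seed + i - 1L)
    geo <- local_seed(seed_i, {
      list(radius = runif(1, 0.109, 0.141) * min(height, width),
           jitter = c(sample(-10:10, 1), sample(-10:10, 1)),
           qdraw = runif(2))       # always consumed: keeps streams aligned
    })
    kind <- kinds[i]
    quality <- switch(kind,
      none = 10L,
      motion_stripe = 5L + as.integer(floor(geo$qdraw[1] * 4)),   # 5..8
      decentered = 6L + as.integer(floor(geo$qdraw[2] * 4)))      # 6..9
    p <- scene_params(height = height, width = width,
                      faz_center = c(round(height / 2) + geo$jitter[1],
                                     round(width / 2) + geo$jitter[2]),
                      base_radius = geo$radius,
                      irregularity_harmonics = irregularity_harmonics,
                      irregularity_amplitude = irregularity_amplitude,
                      vessel_density = vessel_density, noise_sd = noise_sd,
                      artifact_kind = kind, quality_index = quality,
                      seed = seed_i)
    generate_sample(p)
  })
}
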