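#' Dark-region threshold stage of the fallback proposal generator
#'
#' Smooths the image (Gaussian, `sigma` px) and binarizes pixels at or below
#' the given intensity quantile of the smoothed image. Exposed separately
#' because the raw (pre-morphology) dark regions are nested across quantiles
#' — a property the proposal generator relies on.
#'
#' @param image an [octa_image] or intensity matrix.
#' @param quantile_dark quantile in (0, 1).
#' @param sigma smoothing sigma in pixels.
#' @return logical matrix of "dark" pixels.
#' @export
threshold_dark <- function(image, quantile_dark, sigma = 2) {
  sm <- smooth_image(img_pixels(image), sigma)
  sm <= stats::quantile(sm, quantile_dark, names = FALSE)
}

#' Multi-threshold fallback proposal generator
#'
#' A deterministic, weight-free stand-in for a promptable-segmentation
#' backend. The image is smoothed once; for each of `levels` intensity
#' quantiles (evenly spaced over `quantile_range`, default 0.05-0.40) the
#' dark region is binarized, the connected component containing the prompt is
#' extracted, and morphological closing followed by hole-filling is applied
#' (disc structuring element, radius `se_radius`). Components that lose the
#' prompt, exceed `max_area_frac` of the frame, or duplicate an earlier level
#' are discarded. The generator score of each surviving proposal is a
#' stability score: the mean IoU between its component and the components at
#' the adjacent threshold levels (boundary levels score against their single
#' neighbour; a missing neighbour contributes 0; a single requested level
#' scores 1 by convention).
#'
#' @param image an [octa_image] or intensity matrix.
#' @param prompt a `prompt_point` inside the image.
#' @param levels number of threshold levels (default 8).
#' @param sigma Gaussian smoothing sigma in pixels (default 2).
#' @param se_radius closing structuring-element radius in pixels (default 2).
#' @param max_area_frac discard components larger than this fraction of the
#'   frame (default 0.25).
#' @param quantile_range numeric length-2, quantile span (default
#'   `c(0.05, 0.40)`).
#' @return list of `mask_proposal` objects (possibly empty, with a warning,
#'   if no threshold yields a component containing the prompt). Each has
#'   fields `mask`, `generator_score` in `[0,1]`, `source = "fallback"`,
#'   `params_digest`.
#' @export
propose_fallback <- function(image, prompt, levels = 8, sigma = 2,
                             se_radius = 2, max_area_frac = 0.25,
                             quantile_range = c(0.05, 0.40)) {
  px <- img_pixels(image)
  h <- nrow(px); w <- ncol(px)
  if (levels < 1) stop("levels must be >= 1")
  if (prompt$row < 1 || prompt$row > h || prompt$col < 1 || prompt$col > w)
    stop("prompt point lies outside the image")
  sm <- smooth_image(px, sigma)
  qs <- if (levels == 1L) mean(quantile_range)
        else seq(quantile_range[1], quantile_range[2], length.out = levels)
  kern <- EBImage::makeBrush(2L * as.integer(se_radius) + 1L, shape = "disc")
  comps <- vector("list", levels)
  for (i in seq_len(levels)) {
    thr <- stats::quantile(sm, qs[i], names = FALSE)
    dark <- sm <= thr
    if (!dark[prompt$row, prompt$col]) next
    lab <- EBImage::bwlabel(dark)
    comp <- lab == lab[prompt$row, prompt$col]
    comp <- EBImage::imageData(EBImage::fillHull(
      EBImage::closing(comp, kern))) > 0
    # closing can in principle detach the prompt; such a level is unusable
    if (!comp[prompt$row, prompt$col]) next
    comps[[i]] <- comp
  }
  stability <- function(i) {
    if (levels == 1L) return(1)
    nb <- Filter(function(j) j >= 1L && j <= levels, c(i - 1L, i + 1L))
    vals <- vapply(nb, function(j) {
      if (is.null(comps[[j]])) 0 else iou(comps[[i]], comps[[j]])
    }, numeric(1))
    mean(vals)
  }
  digest <- config_digest(list(levels = levels, sigma = sigma,
                               se_radius = se_radius,
                               max_area_frac = max_area_frac,
                               quantile_range = quantile_range))
  out <- list()
  seen <- list()
  for (i in seq_len(levels)) {
    comp <- comps[[i]]
    if (is.null(comp)) next
    if (mean(comp) > max_area_frac) next
    if (any(vapply(seen, function(s) identical(s, comp), logical(1)))) next
    seen[[length(seen) + 1L]] <- comp
    out[[length(out) + 1L]] <- mask_proposal(comp, stability(i), "fallback",
                                             digest)
  }
  if (length(out) == 0L)
    warning("no threshold level yielded a component containing the prompt")
  out
}

#' Construct a mask proposal record
#'
#' @param mask nonempty logical mask.
#' @param generator_score score in `[0, 1]` from the generating backend.
#' @param source `"fallback"` or `"external_backend"`.
#' @param params_digest opaque configuration digest string.
#' @return object of class `mask_proposal`.
#' @export
mask_proposal <- function(mask, generator_score, source = "fallback",
                          params_digest = "") {
  mask <- as_seg_mask(mask)
  if (!any(mask)) stop("proposal mask must be nonempty")
  if (generator_score < 0 || generator_score > 1)
    stop("generator_score must lie in [0, 1]")
  structure(list(mask = mask, generator_score = generator_score,
                 source = source, params_digest = params_digest),
            class = "mask_proposal")
}

#' @export
print.mask_proposal <- function(x, ...) {
  cat(sprintf("<mask_proposal> %s, area %d px (%.2f%%), score %.3f\n",
              x$source, sum(x$mask), 100 * mean(x$mask), x$generator_score))
  invisible(x)
}

#' Register an external promptable-segmentation backend
#'
#' The contract: `fn(image, prompts)` receives an [octa_image] and a list of
#' `prompt_point`s and must return a list of one or more [mask_proposal]s,
#' deterministically for fixed inputs and configuration. Returned masks must
#' match the image dimensions, be nonempty, and contain at least one of the
#' prompts; [run_backend()] enforces these invariants. This is how a wrapper
#' around a pretrained promptable model (weights are never bundled here) is
#' attached without changes to the core.
#'
#' @param fn backend function `(image, prompts) -> list of mask_proposal`.
#' @param name backend name for provenance.
#' @return object of class `proposal_backend`.
#' @export
proposal_backend <- function(fn, name = "external") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, name = name), class = "proposal_backend")
}

#' Run a registered proposal backend with contract validation
#'
#' @param backend a [proposal_backend]; absence (`NULL`) is a configuration
#'   error, never a silent fallback.
#' @param image an [octa_image].
#' @param prompts list of `prompt_point`s (a single point is accepted).
#' @return list of validated [mask_proposal]s tagged
#'   `source = "external_backend"`.
#' @export
run_backend <- function(backend, image, prompts) {
  if (is.null(backend))
    stop("no proposal backend registered (configuration error)")
  stopifnot(inherits(backend, "proposal_backend"))
  if (inherits(prompts, "prompt_point")) prompts <- list(prompts)
  px <- img_pixels(image)
  props <- backend$fn(image, prompts)
  if (!is.list(props) || length(props) < 1L)
    stop(sprintf("backend '%s' returned no proposals", backend$name))
  for (i in seq_along(props)) {
    p <- props[[i]]
    if (!inherits(p, "mask_proposal"))
      stop(sprintf("backend '%s' proposal %d is not a mask_proposal",
                   backend$name, i))
    if (!identical(dim(p$mask), dim(px)))
      stop(sprintf("backend '%s' proposal %d has wrong dimensions (%s vs %s)",
                   backend$name, i, paste(dim(p$mask), collapse = "x"),
                   paste(dim(px), collapse = "x")))
    if (!any(p$mask)) stop(sprintf("backend '%s' proposal %d is empty",
                                   backend$name, i))
    contains <- any(vapply(prompts, function(pt) p$mask[pt$row, pt$col],
                           logical(1)))
    if (!contains)
      stop(sprintf("backend '%s' proposal %d does not contain any prompt point",
                   backend$name, i))
    props[[i]]$source <- "external_backend"
  }
  props
}
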