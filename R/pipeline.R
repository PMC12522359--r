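#' Segment the FAZ in one OCT-A image
#'
#' Runs the full zero-shot pipeline on a single image: prompt placement,
#' proposal generation, semantic + geometric re-ranking, selection. Two
#' prompt modes are supported and must be chosen explicitly:
#' `"mask"` places the prompt at the distance-transform argmax of a supplied
#' reference mask (the evaluation-protocol mode — note it feeds reference
#' information into inference); `"prior"` is reference-free and uses the
#' central dark-region prior.
#'
#' If no proposal contains the prompt the result is an empty mask flagged
#' `failed = TRUE`; downstream evaluation records such an image as IoU 0
#' rather than excluding it.
#'
#' @param image an [octa_image].
#' @param prompt_mode `"mask"` or `"prior"` (no default is applied silently).
#' @param reference_mask logical mask, required for `prompt_mode = "mask"`.
#' @param config a [faz_config()].
#' @param backend `NULL` to use the built-in fallback generator, or a
#'   [proposal_backend()] (required when `config$proposals$backend` names an
#'   external backend).
#' @param embedder embedding backend for ranking
#'   (default [mock_embedding_backend()]).
#' @return object of class `faz_segmentation`: list with `mask` (logical),
#'   `prompt`, `prompt_mode`, `proposals`, `ranking` (score table),
#'   `selected_index`, `failed`, `config_digest`.
#' @export
faz_segment <- function(image, prompt_mode = c("mask", "prior"),
                        reference_mask = NULL, config = faz_config(),
                        backend = NULL,
                        embedder = mock_embedding_backend()) {
  prompt_mode <- match.arg(prompt_mode)
  stopifnot(inherits(image, "octa_image"))
  px <- image$pixels
  prompt <- if (prompt_mode == "mask") {
    if (is.null(reference_mask))
      stop("prompt_mode = 'mask' requires a reference_mask")
    check_same_dim(px, as_seg_mask(reference_mask), "image and reference mask")
    place_prompt_point(reference_mask)
  } else {
    place_prompt_from_prior(px,
                            quantile_dark = config$prompting$prior_quantile,
                            window = config$prompting$prior_window,
                            sigma = config$prompting$sigma)
  }
  proposals <- if (identical(config$proposals$backend, "fallback")) {
    withCallingHandlers(
      propose_fallback(image, prompt,
                       levels = config$proposals$levels,
                       sigma = config$proposals$sigma,
                       se_radius = config$proposals$se_radius,
                       max_area_frac = config$proposals$max_area_frac,
                       quantile_range = c(config$proposals$quantile_low,
                                          config$proposals$quantile_high)),
      warning = function(w) invokeRestart("muffleWarning"))
  } else {
    run_backend(backend, image, list(prompt))
  }
  digest <- config_digest(config)
  if (length(proposals) == 0L) {
    return(structure(list(mask = matrix(FALSE, nrow(px), ncol(px)),
                          prompt = prompt, prompt_mode = prompt_mode,
                          proposals = proposals, ranking = NULL,
                          selected_index = NA_integer_, failed = TRUE,
                          config_digest = digest),
                     class = "faz_segmentation"))
  }
  sel <- select_proposal(image, proposals, prompt,
                         prompts = config_prompts(config),
                         embedder = embedder,
                         weights = unlist(config$ranking$weights),
                         crop_margin = config$ranking$crop_margin,
                         target_area_frac = config$ranking$target_area_frac,
                         zero_area_frac = config$ranking$zero_area_frac)
  structure(list(mask = sel$selected$mask, prompt = prompt,
                 prompt_mode = prompt_mode, proposals = proposals,
                 ranking = sel$table, selected_index = sel$index,
                 failed = FALSE, config_digest = digest),
            class = "faz_segmentation")
}

#' @export
print.faz_segmentation <- function(x, ...) {
  if (x$failed) {
    cat("<faz_segmentation> FAILED: no proposal contained the prompt\n")
  } else {
    cat(sprintf(
      "<faz_segmentation> %s-prompt at (%d, %d); %d proposal(s), selected #%d, area %d px (%.2f%%)\n",
      x$prompt_mode, x$prompt$row, x$prompt$col, length(x$proposals),
      x$selected_index, sum(x$mask), 100 * mean(x$mask)))
  }
  invisible(x)
}

#' @export
summary.faz_segmentation <- function(object, ...) {
  print(object)
  if (!is.null(object$ranking)) {
    cat("Ranking table:\n")
    print(object$ranking, digits = 4)
  }
  invisible(object)
}

#' Plot a segmentation result over its image
#'
#' Displays the image in grayscale with the predicted mask boundary, the
#' prompt point, and optionally the reference mask boundary.
#'
#' @param x a `faz_segmentation`.
#' @param image the [octa_image] that was segmented.
#' @param reference optional reference mask to overlay.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.faz_segmentation <- function(x, image, reference = NULL, ...) {
  px <- img_pixels(image)
  h <- nrow(px); w <- ncol(px)
  # orient so that row 1 is at the top
  graphics::image(x = seq_len(w), y = seq_len(h), z = t(px[h:1, ]) / 255,
                  col = gray.colors(256, 0, 1), asp = 1, axes = FALSE,
                  xlab = "", ylab = "", useRaster = TRUE, ...)
  draw_outline <- function(mask, col) {
    if (!any(mask)) return(invisible())
    graphics::contour(x = seq_len(w), y = seq_len(h),
                      z = t(mask[h:1, ]) * 1, levels = 0.5,
                      drawlabels = FALSE, add = TRUE, col = col, lwd = 2)
  }
  draw_outline(x$mask, "red")
  if (!is.null(reference)) draw_outline(as_seg_mask(reference), "green3")
  graphics::points(x$prompt$col, h - x$prompt$row + 1L, pch = 3,
                   col = "yellow", cex = 1.4, lwd = 2)
  invisible(x)
}

#' Segment every sample of a synthetic cohort
#'
#' @param samples list of `faz_sample` objects (see [generate_cohort()]).
#' @param prompt_mode `"mask"` (prompts from each sample's ground truth) or
#'   `"prior"`.
#' @param config,backend,embedder see [faz_segment()].
#' @return list of `faz_segmentation` results, one per sample.
#' @export
segment_cohort <- function(samples, prompt_mode = c("mask", "prior"),
                           config = faz_config(), backend = NULL,
                           embedder = mock_embedding_backend()) {
  prompt_mode <- match.arg(prompt_mode)
  lapply(samples, function(s) {
    faz_segment(s$image, prompt_mode = prompt_mode,
                reference_mask = if (prompt_mode == "mask") s$gt_mask,
                config = config, backend = backend, embedder = embedder)
  })
}

#' Evaluate segmentations of a cohort against its ground truth
#'
#' @param results list of `faz_segmentation` objects.
#' @param samples the matching list of `faz_sample` objects.
#' @param config a [faz_config()] (controls the CI method of the panel).
#' @return list with `records` (per-sample data.frame) and `stats`
#'   (`faz_cohort_stats` over `iou_faz`).
#' @export
evaluate_cohort <- function(results, samples, config = faz_config()) {
  stopifnot(length(results) == length(samples))
  records <- do.call(rbind, lapply(seq_along(results), function(i) {
    eval_record(sprintf("sample_%03d", i), results[[i]]$mask,
                samples[[i]]$gt_mask)
  }))
  stats <- cohort_stats(records$iou_faz,
                        ci_method = config$evaluation$ci_method,
                        bootstrap_n = config$evaluation$bootstrap_n,
                        seed = config$seed)
  list(records = records, stats = stats)
}
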