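#' Pixel confusion counts between predicted and reference masks
#'
#' @param pred,gt logical masks of equal dimensions.
#' @return named numeric `c(tp, fp, fn)`: pixels in both, prediction only,
#'   reference only.
#' @export
confusion_counts <- function(pred, gt) {
  pred <- as_seg_mask(pred); gt <- as_seg_mask(gt)
  check_same_dim(pred, gt)
  c(tp = sum(pred & gt), fp = sum(pred & !gt), fn = sum(!pred & gt))
}

#' Intersection over union (Jaccard index) of two masks
#'
#' `tp / (tp + fp + fn)`. An empty prediction against a nonempty reference
#' scores 0 (the convention under which failed segmentations are retained in
#' cohort summaries). Two empty masks are a domain error (0/0).
#'
#' @param pred,gt logical masks of equal dimensions.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  denom <- sum(cc)
  if (denom == 0) stop("IoU of two empty masks is undefined")
  unname(cc["tp"] / denom)
}

#' Two-class (foreground/background) mean IoU of a mask pair
#'
#' Mean of the FAZ-class IoU `tp/(tp+fp+fn)` and the background-class IoU
#' `tn/(tn+fp+fn)` — the class-averaged reading of the mIoU formula with
#' N = 2 classes.
#'
#' @param pred,gt logical masks of equal dimensions.
#' @return mIoU in `[0, 1]`.
#' @export
miou_two_class <- function(pred, gt) {
  pred <- as_seg_mask(pred); gt <- as_seg_mask(gt)
  cc <- confusion_counts(pred, gt)
  tn <- sum(!pred & !gt)
  if (sum(cc) == 0) stop("mIoU with two empty masks is undefined")
  iou_fg <- unname(cc["tp"] / sum(cc))
  iou_bg <- unname(tn / (tn + cc[["fp"]] + cc[["fn"]]))
  (iou_fg + iou_bg) / 2
}

#' Per-image evaluation record
#'
#' @param sample_id identifier string.
#' @param pred,gt logical masks of equal dimensions; `gt` nonempty.
#' @return one-row data.frame with columns `sample_id, tp, fp, fn, iou_faz,
#'   iou_background, miou_two_class`.
#' @export
eval_record <- function(sample_id, pred, gt) {
  pred <- as_seg_mask(pred); gt <- as_seg_mask(gt)
  if (!any(gt)) stop("reference mask is empty for sample ", sample_id)
  cc <- confusion_counts(pred, gt)
  tn <- sum(!pred & !gt)
  iou_faz <- unname(cc["tp"] / sum(cc))
  iou_bg <- unname(tn / (tn + cc[["fp"]] + cc[["fn"]]))
  data.frame(sample_id = as.character(sample_id),
             tp = cc[["tp"]], fp = cc[["fp"]], fn = cc[["fn"]],
             iou_faz = iou_faz, iou_background = iou_bg,
             miou_two_class = (iou_faz + iou_bg) / 2)
}

#' Cohort mean IoU (the headline aggregation)
#'
#' Arithmetic mean of the per-image foreground IoU across records — the
#' across-samples reading of mIoU under which a cohort's headline score is
#' reported. The class-averaged per-image reading is available as
#' `miou_two_class` in the records.
#'
#' @param records data.frame with an `iou_faz` column (from [eval_record()]).
#' @return mean IoU.
#' @export
cohort_mean_iou <- function(records) {
  if (NROW(records) == 0L) stop("no evaluation records")
  mean(records$iou_faz)
}

#' Cohort distribution statistics for per-image IoU values
#'
#' The full distribution panel for a cohort: mean, median, quartiles, the
#' 10th/5th/1st percentiles, extremes, sample standard deviation (n-1
#' denominator) and a 95% confidence interval for the mean. Order statistics
#' use linear interpolation between closest ranks (R quantile type 7). The
#' CI defaults to the normal approximation `mean +/- 1.96 sd / sqrt(n)`,
#' unclipped; a seeded percentile bootstrap is available instead. With a
#' single value, sd and CI are `NA`.
#'
#' @param ious numeric vector of per-image IoU values (n >= 1).
#' @param ci_method `"normal"` (default) or `"bootstrap"`.
#' @param bootstrap_n bootstrap resamples (default 2000).
#' @param seed seed for the bootstrap (default 1).
#' @return object of class `faz_cohort_stats`: a list with fields `n`,
#'   `mean_iou`, `median`, `q1`, `q3`, `p10`, `p5`, `p1`, `min`, `max`,
#'   `sd`, `ci95_low`, `ci95_high`, `ci_method`.
#' @export
cohort_stats <- function(ious, ci_method = c("normal", "bootstrap"),
                         bootstrap_n = 2000, seed = 1) {
  ci_method <- match.arg(ci_method)
  if (length(ious) == 0L) stop("cohort_stats of an empty vector is undefined")
  if (anyNA(ious)) stop("ious contain NA")
  n <- length(ious)
  q <- stats::quantile(ious, c(0.01, 0.05, 0.10, 0.25, 0.50, 0.75),
                       type = 7, names = FALSE)
  m <- mean(ious)
  s <- if (n >= 2L) stats::sd(ious) else NA_real_
  ci <- if (n < 2L) c(NA_real_, NA_real_)
  else if (ci_method == "normal") m + c(-1, 1) * 1.96 * s / sqrt(n)
  else local_seed(seed, {
    boots <- vapply(seq_len(bootstrap_n),
                    function(i) mean(sample(ious, n, replace = TRUE)),
                    numeric(1))
    stats::quantile(boots, c(0.025, 0.975), type = 7, names = FALSE)
  })
  structure(list(n = n, mean_iou = m, median = q[5], q1 = q[4], q3 = q[6],
                 p10 = q[3], p5 = q[2], p1 = q[1],
                 min = min(ious), max = max(ious), sd = s,
                 ci95_low = ci[1], ci95_high = ci[2], ci_method = ci_method),
            class = "faz_cohort_stats")
}

#' @export
print.faz_cohort_stats <- function(x, ...) {
  cat(sprintf("Cohort IoU panel (n = %d)\n", x$n))
  cat(sprintf("  mean %.4f  (95%% CI %.4f-%.4f, %s)\n", x$mean_iou,
              x$ci95_low, x$ci95_high, x$ci_method))
  cat(sprintf("  median %.4f  IQR %.4f-%.4f\n", x$median, x$q1, x$q3))
  cat(sprintf("  p10 %.4f  p5 %.4f  p1 %.4f\n", x$p10, x$p5, x$p1))
  cat(sprintf("  min %.4f  max %.4f  sd %s\n", x$min, x$max,
              ifelse(is.na(x$sd), "NA", sprintf("%.4f", x$sd))))
  invisible(x)
}

#' Quality-gate filter for a cohort
#'
#' Retains samples whose scan quality index is at least `min_quality`
#' (default 7, the conventional inclusion threshold for OCT-A signal
#' quality). Samples without a quality index are retained with a warning.
#' The number excluded is reported via `message()`.
#'
#' @param samples list of `faz_sample` or [octa_image] objects, or a
#'   data.frame with a `quality_index` column.
#' @param min_quality inclusion threshold (default 7).
#' @return filtered object of the same shape as `samples`.
#' @export
quality_gate <- function(samples, min_quality = 7) {
  get_q <- function(s) {
    if (inherits(s, "faz_sample")) s$image$quality_index
    else if (inherits(s, "octa_image")) s$quality_index
    else NA_integer_
  }
  if (is.data.frame(samples)) {
    q <- samples$quality_index
    if (is.null(q)) q <- rep(NA_integer_, nrow(samples))
  } else q <- vapply(samples, get_q, integer(1))
  if (anyNA(q))
    warning(sum(is.na(q)), " sample(s) lack a quality index; retained")
  keep <- is.na(q) | q >= min_quality
  message(sum(!keep), " sample(s) excluded by quality gate (min ",
          min_quality, ")")
  if (is.data.frame(samples)) samples[keep, , drop = FALSE]
  else samples[keep]
}

#' Write an evaluation report (JSON cohort panel + per-sample CSV)
#'
#' Emits `cohort_stats.json` — the full [cohort_stats()] panel plus the
#' effective configuration digest if supplied — and `per_sample.csv` with
#' columns `sample_id, tp, fp, fn, iou_faz, miou_two_class`. Numbers are
#' serialized at 4 decimal places. Report schema version 1.
#'
#' @param stats a `faz_cohort_stats`.
#' @param records per-sample data.frame from [eval_record()] rows.
#' @param destination output directory (created if needed).
#' @param config_digest optional configuration digest echoed in the JSON.
#' @return destination, invisibly.
#' @export
report_evaluation <- function(stats, records, destination,
                              config_digest = NULL) {
  stopifnot(inherits(stats, "faz_cohort_stats"))
  ok <- dir.exists(destination) || dir.create(destination, recursive = TRUE)
  if (!ok) stop("cannot write to destination: ", destination)
  panel <- lapply(unclass(stats), function(v)
    if (is.numeric(v)) round(v, 4) else v)
  panel$schema_version <- 1L
  if (!is.null(config_digest)) panel$config_digest <- config_digest
  writeLines(jsonlite::toJSON(panel, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null", pretty = TRUE),
             file.path(destination, "cohort_stats.json"))
  out <- records[, c("sample_id", "tp", "fp", "fn", "iou_faz",
                     "miou_two_class")]
  out$iou_faz <- round(out$iou_faz, 4)
  out$miou_two_class <- round(out$miou_two_class, 4)
  utils::write.csv(out, file.path(destination, "per_sample.csv"),
                   row.names = FALSE)
  invisible(destination)
}
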