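#' Pipeline configuration
#'
#' Bundles every tunable default of the pipeline in one validated, nested
#' list. Unknown keys are rejected so a typo in a YAML file cannot silently
#' fall back to a default. The effective configuration's digest is echoed
#' into segmentation audits and evaluation reports.
#'
#' Sections and defaults:
#' * `prompting`: `prior_quantile` 0.15, `prior_window` 0.5, `sigma` 2 —
#'   the reference-free dark-region prior.
#' * `proposals`: `backend` "fallback", `levels` 8, `sigma` 2, `se_radius` 2,
#'   `max_area_frac` 0.25, `quantile_low` 0.05, `quantile_high` 0.40.
#' * `ranking`: `positive_prompts`, `negative_prompts` (character vectors),
#'   `weights` (`sem` 0.5, `geo` 0.3, `gen` 0.2), `crop_margin` 0.25,
#'   `target_area_frac` 0.015, `zero_area_frac` 0.20.
#' * `evaluation`: `min_quality` 7, `ci_method` "normal",
#'   `bootstrap_n` 2000.
#' * `seed`: 1.
#'
#' @param ... named overrides as nested lists, e.g.
#'   `faz_config(proposals = list(levels = 6))`.
#' @return object of class `faz_config`.
#' @export
faz_config <- function(...) {
  defaults <- list(
    prompting = list(prior_quantile = 0.15, prior_window = 0.5, sigma = 2),
    proposals = list(backend = "fallback", levels = 8, sigma = 2,
                     se_radius = 2, max_area_frac = 0.25,
                     quantile_low = 0.05, quantile_high = 0.40),
    ranking = list(
      positive_prompts =
        "foveal avascular zone located at the center of the macula",
      negative_prompts = c("retinal blood vessels", "image artifact"),
      weights = list(sem = 0.5, geo = 0.3, gen = 0.2),
      crop_margin = 0.25, target_area_frac = 0.015, zero_area_frac = 0.20),
    evaluation = list(min_quality = 7, ci_method = "normal",
                      bootstrap_n = 2000),
    seed = 1)
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  validate_config(cfg)
  structure(cfg, class = "faz_config")
}

# recursive merge that rejects keys absent from the defaults skeleton
merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0L) return(defaults)
  nm <- names(overrides)
  if (is.null(nm) || any(!nzchar(nm))) stop("config overrides must be named")
  unknown <- setdiff(nm, names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in nm) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      ov <- overrides[[k]]
      if (!is.list(ov)) stop("config section '", k, "' must be a mapping")
      defaults[[k]] <- merge_config(defaults[[k]], ov,
                                    paste0(path, ".", k))
    } else defaults[[k]] <- overrides[[k]]
  }
  defaults
}

validate_config <- function(cfg) {
  w <- unlist(cfg$ranking$weights)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("ranking weights must be nonnegative and sum to 1")
  if (cfg$proposals$levels < 1) stop("proposals.levels must be >= 1")
  if (cfg$proposals$quantile_low >= cfg$proposals$quantile_high)
    stop("proposals.quantile_low must be below quantile_high")
  if (cfg$prompting$prior_quantile <= 0 || cfg$prompting$prior_quantile >= 1)
    stop("prompting.prior_quantile must lie in (0, 1)")
  if (length(cfg$ranking$positive_prompts) < 1)
    stop("at least one positive ranking prompt is required")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML mapping and merges it over the defaults of [faz_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `faz_config`.
#' @export
read_faz_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  do.call(faz_config, y)
}

#' Digest of a configuration (or any plain list)
#'
#' MD5 of the canonical JSON serialization; used to stamp reports and audits
#' with the effective configuration.
#'
#' @param cfg a `faz_config` or plain list.
#' @return hex digest string.
#' @export
config_digest <- function(cfg) {
  json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                           null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.faz_config <- function(x, ...) {
  cat("<faz_config>", config_digest(x), "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

# semantic_prompt list from the config's character vectors
config_prompts <- function(cfg) {
  c(lapply(cfg$ranking$positive_prompts, semantic_prompt,
           polarity = "positive"),
    lapply(cfg$ranking$negative_prompts, semantic_prompt,
           polarity = "negative"))
}
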