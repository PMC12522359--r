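#' Semantic text prompt
#'
#' An anatomically grounded descriptive phrase used to score mask proposals,
#' with a polarity: positive prompts describe the target structure, negative
#' prompts describe confusers.
#'
#' @param text nonempty phrase.
#' @param polarity `"positive"` or `"negative"`.
#' @return object of class `semantic_prompt`.
#' @export
semantic_prompt <- function(text, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (!nzchar(text)) stop("prompt text must be nonempty")
  structure(list(text = text, polarity = polarity), class = "semantic_prompt")
}

#' Default semantic prompt set for FAZ selection
#'
#' One positive phrase describing the target ("foveal avascular zone located
#' at the center of the macula") and two negative confuser phrases.
#' @return list of [semantic_prompt]s.
#' @export
default_prompts <- function() {
  list(semantic_prompt("foveal avascular zone located at the center of the macula",
                       "positive"),
       semantic_prompt("retinal blood vessels", "negative"),
       semantic_prompt("image artifact", "negative"))
}

#' Crop an image around a mask for embedding
#'
#' Takes the axis-aligned bounding box of the mask, expands it by `margin`
#' times the box height/width on each side (both expanded endpoints
#' floor-rounded), and clips to the frame. The crop carries its offset for
#' audit.
#'
#' @param image an [octa_image] or intensity matrix.
#' @param mask nonempty logical mask, same dimensions.
#' @param margin nonnegative expansion fraction (default 0.25).
#' @return list with `pixels` (matrix) and `offset` (`c(row, col)` of the
#'   crop's top-left pixel in the frame); class `faz_crop`.
#' @export
crop_for_embedding <- function(image, mask, margin = 0.25) {
  px <- img_pixels(image)
  mask <- as_seg_mask(mask)
  check_same_dim(px, mask, "image and mask")
  if (!any(mask)) stop("cannot crop around an empty mask")
  if (margin < 0) stop("margin must be >= 0")
  idx <- which(mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  mh <- margin * (r1 - r0 + 1L); mw <- margin * (c1 - c0 + 1L)
  rr0 <- max(1L, as.integer(floor(r0 - mh)))
  rr1 <- min(nrow(px), as.integer(floor(r1 + mh)))
  cc0 <- max(1L, as.integer(floor(c0 - mw)))
  cc1 <- min(ncol(px), as.integer(floor(c1 + mw)))
  structure(list(pixels = px[rr0:rr1, cc0:cc1, drop = FALSE],
                 offset = c(rr0, cc0)),
            class = "faz_crop")
}

#' Semantic score of a crop embedding against text prompt embeddings
#'
#' Mean cosine similarity to the positive prompts minus mean cosine
#' similarity to the negative prompts (0 if there are none); with unit-norm
#' vectors the score lies in `[-2, 2]`.
#'
#' @param crop_vec unit-norm embedding of the image crop.
#' @param prompts list of [semantic_prompt]s; at least one positive.
#' @param text_vecs list of unit-norm embeddings aligned with `prompts`.
#' @return numeric score.
#' @export
semantic_score <- function(crop_vec, prompts, text_vecs) {
  pol <- vapply(prompts, `[[`, character(1), "polarity")
  if (!any(pol == "positive"))
    stop("at least one positive prompt is required (configuration error)")
  if (length(prompts) != length(text_vecs))
    stop("prompts and text_vecs must align")
  cosim <- vapply(text_vecs, function(v) sum(crop_vec * v), numeric(1))
  pos <- mean(cosim[pol == "positive"])
  neg <- if (any(pol == "negative")) mean(cosim[pol == "negative"]) else 0
  pos - neg
}

#' Geometric prior score of a proposal mask
#'
#' Product of three factors: prompt containment (1 if the prompt pixel is
#' foreground, else 0); centrality `exp(-||centroid - frame centre|| / D)`
#' with `D` = frame diagonal / 4; and area plausibility, a triangular score
#' peaking at `target_area_frac` of the frame (default 1.5%) and reaching 0
#' at 0% and at `zero_area_frac` (default 20%).
#'
#' @param mask nonempty logical mask.
#' @param prompt a `prompt_point`.
#' @param image_dims `c(height, width)`; default `dim(mask)`.
#' @param target_area_frac area fraction at the score peak.
#' @param zero_area_frac area fraction at which the score reaches 0.
#' @return score in `[0, 1]`.
#' @export
geometric_score <- function(mask, prompt, image_dims = dim(mask),
                            target_area_frac = 0.015, zero_area_frac = 0.20) {
  mask <- as_seg_mask(mask)
  if (!any(mask)) stop("geometric score of an empty mask is undefined")
  if (!mask[prompt$row, prompt$col]) return(0)
  h <- image_dims[1]; w <- image_dims[2]
  idx <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(idx)
  centre <- c((h + 1) / 2, (w + 1) / 2)
  D <- sqrt(h^2 + w^2) / 4
  centrality <- exp(-sqrt(sum((centroid - centre)^2)) / D)
  a <- sum(mask) / (h * w)
  area_factor <-
    if (a <= 0 || a >= zero_area_frac) 0
    else if (a <= target_area_frac) a / target_area_frac
    else (zero_area_frac - a) / (zero_area_frac - target_area_frac)
  centrality * area_factor
}

#' Combine component scores and select the best proposal
#'
#' Semantic scores are min-max normalized across the proposal set (a single
#' proposal, or an all-equal set, normalizes to 1), then combined as
#' `total = w_sem * sem + w_geo * geo + w_gen * generator_score` with
#' nonnegative weights summing to 1. The proposal with the maximum total is
#' selected; ties are broken by larger generator score, then by smaller
#' proposal index. An empty proposal list is a selection error signalling
#' segmentation failure (condition class `faz_no_proposal`).
#'
#' @param proposals list of [mask_proposal]s.
#' @param semantic_scores numeric vector of raw semantic scores.
#' @param geometric_scores numeric vector of geometric scores in `[0, 1]`.
#' @param weights named numeric `c(sem=, geo=, gen=)`, nonnegative, sum 1.
#' @return list with `selected` (index of the winning proposal) and `table`
#'   (data.frame of component and total scores per proposal).
#' @export
rank_and_select <- function(proposals, semantic_scores, geometric_scores,
                            weights = c(sem = 0.5, geo = 0.3, gen = 0.2)) {
  if (length(proposals) == 0L)
    stop(structure(class = c("faz_no_proposal", "error", "condition"),
                   list(message = "no proposals to rank: segmentation failure",
                        call = sys.call())))
  stopifnot(length(semantic_scores) == length(proposals),
            length(geometric_scores) == length(proposals))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be nonnegative and sum to 1")
  rng <- range(semantic_scores)
  sem_norm <- if (diff(rng) < 1e-12) rep(1, length(semantic_scores))
              else (semantic_scores - rng[1]) / diff(rng)
  gen <- vapply(proposals, `[[`, numeric(1), "generator_score")
  total <- weights[["sem"]] * sem_norm + weights[["geo"]] * geometric_scores +
    weights[["gen"]] * gen
  ord <- order(-total, -gen, seq_along(total))
  list(selected = ord[1],
       table = data.frame(proposal = seq_along(total),
                          semantic_raw = semantic_scores,
                          semantic_norm = sem_norm,
                          geometric = geometric_scores,
                          generator = gen, total = total))
}

# ---- mock embedding backend ---------------------------------------------

# Documented text lookup table for the mock embedder (8-dim space).
# Feature axes for crops: 1 mean intensity, 2 intensity sd, 3 centre-vs-
# periphery contrast (positive when the centre is darker), 4 dark-area
# fraction; axes 5-8 are padding. Text vectors load the axes a phrase should
# co-vary with: the FAZ phrase rewards dark-centred, high-dark-fraction,
# low-mean crops; the vessel phrase rewards bright, low-contrast crops; the
# artifact phrase rewards high-variance crops.
mock_text_table <- function() {
  tab <- list(
    "foveal avascular zone located at the center of the macula" =
      c(-0.4, 0, 0.6, 0.7, 0, 0, 0, 0),
    "retinal blood vessels" = c(0.7, 0.3, -0.5, -0.4, 0, 0, 0, 0),
    "image artifact" = c(0.1, 0.9, -0.2, -0.2, 0, 0, 0, 0))
  lapply(tab, function(v) v / sqrt(sum(v^2)))
}

#' Deterministic mock embedding backend
#'
#' A test double for the embedding-backend contract: maps an image crop or a
#' text string to a unit-norm 8-dimensional vector in a shared space. Crops
#' embed as normalized intensity statistics (mean, sd, centre-vs-periphery
#' contrast, dark-area fraction, zero-padded); texts come from a fixed,
#' documented lookup table (see the source of `mock_text_table`). Unknown
#' text is a configuration error. Deterministic for fixed input.
#'
#' @return object of class `faz_embedder` with functions
#'   `embed_image(crop)` and `embed_text(text)`.
#' @export
mock_embedding_backend <- function() {
  table <- mock_text_table()
  embed_image <- function(crop) {
    px <- if (inherits(crop, "faz_crop")) crop$pixels else img_pixels(crop)
    v01 <- px / 255
    h <- nrow(v01); w <- ncol(v01)
    cr <- max(1L, floor(h / 4) + 1L):min(h, ceiling(3 * h / 4))
    cc <- max(1L, floor(w / 4) + 1L):min(w, ceiling(3 * w / 4))
    central <- mean(v01[cr, cc])
    peripheral <- if (length(cr) * length(cc) < h * w)
      (sum(v01) - sum(v01[cr, cc])) / (h * w - length(cr) * length(cc))
    else central
    feat <- c(mean(v01), stats::sd(as.vector(v01)),
              peripheral - central, mean(v01 < 0.5),
              0, 0, 0, 0)
    feat[is.na(feat)] <- 0
    n <- sqrt(sum(feat^2))
    if (n < 1e-12) c(1, rep(0, 7)) else feat / n
  }
  embed_text <- function(text) {
    v <- table[[text]]
    if (is.null(v))
      stop("no mock embedding table entry for text: '", text,
           "' (configuration error)")
    v
  }
  structure(list(embed_image = embed_image, embed_text = embed_text,
                 dim = 8L, name = "mock"),
            class = "faz_embedder")
}

#' Score and select the best proposal for an image
#'
#' Orchestrates the ranking stage: crops each proposal's region
#' ([crop_for_embedding()]), embeds crop and text prompts with `embedder`,
#' computes semantic and geometric scores, and applies [rank_and_select()].
#'
#' @param image an [octa_image].
#' @param proposals list of [mask_proposal]s.
#' @param prompt the `prompt_point` the proposals answer.
#' @param prompts list of [semantic_prompt]s (default [default_prompts()]).
#' @param embedder a `faz_embedder` (default [mock_embedding_backend()]).
#' @param weights score weights, see [rank_and_select()].
#' @param crop_margin margin for [crop_for_embedding()].
#' @param target_area_frac,zero_area_frac see [geometric_score()].
#' @return list with `selected` ([mask_proposal]), `index`, and the scoring
#'   `table`.
#' @export
select_proposal <- function(image, proposals, prompt,
                            prompts = default_prompts(),
                            embedder = mock_embedding_backend(),
                            weights = c(sem = 0.5, geo = 0.3, gen = 0.2),
                            crop_margin = 0.25, target_area_frac = 0.015,
                            zero_area_frac = 0.20) {
  text_vecs <- lapply(prompts, function(p) embedder$embed_text(p$text))
  sem <- vapply(proposals, function(p) {
    crop <- crop_for_embedding(image, p$mask, crop_margin)
    semantic_score(embedder$embed_image(crop), prompts, text_vecs)
  }, numeric(1))
  geo <- vapply(proposals, function(p) {
    geometric_score(p$mask, prompt, dim(img_pixels(image)),
                    target_area_frac, zero_area_frac)
  }, numeric(1))
  sel <- rank_and_select(proposals, sem, geo, weights)
  list(selected = proposals[[sel$selected]], index = sel$selected,
       table = sel$table)
}
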