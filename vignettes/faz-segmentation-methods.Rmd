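---
title: "Methods: zero-shot FAZ segmentation and its synthetic evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zero-shot FAZ segmentation and its synthetic evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fazseg)
```

## The problem and the pipeline

The foveal avascular zone (FAZ) is the capillary-free region at the centre
of the macula. In en-face OCT-A it is a dark, irregular, roughly central
region amid bright flow signal, and its area and shape carry clinical
meaning in retinal ischemia. `fazseg` delineates it *zero-shot*: no
FAZ-labelled training data, only (a) a point prompt, (b) a pool of candidate
masks, and (c) a selection rule grounded in what the structure *is* — dark,
central, of plausible size, describable in words.

The pipeline is three pure stages, each swappable behind a small contract:

1. **Prompt placement.** Given a reference mask, the prompt is the argmax of
   the exact Euclidean distance transform (EDT) — the most interior pixel.
   The frame border is treated as background so border-touching masks keep
   finite depths and a well-defined argmax; ties break to the smallest row,
   then column, so placement is deterministic across platforms. A
   reference-free mode thresholds the smoothed image at a low quantile
   (default 0.15) inside the central window (default the central 50% per
   dimension), takes the largest dark component there, and prompts at its
   EDT argmax, falling back to the image centre when nothing qualifies.
2. **Proposal generation.** The default generator is deterministic and
   weight-free: smooth (Gaussian sigma 2 px), binarize at 8 intensity
   quantiles spanning 0.05–0.40, keep the connected component containing the
   prompt, close (disc radius 2 px) and fill holes, drop components above
   25% of the frame and duplicates. Each survivor's *stability score* is the
   mean IoU with the components at adjacent threshold levels (a mask stable
   across thresholds is evidence of a real intensity boundary). An external
   promptable model can replace this stage through `proposal_backend()`;
   returned masks are validated (dimensions, nonempty, prompt containment)
   and never silently substituted.
3. **Re-ranking and selection.** Each proposal's bounding-box crop (25%
   margin per side, expanded endpoints floor-rounded) is embedded in a joint
   image–text space and scored as mean cosine similarity to positive text
   prompts minus mean similarity to negatives. Semantic scores are min–max
   normalized within the image's proposal set — this makes the weights
   meaningful across embedding backends with different score scales — and
   combined as `0.5 * semantic + 0.3 * geometric + 0.2 * stability`. The
   geometric prior is a product of prompt containment (hard 0/1), centrality
   `exp(-d / D)` with `D` the quarter-diagonal, and a triangular area score
   peaking at 1.5% of the frame and vanishing at 0% and 20%. Ties break by
   higher stability, then lower index.

Whether semantic information should steer mask *generation* or only
*selection* is genuinely open; `fazseg` implements selection-only, which
keeps the proposal stage contract minimal and every score auditable per
image (the audit JSON records all component scores for all proposals).

The bundled embedder is an explicitly synthetic test double: crops map to
normalized intensity statistics (mean, SD, centre-vs-periphery contrast,
dark-area fraction), texts to a fixed documented table in the same
8-dimensional space. It reproduces the *ordering* a vision–language model
should induce on this task (dark, central crops score highest against the
FAZ phrase) without any weights; a real CLIP-style backend plugs in through
the same two-function contract (`embed_image`, `embed_text`, unit-norm
output).

## Evaluation semantics

The per-image agreement metric is `IoU = TP / (TP + FP + FN)`. Two
aggregations are deliberately kept apart because the common usage of "mIoU"
conflates them: the **cohort mean of per-image FAZ IoU** (the headline
number) and the **per-image two-class mean** over FAZ and background,
`(IoU_faz + IoU_bg) / 2`, which is dominated by the background class when
the FAZ is small. Reports label both unambiguously (`iou_faz`,
`miou_two_class`).

`cohort_stats()` reports mean, median, Q1/Q3, the 10th/5th/1st percentiles,
extremes, sample SD (n−1), and a 95% CI. Order statistics use linear
interpolation between closest ranks (R quantile type 7) — the 1st/5th/10th
percentiles of a 20-image cohort depend on this convention, so it is fixed
and oracle-tested. The CI defaults to the normal approximation
`mean ± 1.96 sd / √n` (closed-form, testable); a seeded percentile bootstrap
(2000 resamples) is available via `evaluation.ci_method`. Whether a sample
SD or a normal CI is the "right" convention for small IoU cohorts is
arguable; both choices are documented rather than inferred.

A failed segmentation (no proposal contains the prompt) yields an empty
mask recorded as IoU 0 — catastrophic outliers stay in the distribution
rather than being excluded. A quality gate (`quality_gate()`, default
threshold 7 on the 0–10 device scan-quality index) filters cohorts before
aggregation, mirroring standard OCT-A inclusion practice; samples lacking
an index are retained with a warning.

## The synthetic scene generator

Real FAZ cohorts are patient data and cannot ship with a package. The
generator emulates exactly the geometry the pipeline exploits, with known
ground truth:

* **Shape.** The FAZ outline is a radial-harmonic polygon
  `r(θ) = R (1 + Σ_k a_k sin(kθ + φ_k))`, K = 4 harmonics, coefficients
  drawn per-seed with `Σ|a_k|` bounded by the irregularity amplitude
  (default 0.25) so the radius stays positive and the region star-shaped
  (hence one connected component). The mask is the polygon rasterized by
  the package's own pixel-centre even–odd rule, so mask and LabelMe
  annotation are exactly consistent.
* **Scale.** Default R = 32 px on a 256 × 256 frame standing for a 3 × 3 mm
  scan: area ≈ 4.9% of the frame ≈ 0.44 mm², within the healthy-eye range.
  Cohorts jitter R uniformly over ≈ 28–36 px (0.34–0.56 mm²) and the centre
  by ±10 px. The lower end of this range also keeps the FAZ's pixel
  fraction near the lowest proposal quantile (0.05), which is what lets the
  fallback generator cut a tight boundary — a testability-driven choice,
  stated as such: the generator's defaults are calibrated for a resolvable
  task, not fitted to any clinical distribution.
* **Appearance.** Hard-edged dark interior (40) on a mid-gray background
  (120) with bright correlated-random-walk vessel strokes (~170–235,
  coverage growing with `vessel_density`), plus additive Gaussian noise
  (default SD 8), clipped to 8-bit. Contrast between interior and exterior
  is a tested invariant up to noise SD 10.
* **Artifacts.** `motion_stripe` replaces two row bands (24–40 px) with
  horizontally shifted, dimmed copies — when a band crosses the FAZ the
  image no longer matches its ground truth, which is precisely the failure
  mode of interest. `decentered` displaces the FAZ centre by 40–70 px per
  axis *before* mask generation, so image and ground truth stay consistent
  and the centre remains inside the mask; rendering applies no further
  change for this kind. Artifact samples get seeded quality indices
  (motion stripe 5–8, decentered 6–9; clean samples 10) so the quality gate
  has both retained and excluded scans to act on.
* **Seeding.** Sample *i* of a cohort uses `base_seed + i − 1`; geometry,
  rendering and artifact draws use separate offset streams. Two
  consequences, both tested: any sample is regenerable in isolation, and
  cohorts differing only in `artifact_fraction` share identical FAZ
  geometry sample-for-sample, making the clean-versus-artifact comparison
  paired.

What passing the synthetic protocol does **not** show: robustness to real
OCT-A speckle/decorrelation statistics, projection artifacts, multilayer
plexus separation, pathology (enlarged or fragmented FAZ), or cross-device
intensity profiles. The synthetic cohort certifies the *machinery* —
contracts, determinism, metric correctness, the direction of
artifact-induced degradation — not clinical accuracy.

## Numerical conventions

* **Coordinates.** Matrices are `[row, col]`, 1-based, origin top-left;
  LabelMe points are `(x, y)` with pixel `(r, c)` centred at
  `(c − 0.5, r − 0.5)`. This mapping is stated once and round-trip tested.
* **Rasterization.** Pixel-centre even–odd rule; centres exactly on an edge
  (tolerance 1e-9) count as inside; self-intersecting polygons are handled
  by the even–odd rule with a warning. Chosen over supersampling because it
  is deterministic and checkable against per-pixel enumeration; rasterized
  area converges to the shoelace area under canvas supersampling (tested).
* **EDT.** Computed on a one-pixel background-padded frame (the nearest
  out-of-frame source always lies in the first ring), exact against the
  all-sources oracle; argmax ties compared on integer squared distances.
* **Mask PNGs.** Foreground ⇔ stored value ≥ 128; written as 0/255. 16-bit
  or multi-channel mask input is a format error, never a silent rescale.
  Images may be 8-bit grayscale or RGB (Rec. 601 luminance).
* **Degenerate inputs.** Empty mask: domain error for EDT/crop/IoU-of-two-
  empties; uniform image: centre fallback for the prior, empty proposal
  list (warning, not exception) for the generator; n = 1 cohort: SD/CI
  marked absent.
* **Determinism.** Every stochastic step runs under a locally scoped seed
  and restores the caller's RNG state; fixed (inputs, config, seed) give
  bit-identical cohorts, predictions and reports. The effective config's
  MD5 digest is stamped into audits and reports.

## Problem sizes

The end-to-end checks use cohorts of 20 images at 256 × 256 — the package's
chosen study size for a synthetic protocol that a laptop reruns in seconds —
with oracle equivalence checked exhaustively on small grids (≤ 32 × 32
masks, hundreds of random cases) where brute-force enumeration is exact.

## Known limitations

* The fallback generator assumes the FAZ is the darkest coherent structure
  under the prompt; heavy shadowing or media opacity would defeat it — with
  a real promptable backend attached, only the contract, not the heuristic,
  is load-bearing.
* The mask-derived prompt mode feeds reference information into inference;
  it matches the evaluation protocol of prompt-based zero-shot studies but
  overstates fully automatic performance. The prior mode exists precisely
  so both can be reported separately; neither is a silent default in the
  command layer.
* The mock embedder is a stand-in with hand-written text vectors; its
  scores are meaningful only ordinally, within one proposal set.
* Percentile and CI conventions are fixed choices among defensible
  alternatives; comparisons against panels computed under other conventions
  (nearest-rank percentiles, t or bootstrap intervals) will differ in the
  last digits.
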