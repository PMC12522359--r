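# fazseg

Zero-shot segmentation of the **foveal avascular zone (FAZ)** in en-face
**OCT angiography (OCT-A)** images, with no FAZ-specific training data.

The FAZ is the capillary-free region at the centre of the macula; its area
and shape are biomarkers of retinal ischemia in conditions such as diabetic
retinopathy and AMD. On an en-face OCT-A slab it appears as a dark,
irregular, roughly central region surrounded by bright vascular texture.
Manual delineation is precise but slow and observer-dependent; fully
supervised networks need pixel-level labels. `fazseg` implements a
promptable, label-free alternative for researchers who want a reproducible,
auditable FAZ segmentation and evaluation protocol:

1. **Prompting** — a foreground seed is placed at the argmax of the exact
   Euclidean distance transform of a reference mask (`place_prompt_point()`),
   or, reference-free, from a central dark-region prior
   (`place_prompt_from_prior()`).
2. **Proposals** — candidate masks for the prompt come from a deterministic
   multi-threshold generator (`propose_fallback()`), or from any external
   promptable-segmentation backend (e.g. a SAM-style model) attached through
   the validated `proposal_backend()` contract. No model weights are bundled.
3. **Re-ranking** — each candidate is scored by semantic similarity of its
   image crop to anatomically grounded text prompts (positive: *"foveal
   avascular zone located at the center of the macula"*; negatives:
   *"retinal blood vessels"*, *"image artifact"*) through a pluggable
   image/text embedder, combined with geometric priors (prompt containment,
   centrality, plausible area) and the generator's stability score; the best
   total wins (`rank_and_select()`).

Agreement with reference annotations uses the Jaccard index per image,

```
IoU_i = TP_i / (TP_i + FP_i + FN_i)
```

aggregated two ways: the cohort mean of the per-image FAZ IoU (the headline
mIoU) and the per-image two-class mean over FAZ and background,
`(IoU_faz + IoU_bg) / 2`. `cohort_stats()` reports the full distribution
panel (mean, median, quartiles, 10th/5th/1st percentiles, extremes, SD,
95% CI).

A seeded synthetic OCT-A scene generator (`generate_cohort()`) produces
images with known ground truth — dark radial-harmonic FAZ, bright
curvilinear vessels, speckle-like noise, and motion-stripe / decentering
artifact modes with degraded quality indices — so the entire pipeline runs
and is tested completely offline. LabelMe polygon JSON and 8-bit PNG masks
are the interchange formats.

## Worked example

```r
library(fazseg)

s <- generate_sample(scene_params(seed = 7))
s
#> <faz_sample> seed 7, none artifact, FAZ area 3225 px (4.92%)

res <- faz_segment(s$image, prompt_mode = "mask", reference_mask = s$gt_mask)
res
#> <faz_segmentation> mask-prompt at (129, 128); 8 proposal(s), selected #1, area 3277 px (5.00%)
iou(res$mask, s$gt_mask)
#> [1] 0.9709003
```

The prompt landed at the most interior point of the reference mask (row 129,
col 128, 30.5 px deep); eight threshold levels produced eight candidates and
the re-ranker selected the tightest one, overlapping the ground truth at
IoU 0.97. On a clean 20-image cohort:

```r
co  <- generate_cohort(20, base_seed = 11)
ev  <- evaluate_cohort(segment_cohort(co, prompt_mode = "mask"), co)
ev$stats
#> Cohort IoU panel (n = 20)
#>   mean 0.8745  (95% CI 0.8530-0.8960, normal)
#>   median 0.8687  IQR 0.8407-0.8950
#>   p10 0.8206  p5 0.8148  p1 0.8112
#>   min 0.8103  max 0.9776  sd 0.0491
```

Per-sample records carry the confusion counts and both mIoU readings; the
`plot()` method overlays prediction, reference and prompt on the image.
`cmd_synth()` / `cmd_segment()` / `cmd_evaluate()` (or the thin wrapper
`inst/cli/faz.R`) run the same stages over directories, writing predictions,
per-image audit JSON, and a JSON + CSV evaluation report; a YAML config
(`read_faz_config()`) controls every tunable and its digest is stamped into
all outputs.

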