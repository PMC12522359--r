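Package: fazseg
Title: Zero-Shot Segmentation of the Foveal Avascular Zone in OCT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A backend-agnostic pipeline for zero-shot segmentation of the
    foveal avascular zone (FAZ) in 2-D en-face optical coherence tomography
    angiography (OCT-A) images. Prompt points are placed at the Euclidean
    distance-transform maximum of a reference mask (or from a reference-free
    dark-region prior), candidate masks are produced by a deterministic
    multi-threshold proposal generator or an external promptable-segmentation
    backend, and proposals are re-ranked by semantic similarity to
    anatomically grounded text prompts combined with geometric priors.
    Includes LabelMe polygon annotation I/O, a seeded synthetic OCT-A scene
    generator with known ground truth and artifact failure modes, and an
    evaluation module computing per-image IoU, two-class mIoU and full cohort
    distribution statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
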