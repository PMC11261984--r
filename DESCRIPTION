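Package: cryoprompt
Title: Training-Free Prompt-Based Particle Segmentation for Cryo-Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prompt-based, training-free 3D particle segmentation and picking
    for cryo-electron tomography density volumes. A single point prompt seeds
    2D segmentation on the three orthogonal planes through it; cross-plane
    self-prompting propagates each plane's mask and confidence peak to
    adjacent slices until the adjacent-slice IoU drops, and the union of all
    accepted planes forms the 3D instance mask. A masked-average-pooled query
    feature built from tri-view slice encodings is then matched against a
    coarse-to-fine feature pyramid; thresholded keep-masks restrict each finer
    level's evaluation, and non-maximum suppression proposes up to K new point
    prompts, turning one prompt into a full-tomogram semantic segmentation.
    Segmenter and encoder backends are pluggable; deterministic mock backends
    and a synthetic tomogram generator with known ground truth make every
    stage testable without model weights or external data. Includes MRC2014
    volume I/O and particle-picking precision/recall/F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
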