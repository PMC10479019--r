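Package: uscontour
Title: Semi-Automatic Parametric Contour Extraction for Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Point-guided extraction of smooth closed organ contours from
    grayscale ultrasound images. A few operator-supplied points near the
    boundary are denoised (Z-score filtering, histogram equalization),
    clustered by a neutrosophic-set mean shift with adaptive bandwidth to
    discover the vertices of a closed principal curve, and projected onto
    that curve to obtain arc-length indices. A small three-layer network
    trained with Caputo-type fractional-order gradient descent (seeded by a
    memory-based quantum-inspired differential evolution search) maps the
    index to boundary coordinates, yielding an explicit closed-form contour
    formula. Includes a speckle phantom generator with known ground truth,
    Dice/Jaccard/accuracy metrics, salt-and-pepper robustness sweeps and
    ablation switches.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
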