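Package: beekc
Title: Simulating Honeybee Visual Discrimination with Lobula Neurons and
    Mushroom Body Kenyon Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A bio-inspired simulator of achromatic pattern discrimination
    and generalization in the honeybee. Stimulus images (bars, crosses,
    sector and spiral discs, octagonal rings, checkerboards) are reduced to
    per-quadrant edge-orientation histograms by a retina-like pipeline
    (binarization, Canny/Sobel edge analysis). Eight large-field lobula
    orientation-sensitive neuron firing rates are computed from orientation
    tuning curves and a sublinear edge-length scale factor, and fed to
    populations of binary-threshold Kenyon cells wired under two
    alternative schemes: DISTINCT (one visual-field quadrant per cell) and
    MERGED (the same dorsal or ventral band of both eyes). Discrimination
    and generalization experiments are scored by a Kenyon cell similarity
    ratio over (rewarded, correct, incorrect) pattern triplets, including
    horizontal-offset sweeps probing stimulus-location invariance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
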