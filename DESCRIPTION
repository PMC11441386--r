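Package: mooneyr
Title: Automatic Generation and Evaluation of Two-Tone (Mooney) Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning photographs into two-tone (Mooney) images for
    visual psychophysics. Implements the full generation pipeline (CIE1931
    grayscale conversion, truncated Gaussian smoothing, 8-bit quantization,
    binarization) with four global threshold-selection techniques: mean
    intensity, Otsu's between-class variance criterion, and two spatial
    selectors that search all 256 candidate thresholds to maximize Canny
    edge-pixel count or minimize the directed Hausdorff distance between
    template and thresholded edge maps. Also provides image-level evaluation
    statistics (pairwise dissimilarity ratios, threshold distribution
    summaries, difficulty stratification), nearest-neighbour foil selection
    in a shape-related subspace of a concept embedding, a deterministic
    synthetic fixture generator, and a batch command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
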