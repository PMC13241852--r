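Package: histomil
Title: Region-Filtered Attention-Based Multiple Instance Learning for
    Slide-Level Grading of Intestinal Inflammation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Weakly supervised grading of inflammatory bowel disease
    histology from whole-slide images. Provides slide tiling with
    quality control, a portable container format for multi-level tissue
    segmentation maps (nuclei, glands, lumina, tissue types),
    quantitative per-slide histology statistics with a gradient-boosted
    baseline classifier, tissue-driven region filtering of encoder
    patches, a per-patch embedding store with a pluggable frozen-encoder
    adapter, and a gated-attention multiple instance learning classifier
    trained with focal loss and dynamic class weights that predicts
    Nancy Histological Index grades and renders interpretable attention
    maps. Deterministic synthetic generators for label maps, slide-like
    rasters and embedding bags make the full pipeline runnable and
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    rhdf5,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
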