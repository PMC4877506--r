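Package: stemdissect
Title: Anatomical Stem-Based Virtual Dissection of White-Matter Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting ventral association tracts (inferior
    fronto-occipital and uncinate fasciculi) from whole-brain diffusion-MRI
    tractograms by their anatomical stems: tractogram preparation filters
    (length, cortex-confined, U-shaped, cerebellar and inter-hemispheric
    streamline removal), stem exposure and single-slice stem ROI handling,
    stem-based tract extraction with exclusion rules, stem morphometry and
    inter-operator reliability, and quantitative cortical-termination
    analysis (normalized termination density scores, false-positive-region
    thresholding, Wilcoxon territory tests, presence frequencies and
    hemispheric asymmetry indexes). Includes a synthetic labeled-phantom and
    streamline-cohort generator with per-streamline ground truth for
    validating every filter and statistic. Reads and writes TrackVis TRK,
    MRtrix TCK and NIfTI-1 volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
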