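Package: cystscreen
Title: Gaussian-Filter Screening of Liver Cysts in CT Tumor Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing for deep-learning liver tumor segmentations on
    CT. Predicted tumor masks are decomposed into connected regions, each
    region's Hounsfield-unit histogram is smoothed and fitted with a Gaussian
    curve, and regions whose fitted mean falls below a cutoff (default 45 HU)
    are screened out as cysts. Includes NIfTI volume I/O, a synthetic CT
    phantom generator with known tumor/cyst ground truth, Dice and
    95th-percentile Hausdorff distance evaluation with paired comparisons,
    and a reference implementation of the multi-scale cross-entropy plus
    Dice training loss with deep supervision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
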