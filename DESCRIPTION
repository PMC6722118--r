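Package: mosaicquant
Title: Quantification of Mosaic DAB Immunostaining in Cardiac Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated scoring of cardiomyocyte protein mosaicism from
    DAB/hematoxylin brightfield histology. Unmixes RGB tissue-microarray core
    images into stain channels by optical-density color deconvolution, builds a
    ladder of binary masks from a global two-class Otsu threshold scaled by
    correction factors, removes sub-50-pixel debris, and scores each core as
    the percent of myocyte area strongly DAB-positive. Includes a ground-truthed
    synthetic image and cohort generator, validation statistics (manual-count
    concordance, replicate-core variation, paired cell-area comparison), and
    cohort-level linear mixed models with crossed random intercepts for subject
    and tissue microarray.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    lmerTest,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
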