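Package: stromascore
Title: Spatial Scoring of Tumor-Stroma Immune Microenvironments from Multiplex IHC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell spatial profiling of multiplex-immunohistochemistry tumor
    fields: segmentation of each field into invasive front, tumor nest and
    intratumoral stroma; marker gating against fluorescence-minus-one thresholds;
    region-wise cell densities; conventional and stroma-restricted Immunoscores;
    the MMP14-positive CAF fraction; four-group risk stratification with
    Kaplan-Meier and Cox proportional-hazards analysis; and a target-gene
    transcriptomic screen (Spearman correlation ranking and median-split
    differential expression with Benjamini-Hochberg FDR). Includes seeded
    generators for synthetic tissue fields, patient cohorts with survival
    outcomes, and expression matrices with planted co-expression.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    EBImage,
    survival,
    stats,
    utils,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
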