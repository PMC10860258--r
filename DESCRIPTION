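Package: mtbkit
Title: Molecular Tumor Board Analytics for Pediatric Precision Oncology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a molecular-guided therapy (MGT)
    decision pipeline for relapsed and refractory childhood solid tumors:
    expression-outlier scoring of tumor RNA against a whole-body panel of
    normal tissues (NRZ Z-scores) and a cancer-reference percentile (CRC),
    chromosome arm-level copy-number event calling, tumor mutational burden,
    mutational-signature decomposition of 96-context catalogs by non-negative
    least squares, a three-tier drug-gene matching algorithm assembling
    up-to-four-drug combination plans with resistance vetoes and interaction
    screening, RECIST v1.1 best-response classification with clinical-benefit
    and feasibility statistics, longitudinal shared/unique event partitions,
    and a seeded synthetic-cohort generator so the whole pipeline is testable
    without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    jsonlite,
    pracma,
    ggplot2,
    generics,
    withr,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
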