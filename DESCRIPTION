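Package: somaticsieve
Title: Tumor-Normal Somatic Variant Filtering and Recurrence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale reimplementation of a whole-exome somatic mutation
    detection and filtering cascade for matched tumor-normal pairs, together
    with a seeded synthetic cohort generator, a simulated-read remappability
    filter for pseudo-gene and segmental-duplication artifacts, and gene-level
    two-group recurrence statistics (two-sided Fisher exact tests, mutation
    frequencies, exclusivity calls, mutation spectrum). Candidate variants are
    enumerated directly from samtools mpileup-style text pileups, pushed
    through heuristic somatic rules, Phred-like variant quality, elimination
    criteria, remappability and germline-catalog masks, and summarised per
    gene across a two-group cohort. Includes closed-form laboratory scores
    (T7E1 indel percentage, immunohistochemistry product score, ellipsoid
    xenograft volume).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
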