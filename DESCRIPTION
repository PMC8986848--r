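Package: plasmacall
Title: Molecular-Tag Consensus Collapsing and Error-Profile Variant Calling for cfDNA Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for ultra-sensitive detection of low-frequency somatic variants in
    cell-free DNA from tag-based targeted sequencing. Aligned reads carrying molecular
    tags (UMIs) are grouped into read families keyed by tag, alignment position and
    strand, collapsed into single-strand consensus sequences under a strict majority
    vote, and piled up over a capture panel. A per-position, per-allele background
    error profile built from mutation-free control plasma samples - with conservative
    upper confidence bounds at error-free positions - drives a binomial tail test with
    Bonferroni control of the family-wise false-positive rate and a filter chain
    (minimum consensus coverage, dual-strand support, strand-bias exact test, minimum
    indel length, SNP masking). A synthetic tagged-read simulator with truth manifests
    supports spike-in dilution series and normal-control cohorts for sensitivity and
    specificity experiments at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang (>= 1.0.0),
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    Biostrings,
    rtracklayer,
    Rsamtools,
    BiocGenerics,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
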