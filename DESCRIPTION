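Package: rvpdt
Title: Haplotype- and Variant-Collapsing Pedigree Disequilibrium Tests
    for Rare Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Family-based association tests for rare variants in nuclear
    pedigrees.  Implements the haplotype-collapsing and variant-collapsing
    pedigree disequilibrium tests (hPDT, vPDT), the single-unit maximum
    tests (maxH, maxV) with pooled-permutation p-values, and
    training-split signed-weight variants (hPDT-t, vPDT-t), together with
    an EM algorithm over Mendelian-consistent phase configurations for
    unphased genotypes, linkage-format pedigree input/output, and two
    family-based simulators for power and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
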