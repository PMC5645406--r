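Package: polystrat
Title: Annotation-Stratified Burden Testing for Pooled Case-Control Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene- and pathway-level association testing for pooled
    targeted-sequencing studies. Implements an annotation-stratified
    one-sided burden test on per-pool non-reference allele rates across
    sixteen functional-by-evolutionary variant categories, with
    permutation p-values and empirical family-wise (minP) multiple-testing
    correction; hypergeometric gene-set enrichment pre-filtering and
    set-level burden tests; an isoform-collapsed chi-square comparison of
    a sequenced cohort against a large reference cohort with a
    case/control chi-square ratio score and per-isoform residual
    diagnostics; and a synthetic pooled-cohort generator with planted
    effects so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    Matrix,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    jsonlite
Config/testthat/edition: 3
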