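Package: fsgdep
Title: Subtype-Stratified CRISPR Dependency Analysis of Ferroptosis
    Suppressor Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes essential ferroptosis suppressor genes per tumor
    subtype from CRISPR knockout-screen dependency probabilities and matched
    expression data. Implements the DepMap-style filter cascade (expression,
    missingness, median-dependency cutoff, minimum essentiality fraction,
    common-essential removal), per-gene differential essentiality between two
    subtypes with an exact Wilcoxon rank-sum test and bias-corrected Hedges'
    g effect size, hypergeometric over-representation analysis, and a
    synthetic screen generator with planted gene roles for parameter-recovery
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
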