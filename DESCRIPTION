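Package: pleioscan
Title: Cross-Trait Pleiotropy Discovery from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finds genetic risk loci shared between pairs of complex traits
    from genome-wide association study (GWAS) summary statistics. Implements
    pairwise allele harmonization, lead-variant pooling with HLA/MHC region
    exclusion, linkage-disequilibrium (LD) proxy substitution, gatekeeper
    cross-trait testing under Bonferroni family-wise error control,
    single-causal-variant Bayesian colocalization with approximate Bayes
    factors, effective-sample-size formulas for case-control GWAS, and a
    synthetic summary-statistics generator with locus-level LD structure for
    end-to-end validation without access to real GWAS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    MASS,
    GenomicRanges,
    IRanges,
    rtracklayer,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
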