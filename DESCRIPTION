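Package: rcnvassoc
Title: Rare Copy-Number-Variant Case-Control Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Case-control association analysis of rare copy-number variants
    (rCNVs) called from genotyping-array data. Provides quality-control and
    frequency filtering of PLINK-format CNV calls, genome-wide burden metrics
    (total distance, CNV count, dosage-sensitive gene hits, evolutionarily
    constrained base proportions) with covariate-adjusted logistic burden
    tests, annotation of calls to syndromic and pleiotropic locus lists with
    Firth penalized-likelihood association tests, a CNV-type-specific rare
    breakpoint genome-wide scan with r-squared-based CNV-region definition and
    mirror-effect detection, analytic burden power calculations, and a seeded
    synthetic-data generator that emulates post-calling array CNV call sets
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
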