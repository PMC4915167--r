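Package: bayescqtl
Title: BayesC QTL Mapping with Bayes Factor Region Calling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian variable-selection association mapping for quantitative
    traits on dense SNP genotypes. Implements the BayesC mixture model (each
    marker effect is zero with probability 1 - pi and normal otherwise) with a
    weighted Gibbs sampler supporting deregressed-EBV pseudo-phenotypes,
    Bayes Factor evidence scoring of markers, sliding-window QTL region
    calling, cross-trait common-region identification and gene-interval
    annotation, together with a synthetic-data generator emulating half-sib
    cattle populations with block linkage disequilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    Rcpp,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
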