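Package: gerphet
Title: Deleterious-Allele Burden, Dominance and Heterosis in Diallel Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of incompletely dominant deleterious alleles in a
    partial diallel of inbred lines, using per-site evolutionary
    conservation (GERP) scores to identify putatively deleterious variants
    a priori. Provides best linear unbiased estimates of genotype values
    from multi-year field trials with broad-sense heritability, mid-parent
    heterosis and combining abilities; per-line deleterious-allele burden
    and hybrid complementation statistics; an additive-plus-dominance
    GBLUP model with per-SNP effect backsolving and degree-of-dominance
    estimation; identity-by-descent haplotype-block construction and
    GERP-weighted block complementation scores; BayesC genomic prediction
    with cross-validation against circularly permuted conservation scores;
    a mutation-selection-balance simulator; and a synthetic-data generator
    that emulates the statistical structure of a resequenced maize diallel
    for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
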