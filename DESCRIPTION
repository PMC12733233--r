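Package: mmpassoc
Title: Case-Control Association Analysis of MMP Polymorphisms and ACL Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for candidate-gene case-control association
    studies of biallelic SNP panels, built around the three matrix
    metalloproteinase polymorphisms (MMP1 rs1799750, MMP10 rs486055, MMP12
    rs2276109) studied for anterior cruciate ligament (ACL) injury risk.
    Provides single-locus tests under codominant, dominant, recessive,
    overdominant and log-additive genetic models with crude and
    covariate-adjusted odds ratios, Woolf confidence intervals and
    Benjamini-Hochberg false discovery rate control; exact and chi-square
    Hardy-Weinberg equilibrium tests; EM haplotype frequency estimation with
    posterior-weighted haplotype GLMs; logic-regression multi-locus analysis
    (simulated-annealing Boolean trees, bagged importance measures, and a
    permutation-null comparison protocol); analytic power and
    minimal-detectable-odds-ratio calculations; and a synthetic cohort
    generator emulating the study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
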