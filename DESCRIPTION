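Package: admixtract
Title: Demographic Inference from Local-Ancestry Tracts in Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the admixture history of recently admixed
    populations from phased haplotype data. Implements pulse-migration demographic
    models fit to local-ancestry tract-length spectra by Poisson composite
    likelihood, with simulation-calibrated likelihood-gain tests for choosing
    between nested migration models; ancestry-specific principal component
    analysis of locally masked haplotypes joined with subcontinental reference
    panels; haploid identity-by-descent detection with per-segment ancestry
    profiles, normalized sharing matrices and chromosome-weighted jackknife
    standard errors; and a forward pedigree simulator of admixed cohorts with
    known migration schedules that serves as the oracle for the analytic tract
    model and generates fully synthetic test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
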