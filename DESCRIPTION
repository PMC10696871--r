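Package: msnsubtype
Title: Morphometric Similarity Network Subtyping and Imaging Transcriptomics
Version: 0.1.0
Authors@R:
    person("MSN", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Construction of per-subject morphometric similarity networks (MSN)
    from regional cortical features, semi-supervised max-margin subtyping of
    patients (HYDRA) with cross-validated cluster-stability model selection,
    case-control regional statistics with covariate adjustment, AHBA-style
    expression preprocessing, PLS-based imaging transcriptomics with spin
    permutation and bootstrap inference, cross-disorder gene correlations, and
    regional cell-type scoring by ssGSEA. Includes a synthetic cohort generator
    that emulates the statistical structure these analyses assume, with ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
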