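Package: rdsprev
Title: Respondent-Driven Sampling Estimation of Hidden-Population Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for chain-referral (respondent-driven sampling, RDS) surveys
    of hidden populations, built around the reciprocity (RDS-I) estimator:
    referral-code parsing and recruitment-forest construction, estimation of the
    group-to-group recruitment transition matrix treated as a Markov chain,
    equilibrium (stationary) proportions, degree-weighted RDS-adjusted
    prevalence with dependent-bootstrap standard errors, Wald contrasts and
    prevalence ratios between strata, cumulative per-wave equilibrium
    diagnostics, and a synthetic chain-referral simulator for design studies
    when field data are confidential.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
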