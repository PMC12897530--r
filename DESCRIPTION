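Package: trustbayes
Title: Hierarchical Bayesian Modelling of Trust-Game Decision-Making
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a participant-level hierarchical Bayesian model of
    trust-game behaviour: a latent face evaluation built from
    attractiveness and trustworthiness ratings, a sigmoidal
    invest/not-invest choice, and a Gaussian investment amount. Includes
    Shannon-entropy response quality control, MCMC (slice-within-Gibbs)
    and MAP inference with convergence diagnostics, cross-validated
    prediction of held-out partners, biomarker association screening
    with Benjamini-Hochberg FDR control, and a synthetic-cohort
    generator with planted biomarker effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
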