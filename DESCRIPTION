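Package: aggpk
Title: Aggregate-Data Estimation for Nonlinear Mixed-Effects Pharmacokinetic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Maximum-likelihood estimation of population pharmacokinetic
    (nonlinear mixed-effects) models from aggregate data, i.e. the mean
    vector and variance-covariance matrix of observations across subjects
    sharing a design. Provides first-order (FO), first-order conditional
    (FOCE/FOCEI) and quasi-Monte-Carlo (MC) approximations of the predicted
    aggregate moments, the matching individual-data FO/FOCE(I) likelihoods,
    expected Fisher information by numerical differentiation of the
    aggregate log-likelihood (optimal design, including designs where the
    data-generating and data-analytic models differ), and a deterministic
    one-step replacement for stochastic simulation-and-estimation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
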