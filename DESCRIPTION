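Package: radpk
Title: Population Pharmacokinetics of Lisinopril in Irradiated and Control
    Rats
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models the pharmacokinetics of the ACE inhibitor lisinopril
    in partial-body-irradiated and control rats.  Provides the exact
    solution of a two-compartment disposition model with an oral (gavage)
    depot and a cumulative urine compartment, nonlinear mixed-effects
    estimation by the Laplace approximation with radiation-group
    covariate ratios, likelihood-ratio comparison of nested compartmental
    models, non-compartmental trapezoidal AUC estimation with bootstrap-t
    confidence intervals for sparse batch (serial-sacrifice) designs, and
    a synthetic-study generator that reproduces the study's sparse
    sampling layout so that every stage of the pipeline can be validated
    by simulation.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    graphics,
    Matrix,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    knitr,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
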