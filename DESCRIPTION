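Package: npqm
Title: Nonparametric Population Pharmacokinetics and Artificial
    Quasi-Models for Individual Dose Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for nonparametric population pharmacokinetic modeling of
    intravenously infused drugs, with piperacillin in critically ill adults
    as the reference application. Provides closed-form one- and
    two-compartment infusion models (optionally with creatinine clearance
    driving renal elimination), polynomial assay-error models mapping
    concentration to measurement standard deviation, an adaptive-grid
    nonparametric maximum-likelihood estimator of the discrete population
    mixing distribution, nonparametric maximum a posteriori (MAP) Bayesian
    individual estimation, and generators for fully artificial "quasi-model"
    priors (uniform random support points with equal probabilities) that can
    substitute for data-derived population models when few subjects are
    available. Includes a synthetic-cohort simulator emulating a rich
    q6h/3-h-infusion sampling design, Jelliffe's unstable-renal-function
    creatinine clearance, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
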