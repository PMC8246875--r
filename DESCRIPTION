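Package: raschsel
Title: Semi-Automated Rasch Analysis and Questionnaire Item Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the generalized partial credit model by ridge-penalized
    joint maximum likelihood, scores any split of a questionnaire into
    included and excluded items with the in-plus-out-of-questionnaire log
    likelihood (IPOQ-LL), and searches for the itemset maximizing this
    criterion by stepwise selection or exhaustive enumeration. Includes
    standard Rasch diagnostics (outfit and infit mean squares, residual
    correlations, person separation reliability, ability standard errors),
    random-instrument baselines, a chance-overlap probability, and seeded
    simulators for inhomogeneous, multidimensional and correlated survey
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
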