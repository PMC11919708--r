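Package: fjordSDM
Title: Presence-Only Species Distribution Modelling with Effort-Based
    Pseudo-Absences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for monthly presence-only species distribution
    modelling in small coastal study areas. Implements a penalized
    maximum-entropy presence/background model with hinge features, a
    6-16-32-64-1 feedforward neural network trained by gradient descent
    with warm starting across months, effort-proportional pseudo-absence
    generation from boat-trackline density, covariate screening (Pearson
    correlation and variance inflation factors), 10-fold cross-validated
    AUC evaluation with permutation importance, forward projection
    protocols, and a fully synthetic fjord data generator for end-to-end
    testing without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
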