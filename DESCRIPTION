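Package: ginsengms
Title: Geographic Origin Discrimination of Ginseng from LC-MS Metabolite Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end chemometrics pipeline for discriminating the
    geographic origin of Panax ginseng batches from UHPLC-Q-TOF-MS peak
    lists. Includes common-peak screening and alignment, ginsenoside
    annotation against a packaged reference table of negative-mode adduct
    masses and diagnostic aglycone fragments, mean and Z-score
    normalization, PCA and PLS-DA baselines with a label-permutation test,
    a soft-margin RBF support vector machine solved in its dual form with
    grid-searched hyperparameters, permutation-importance quality-marker
    discovery, and prediction of held-out samples from marker panels. A
    synthetic-data generator emulates the statistical structure of aligned
    peak-area tables so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
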