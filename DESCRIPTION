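Package: vbmsvm
Title: Linear Hard-Margin SVM Biomarkers from Voxel-Based Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains linear hard-margin support vector machines on modulated
    gray-matter volume maps to derive a per-subject structural brain biomarker
    (the signed distance to the decision boundary), with leave-one-out and
    split-half cross-validation, label-permutation inference for global
    accuracy/AUC and for voxelwise weight maps, the DeLong test for correlated
    ROC curves, covariate removal via residual-forming projections, and
    correlation/subgroup analyses against gestational age, birth weight and
    IQ. Includes a synthetic-cohort generator emulating a preterm-birth
    case-control morphometry study, and a minimal NIfTI-1 reader and writer.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    jsonlite,
    optparse
Config/testthat/edition: 3
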