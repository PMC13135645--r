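Package: avfflow
Title: Geometry and Wall-Shear Haemodynamics of Arteriovenous Fistulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anatomical and haemodynamic characterisation of
    end-to-side arteriovenous fistula (AVF) lumens. Generates parameterised
    synthetic AVF surface meshes and analytic pulsatile (Womersley) wall-shear
    fields, extracts centrelines with per-station equivalent diameter and
    curvature, measures the anastomosis angle, partitions vessels into 1 cm
    segments, computes wall-shear metric maps (TAWSS, OSI, transverse WSS,
    WSS spatial gradient, localised normalised helicity) with per-segment
    aggregation, evaluates a lumped Poiseuille pressure network for distal
    flow reversal, and reproduces cohort-level group summaries and
    Mann-Whitney ROC analysis of anatomical predictors of high venous outflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    glmnet,
    optparse
Config/testthat/edition: 3
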