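Package: alffsvm
Title: Longitudinal Resting-State ALFF Classification with RFE-SVM
Version: 0.1.0
Authors@R: person("alffsvm", "maintainers", email = "alffsvm@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for longitudinal (paired pre/post) resting-state
    fMRI analysis based on the amplitude of low-frequency fluctuations (ALFF).
    Computes voxel-wise and atlas-parcellated region-wise ALFF from 4D BOLD-like
    volumes, screens scans by Power framewise displacement, performs two-stage
    feature selection (leave-one-out paired t-test screening with confound
    residualization, followed by accuracy-driven recursive feature elimination
    around a linear soft-margin support vector machine), evaluates pre- versus
    post-training classification by leave-one-out cross-validation with
    permutation-based significance, and relates region-wise ALFF changes to
    behavioral change with FDR control. Includes a seeded synthetic-data
    generator producing paired BOLD-like images, parcellation atlases, motion
    traces and behavioral scores with known planted effects, so that every
    stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
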