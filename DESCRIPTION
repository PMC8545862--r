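Package: gbcmvpa
Title: Global Brain Connectivity Mapping and Multivariate Pattern Classification for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a resting-state fMRI analysis
    pipeline built around voxel-wise global brain connectivity (GBC, a
    degree-centrality map over a gray-matter mask) and multivariate pattern
    classification. Provides a synthetic multi-group cohort generator with
    planted connectivity effects, motion traces and clinical scores;
    framewise-displacement motion quality control; joint nuisance
    regression, detrending and band-pass filtering; blockwise thresholded
    Fisher-z GBC mapping with mask-aware Gaussian smoothing; linear-kernel
    support vector machine and Laplace-approximation Gaussian process
    classifiers under leave-one-subject-out cross-validation; permutation
    inference on performance and on voxel-wise discriminative weights with
    cluster extraction; and ROI-level statistics (Pearson and partial
    correlation with Bonferroni correction, summary-statistic ANOVA,
    covariate-adjusted voxel-wise t maps with TFCE permutation correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    e1071,
    pROC,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
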