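Package: typicality
Title: Convergence-State (Pattern Typicality) Analysis for Trial-Level fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the convergence of multivoxel activation
    states toward a prototypical pattern and for linking that convergence to
    behaviour. Implements trial-level least-squares-all (LSA) GLM estimation
    of beta series with t-to-z conversion, leave-one-run-out correlation-
    distance pattern typicality with k-means-mean or medoid centroids,
    univariate ROI summaries, mixed-effects models relating a modulatory
    univariate signal, typicality and trial-level memory outcomes (including
    likelihood-ratio model selection, subject-level bootstrap mediation and
    between-subject correlations), and a permutation-null-adjusted voxelwise
    correlation map with group-level family-wise error control. A seedable
    synthetic-cohort generator with planted effects supports end-to-end
    validation at both the pattern level and the BOLD level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr
Config/testthat/edition: 3
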