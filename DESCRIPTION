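Package: arcconflict
Title: Model-Based Analysis of Approach-Avoidance Conflict Behavior and BOLD Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint hierarchical Bayesian modelling of choices and response
    times in the aversion-reward conflict (ARC) task, yielding per-trial
    estimates of approach-avoidance conflict (the distance-to-decision-
    boundary statistic), together with the model-based fMRI pipeline that
    uses those estimates: variable-epoch parametric-modulation design
    matrices, voxelwise first-level GLM with percent-signal-change scaling,
    and second-level weighted least-squares inference with Freedman-Lane
    permutations, threshold-free cluster enhancement and family-wise error
    correction. Includes a synthetic-data generator for behavior and BOLD
    time series with known ground truth, so every stage is testable end to
    end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    coda,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags,
    RNifti
Config/testthat/edition: 3
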