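Package: hicap
Title: Hierarchical Co-Activation Pattern Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Volume-wise co-activation pattern (CAP) analysis of
    resting-state fMRI. Individual BOLD volumes are temporally normalized,
    masked, and clustered with Ward's method on cosine distances; cutting
    the merge tree at every level from 2 to 30 yields a nested registry of
    CAPs with level-ordinal labels. Per-CAP voxel-wise z-statistic maps,
    per-subject occupancy statistics (bootstrap confidence intervals of
    group medians, Mann-Whitney tests with Benjamini-Hochberg correction),
    voxel-wise two-group permutation contrasts with subject-level
    exchangeability blocks, threshold-free cluster enhancement (TFCE), and
    FDR pooled across all contrasts are provided, together with
    network-level summary matrices against a supplied atlas of network
    z-maps. A synthetic multi-subject brain-state generator with latent
    Markov dynamics supplies ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
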