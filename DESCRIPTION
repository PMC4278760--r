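Package: inlimbo
Title: Identify Brain Regions 'in Limbo' with Sandwich-Variance GLMs for fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mass-univariate general linear modelling of BOLD fMRI time series
    with replication-block sandwich variance and cross-voxel covariance
    estimators, cluster-extent thresholding (Gaussian random field or
    simulation-based), and a three-way classification of the brain into
    significantly activated voxels, voxels significantly less activated than
    the least-significant activated voxel, and voxels "in limbo" (differing
    neither from baseline nor from activated regions). Includes single-subject
    and weighted-least-squares group-level inference, a synthetic 2D fMRI data
    generator with ground truth for recovery studies, NIfTI-1 input/output,
    and a small command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    RNifti,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
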