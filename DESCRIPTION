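Package: thalnet
Title: Thalamocortical Functional Connectivity Parcellation and Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates thalamus-related functional brain networks from
    resting-state fMRI. Builds whole-brain Fisher-z correlation maps for every
    thalamic voxel, decomposes the concatenated group stack by spatial
    independent component analysis into network regions of interest, localizes
    the thalamic subdivisions driving each network by dual regression, and
    tests group differences with nonparametric permutation inference
    (threshold-free cluster enhancement and cluster-extent correction, with
    Freedman-Lane handling of nuisance covariates). Includes a synthetic
    two-group cohort generator with planted thalamocortical networks for
    validation, and the standard demographic comparison statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
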