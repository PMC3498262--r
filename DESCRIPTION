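Package: ptclock
Title: Clock-Face Localization of the Pyramidal Tract Relative to Deep-Seated Brain Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for locating the pyramidal tract (corticospinal tract)
    relative to thalamic and basal ganglia tumors from diffusion-weighted MRI.
    Fits the diffusion tensor per voxel by log-linear least squares, propagates
    streamlines with a tensor-deflection rule (20% previous direction, 80% major
    eigenvector), selects the tract with a three-VOI protocol, gates cases on
    voxel-wise Cohen's kappa between two operators, classifies tumors into eight
    types from a three-line landmark geometry on the foramen-of-Monro slice, and
    reports the tract position as an eight-sector clock-face statistic. Includes
    a digital tensor phantom generator with analytic ground truth that emulates
    the clinical acquisition (b = 1000 s/mm2, 12 directions, 1.9 x 1.9 x 3 mm
    voxels) for end-to-end in-silico validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
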