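Package: emsynapse
Title: Automated Chemical Synapse Detection in Anisotropic Serial-Section EM Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage detector for chemical synapses in serial-section
    transmission electron microscopy (ssTEM) image stacks with strongly
    anisotropic voxels. A 3D filter bank (Gaussian smoothing, Hessian and
    structure-tensor eigenvalues, Laplacian and difference of Gaussians)
    feeds a sparse-label Random Forest pixel classifier; synapse candidates
    are extracted from the resulting probability map by thresholding,
    connected components and size filtering, then segmented per candidate by
    exact minimization of a unary plus constant-Ising energy via
    max-flow/min-cut on the 6-connected voxel grid; a second Random Forest
    filters candidates using object-level intensity statistics, uniform
    local-binary-pattern histograms and shape anisotropy. Includes
    evaluation against point ground truth, per-synapse morphometrics
    (cross-section area, z-range, skeleton size, perforation count),
    blockwise processing with halos, and a synthetic phantom generator so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
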