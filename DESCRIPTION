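Package: langmap
Title: Language Network Mapping from Resting-State fMRI with a 3D Dense
    Convolutional Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the language resting-state network from
    functional MRI. Implements a complete phantom-to-ROC pipeline: synthetic
    BOLD phantom generation with planted resting-state networks, the standard
    denoising chain (detrending, low-pass filtering, spatial smoothing,
    nuisance and global-signal regression, frame censoring), seed-correlation
    feature volumes, a densely connected 3D convolutional network that
    classifies voxels into resting-state networks, a block-design task-fMRI
    general linear model comparator, construction of Broca- and Wernicke-like
    ground-truth regions from meta-analytic Z-maps, and group-level ROC
    evaluation with vertically averaged bootstrap confidence bands.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
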