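Package: midbrainseg
Title: Automated Segmentation of Midbrain Nuclei from Neuromelanin MRI and
    Quantitative Susceptibility Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic delineation of the neuromelanin-rich substantia
    nigra, iron-rich substantia nigra, red nucleus and subthalamic nucleus
    from paired magnetization-transfer GRE magnitude images and quantitative
    susceptibility maps (QSM). Implements the QSM reconstruction chain (phase
    unwrapping, SHARP background-field removal, iterative truncated k-space
    division), deformable-template atlas construction and mapping with a red
    nucleus slice-anchored midbrain crop, background-referenced and Otsu
    thresholding, a cyclic dynamic-programming active-contour boundary
    refinement balancing signal gradients against local radius of curvature,
    derivation of the substantia nigra pars compacta as the overlap of the
    neuromelanin and iron compartments, and evaluation metrics (DICE, volume
    ratio, volume loss, total iron and neuromelanin content). Includes
    synthetic phantom generators (shape phantoms, dipole-forward
    susceptibility phantoms, warped midbrain cohorts) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
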