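Package: gastroKT
Title: Dynamic Gastric MRI Simulation, k-t Interpolated Reconstruction,
    and Motility Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for contrast-enhanced dynamic
    gastric MRI in small animals. Provides a dynamic stomach phantom
    with saturation-recovery T1 contrast, quasi-periodic antral
    contractions and respiration; a time-interleaved Cartesian
    undersampling model with autocalibration lines and
    respiration-triggered packet scheduling; single-coil k-t
    convolutional-interpolation reconstruction calibrated by
    unregularized least squares on the autocalibration region; image
    quality metrics (relative error, SSIM, PSNR, maximum intensity
    projections); and gastric motility quantification (antral
    contraction amplitude, frequency, propagation velocity, and
    luminal volume) from dynamic image series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    RNifti,
    EBImage,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'gastroKT-package.R'
    'utils.R'
    'io.R'
    'methods.R'
    'motility.R'
    'phantom.R'
    'pipeline.R'
    'quality.R'
    'recon.R'
    'sampling.R'
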