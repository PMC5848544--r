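Package: histomri
Title: Integration of Post Mortem Brain MRI with Quantitative Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for relating quantitative post mortem brain MRI to
    stained histology sections. Provides voxel-wise quantitative MR
    parameter-map fitting (inversion-recovery T1, multi-echo T2 and T2*,
    log-linear diffusion tensor, and a quantitative susceptibility mapping
    chain of Laplacian phase unwrapping, V-SHARP background-field removal
    and thresholded k-space dipole inversion), colour-deconvolution stain
    quantification with positive-pixel classification and stained area
    fractions, a staged photograph-mediated histology-to-MRI
    co-registration chain (background keying, NMI block-face insertion,
    MIND-driven affine and deformable registration, curvilinear surface
    resampling and boundary-based registration), ROI-level comparison
    statistics, and seeded synthetic phantom generators with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    yaml,
    png,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
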