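Package: voxseg
Title: Modular Pipelines for Volumetric Medical Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular framework for semantic segmentation of volumetric
    (and planar) medical images: NIfTI data input/output behind an open
    data-interface contract, configurable preprocessing (intensity clipping,
    normalization, voxel-spacing resampling, one-hot encoding), deterministic
    overlapping patch extraction with mean-probability merging, training-time
    data augmentation (mirroring, rotation, scaling, elastic deformation,
    brightness, contrast, gamma, Gaussian noise), segmentation losses and
    metrics (soft and class-wise Dice, Jaccard, Tversky, categorical
    cross-entropy), a configurable 2D/3D U-Net with a native training engine,
    batch management with disk caching and epoch shuffling, and automatic
    evaluation (k-fold cross-validation, dataset statistics, tab-separated
    reports, slice overlay images). A synthetic labeled-phantom generator
    provides self-contained test data so the whole pipeline runs at desk
    scale on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    RNifti,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
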