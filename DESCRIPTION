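Package: epifat
Title: Epicardial Fat Quantification from Cine Dixon Water-Fat Cardiac MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying epicardial adipose tissue from
    water-fat separated (Dixon) cardiac magnetic resonance volumes.
    Provides a seeded synthetic cine Dixon cardiac phantom with an
    epicardial-versus-paracardial motion contrast, a reference two-point
    Dixon water-fat separation, per-voxel fat-fraction mapping,
    threshold-based epicardial fat segmentation and volumetry within
    per-slice regions of interest, cine frame selection by trigger
    delay, and observer-agreement statistics (Bland-Altman limits of
    agreement, intraclass correlation coefficients, body-surface-area
    indexed regression, paired comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dixon.R'
    'epifat-package.R'
    'fatfraction.R'
    'io.R'
    'stats.R'
    'roi.R'
    'quantify.R'
    'phantom.R'
    'observer.R'
    'utils.R'
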