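Package: GLIMtools
Title: Quantitative Intra-Golgi Transport Analysis with Golgi Ministacks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying intra-Golgi secretory transport from
    multi-channel fluorescence images of nocodazole-induced Golgi
    ministacks. Implements GLIM (Golgi localization by imaging centers of
    mass): sub-pixel center-of-mass localization, chromatic aberration
    correction from bead fields, the localization quotient (LQ) that places
    a cargo on the cis-to-trans Golgi axis, and Golgi region zoning.
    Fits LQ-versus-time series to first-order exponential kinetics, derives
    instantaneous transport velocities in LQ units and nm/min, estimates
    Golgi residence times from fluorescence decay traces with quality-control
    gates, and performs side and en-face particle averaging with axial
    Gaussian peak fitting and radial intensity profiling. A synthetic-image
    module generates ministack, bead, side-view and en-face images with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    minpack.lm,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Software, CellBiology, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
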