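Package: ommatid
Title: Quantification of Compound-Eye Ommatidial Mosaics from Immunohistochemistry and Eyeshine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify the organization of butterfly compound eyes
    from multichannel opsin immunohistochemistry, eyeshine photographs and
    calibrated monochromatic reflectance stacks. Provides automated
    segmentation of ommatidia from merged binary masks with area filtering,
    fill-fraction based opsin-positivity calls and ommatidial class counting
    with cross-section consistency checks; red/yellow eyeshine counting with
    dorsoventral regional summaries and repeatability reports; constant
    photon-flux shutter calibration, ROI spectra with dynamic-range quality
    control and per-wavelength group comparisons under Holm-Bonferroni
    correction; and a least-squares model that converts yellow-eyeshine
    fractions and ommatidial class proportions into an estimate of the
    probability that a blue photoreceptor co-expresses the long-wavelength
    opsin. A synthetic retinal-mosaic generator renders all three imaging
    modalities with exact ground truth so that every stage of the pipeline
    can be validated without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    car,
    withr,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
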