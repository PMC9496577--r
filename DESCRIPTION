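Package: platequant
Title: Quantitative Colorimetric Readout of 96-Well Microplate Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Turns a photograph of a white 96-well microplate into per-well
    optical densities and biomarker concentrations. The pipeline registers
    the image to the plate frame using four dark corner fiducials, corrects
    inhomogeneous illumination with a white-block calibration image,
    summarises each well by the mode of its RGB histograms weighted by the
    camera sensitivity at the assay's peak absorbance wavelength, estimates
    per-well incident light from neighbouring empty wells, and converts
    optical density to concentration through a log-linear standard curve
    with dilution correction. A synthetic plate-image generator with exact
    ground truth makes every stage testable without physical hardware.
    Ships configurations for Jaffe creatinine (490 nm) and glucose
    oxidase/peroxidase (560 nm) assays.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
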