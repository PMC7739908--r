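Package: stenoflow
Title: Haemodynamics and Occlusion Analysis for Stenotic Microfluidic Flow Chambers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Tools for analysing high-shear platelet aggregation assays in
    stenotic microfluidic flow chambers. Provides a parametric chamber
    geometry with rasterization, a steady Stokes flow solver (body-force
    driven, flow-wise periodic) with wall-offset shear-rate and shear-stress
    extraction, cell-transport metrics from labelled cell-position snapshot
    series (platelet flux maps, residence times, red-cell volume fraction and
    cell-depleted-layer thickness), an experimental occlusion pipeline
    (evaporation-corrected mass-balance flow metering, occlusion-time
    detection, width-averaged image intensity profiling and occlusion
    localization), and synthetic ground-truth generators that emulate the
    statistical structure of cell-resolved blood-flow simulations and
    bright-field microscopy recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
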