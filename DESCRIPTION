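Package: glucoFRET
Title: Simulation and Analysis of Ratiometric FRET Glucose Biosensor Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of two-photon time-lapse recordings of a
    genetically encoded ratiometric (YFP/CFP) glucose sensor expressed in
    single cells, together with a biophysical simulator that renders
    ground-truth two-channel image stacks for validating every stage by
    parameter recovery. Provides correlation-based rigid motion correction
    with subpixel refinement, boxcar temporal smoothing, mean-then-divide
    ROI ratiometry, one-point aglycemia calibration, transport-stop
    consumption-rate and uptake kinetics estimation, hierarchical
    (cells-within-slices-within-animals) mixed-model group comparison, and
    morphometric utilities (Sholl intersection profiles, edema-corrected
    infarct volumetry).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    lme4,
    lmerTest,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'protocol.R'
    'kinetics.R'
    'sensor.R'
    'simulate.R'
    'calibration.R'
    'glucoFRET-package.R'
    'groupstats.R'
    'io.R'
    'morphometry.R'
    'photometry.R'
    'registration.R'
    'scene.R'
    'pipeline.R'
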