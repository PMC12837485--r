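Package: pvla
Title: Quantitative Indices for the Fetal Pulmonary Venous-Left Atrium
    Connection on 3D Label Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the spatial relationship between the
    pulmonary veins (PV) and the left atrium (LA) on 3D segmentation label
    volumes from fetal cardiac ultrasound sweep scans, aimed at screening
    for total anomalous pulmonary venous connection (TAPVC). Implements the
    PV-LA distance (PLD) and PV-LA angle (PLA) indices, Dice and
    95th-percentile Hausdorff distance (HD95) segmentation-evaluation
    metrics, ROC/AUC screening analysis of normal versus TAPVC cohorts, and
    a synthetic voxel-phantom generator that emulates normal and TAPVC mask
    geometry so the full pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'mask_io.R'
    'indices.R'
    'phantom.R'
    'screening.R'
    'seg_metrics.R'
    'cli.R'
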