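Package: avfquant
Title: Wall Shear Stress and Notch Receptor-Ligand Interaction Quantification
    in a Rat Arteriovenous Fistula Model
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for vascular remodelling studies in the rat
    carotid-jugular arteriovenous fistula (AVF) model of arteriovenous
    malformations. Estimates wall shear stress from Doppler flow traces via the
    Poiseuille relation, quantifies immunofluorescence intensity (mean gray
    value, primary-antibody-control corrected) in endothelial and medial
    regions of interest, calls proximity ligation assay (PLA) interaction
    events from confocal z-stacks using intensity-threshold, particle-size,
    merged-blob and negative-control background rules, and links marker
    time-courses to shear stress with group summaries, baseline tests and
    correlation analysis. A seeded synthetic phantom generator produces
    ground-truth-known vessel cross-section images and flow series calibrated
    to the study design, so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    igraph,
    pracma,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'avfquant-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'hemodynamics.R'
    'roi.R'
    'phantom.R'
    'synthetic.R'
    'if_quant.R'
    'pla_quant.R'
    'stats.R'
    'io.R'
    'pipeline.R'
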