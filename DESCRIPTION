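Package: stimchip
Title: Dosimetry and Calcium-Imaging Analysis for On-Chip DC Electric
    Field Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic dosimetry for microfluidic direct-current
    electric-field (dcEF) stimulation chambers and a calcium-imaging
    analysis pipeline for the neuronal recordings such chambers produce.
    The dosimetry side models the electrolyte-filled channel network as a
    resistor network (Pouillet's law), solves branch currents by nodal
    analysis, converts them to per-section field intensities, and budgets
    electrode charge (delivered charge, disk current density, capacitive
    discharge window, capacitance from slow cyclic voltammetry and
    constant-current voltage excursions). The imaging side provides a
    seeded synthetic two-channel movie generator with ground truth,
    nuclear-channel cell detection by median blur, morphological
    background subtraction, thresholding and connected components,
    per-ROI trace extraction with rolling-median detrending to
    deltaF/F0, mean + k*SD calcium spike calling, and condition
    comparison by unpaired t-test with a culture-level cluster
    bootstrap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dosimetry.R'
    'electrochem.R'
    'group_stats.R'
    'io.R'
    'network.R'
    'pipeline.R'
    'segmentation.R'
    'synthetic.R'
    'traces.R'
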