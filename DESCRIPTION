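Package: oxyquant
Title: Targeted LC-MS/MS Quantification and Bioanalytical Validation of
    Plasma 4beta- and 4alpha-Hydroxycholesterol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, calibration and full bioanalytical validation
    workflow for the simultaneous targeted quantification of the
    oxysterols 4beta-hydroxycholesterol (a CYP3A phenotyping probe) and
    4alpha-hydroxycholesterol (an autoxidation marker) in human plasma by
    stable-isotope-dilution LC-MS/MS. Provides MRM chromatogram
    simulation and windowed peak integration, 1/x-weighted surrogate-
    matrix calibration with back-calculation, endogenous background-
    addition accuracy and precision statistics, apparent recovery and
    matrix-effect assessment, storage-stability classification against
    the 85-115 percent residual window, and three-group cohort
    comparisons (one-way ANOVA with Dunnett's many-to-one test,
    Kruskal-Wallis with Dunn's test). A synthetic-data generator with
    known ground truth drives every stage so the complete pipeline runs
    and is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    mvtnorm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'calibration.R'
    'constructors.R'
    'chromatogram.R'
    'cohort.R'
    'io.R'
    'oxyquant-package.R'
    'synthetic.R'
    'validation.R'
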