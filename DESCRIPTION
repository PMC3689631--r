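Package: epiTurnover
Title: Epidermal Protein Turnover from Heavy-Water Labeling of Tape Strips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring epidermal protein turnover non-invasively
    from oral heavy-water (2H2O) labeling and serial tape stripping.
    Implements mass-isotopomer distribution computation for derivatized
    alanine and the excess M1 (EM1) labeling readout, one-compartment
    simulation and interpolation of body-water deuterium enrichment under a
    twice-daily dosing protocol, precursor-product fractional synthesis,
    fitting of a delayed mono-exponential (conveyor-belt) rise to recover
    label appearance lag and replacement rate per skin site, spectral-count
    proteomics summaries (abundance index and keratin fraction), and
    transepidermal water loss (TEWL) contrasts between lesional and
    uninvolved skin. A seeded synthetic-cohort generator reproduces the
    statistical structure of a heavy-water tape-strip study for closed-loop
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'isotopomers.R'
    'bodywater.R'
    'kinetics.R'
    'proteomics.R'
    'tewl.R'
    'synthetic.R'
    'io.R'
    'epiTurnover-package.R'
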