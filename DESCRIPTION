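Package: hdnirs
Title: High-Density fNIRS Motor-Imagery Analysis and Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for high-density continuous-wave functional
    near-infrared spectroscopy (fNIRS) recordings of short-duration left/right
    hand motor imagery. Provides a 12-tile montage geometry model, a synthetic
    multi-subject cohort generator with hair/demographic coupling effects,
    causal preprocessing (log optical density, MACD-type bandpass, temporal
    derivative distribution repair, GVTD trial rejection, recursive ZCA,
    modified Beer-Lambert law), per-channel and ROI-weighted signal-quality
    scoring with poor-quality session partitioning, block-average hemodynamic
    response estimation with FDR-corrected group statistics, a
    subject-independent spatio-temporally regularized logistic-regression
    decoder (trace-norm plus Tikhonov penalties, solved by monotone FISTA),
    five reference decoders from the motor-imagery literature, leave-one-
    subject-out and blockwise cross-validation harnesses, and a demographic
    factor-analysis battery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    Matrix,
    MASS,
    e1071,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
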