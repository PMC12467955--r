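Package: eisfit
Title: Automated Equivalent-Circuit Analysis of Electrochemical Impedance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automated interpretation of electrochemical impedance spectroscopy (EIS)
    data. Provides a library of equivalent-circuit models (Randles, constant-phase-element
    and Warburg variants, layered biofilm circuits), hybrid global-local parameter
    estimation combining bounded differential evolution with Levenberg-Marquardt
    refinement under physical constraints, circuit selection by a gradient-boosted
    classifier on multi-metric error features with error-importance feedback,
    Kramers-Kronig measurement-model validation and time-constant distribution
    analysis, a calibrated synthetic-spectrum generator for training and benchmarking,
    and interpretable random-forest regression from fitted circuit parameters to an
    external quantity such as analyte concentration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    parallel,
    pracma,
    xgboost,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
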