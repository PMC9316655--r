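Package: specfp
Title: Molecular Fingerprint Prediction from Tandem Mass Spectra for Metabolite Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates metabolites from tandem mass spectrometry (MS/MS) data by
    predicting a 528-bit composite molecular fingerprint (MACCS, FP3 and FP4
    keys) from binned fragment spectra with a one-dimensional convolutional
    neural network, then ranking candidate compounds retrieved by precursor
    mass or molecular formula using Tanimoto similarity between predicted and
    computed fingerprints. Includes readers and writers for MSP and MGF
    spectral libraries, the spectral preprocessing chain (scaling, filtering,
    merging, integer m/z binning), classical multi-label baselines, instrument
    context routing across eight model cells, structure-disjoint evaluation
    with top-k ranking accuracy, and a synthetic corpus generator with a
    planted fingerprint-to-spectrum mapping for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
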