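Package: praman
Title: Raman and Fluorescence Chemometrics for Photodynamic Theranostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Spectral analysis toolkit for combined Raman-spectroscopic
    diagnosis and photodynamic-therapy (PDT) monitoring. Implements the
    full single-point Raman preprocessing chain (cropping, asymmetric
    Whittaker baseline subtraction, cosmic-ray despiking, Savitzky-Golay
    smoothing, area normalisation), PLS-DA classification with Venetian
    blinds cross-validation, replicate quality statistics (SNR, spectral
    coefficient of variation), difference-spectrum treatment monitoring,
    and a fluorescence-based protoporphyrin IX (PPIX) tissue
    quantification assay with standard curves and PDT dosimetry helpers.
    Ships seeded synthetic-data generators emulating tumour and control
    tissue Raman signatures and PPIX fluorescence standards so that every
    stage of the analysis can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
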