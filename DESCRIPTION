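Package: jujubeNIR
Title: Near-Infrared Determination of Vitamin C in Fresh Jujube and
    Shelf-Life Prediction from Degradation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A chemometrics pipeline for quantifying vitamin C in fresh
    jujube (Ziziphus jujuba) from Fourier-transform near-infrared spectra
    and predicting shelf life at room temperature. Implements spectral
    pretreatment (Savitzky-Golay smoothing and derivatives, multiplicative
    scatter correction), regression-coefficient wavelength selection,
    multiple linear regression calibration with hold-out validation,
    zero-order and first-order vitamin C degradation kinetics, and the
    combined spectra-to-storage-time inversion that estimates safe storage
    time. Includes a synthetic storage-study generator emulating a
    destructive longitudinal sampling design (daily spectra, one group
    titrated per day) for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
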