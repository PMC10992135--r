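Package: photodose
Title: Photon-Dose Modelling of Light-Induced Beta-Carotene Accumulation in Dunaliella salina
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiative transfer and photon dosimetry for flat-plate
    photobioreactor cultures of the halotolerant green alga Dunaliella
    salina. Implements the Lambert-Beer and Cornet two-flux light
    attenuation models with pigment-dependent optical coefficients,
    volume-averaged irradiance by Gauss-Legendre quadrature, the average
    number of photons received per cell (APRPC) dose metric, closed-loop
    constant-dose induction simulation with feedback control of the
    incident irradiance, spectrophotometric pigment quantification, and
    recovery of the trigger and saturation photon doses for beta-carotene
    accumulation from dose-response data. Ships a synthetic-data generator
    for attenuation and induction experiments together with the published
    coefficient and dose tables as plain-text fixtures.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    pracma,
    withr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
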