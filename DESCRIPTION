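Package: uaextract
Title: Modeling and Optimization of Ultrasound-Assisted Phytochemical Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling ultrasound-assisted solid-liquid extraction of
    phytochemicals: four-factor central composite circumscribed designs, a
    feed-forward log-sigmoid neural-network surrogate trained by a
    Levenberg-Marquardt optimizer with analytic Jacobians, signed
    connection-weight influence analysis, real-coded genetic-algorithm
    optimization over the surrogate, pseudo-second-order extraction kinetics,
    Arrhenius and Van't Hoff thermodynamic analysis (activation energy,
    enthalpy, entropy, Gibbs free energy), film/diffusion transport numbers,
    and a synthetic-study generator that emulates the full experimental
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
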