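Package: halocat
Title: Quantitative Assay Analytics for Halohydrin Dehalogenase Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for enzyme-engineering assay data from halohydrin
    dehalogenase (HHDH) campaigns: quantification of epoxide ring-opening via a
    ratiometric bromothymol-blue pH-indicator assay (isosbestic normalization,
    indicator equilibrium, buffer capacity), halide-release dehalogenation
    quantification with linear standard curves, background-subtracted initial
    rates and specific activities, Michaelis-Menten and cooperative Hill
    kinetic fitting, enantiomeric-ratio (E-value) and regioselectivity
    computation for kinetic resolutions, derivative-maximum melting-temperature
    extraction from thermofluor melt curves, and shortest-path-map analysis of
    residue-motion correlation graphs. A synthetic-data module generates every
    input the pipeline consumes, with the statistical structure the analyses
    assume, so the full chain is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
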