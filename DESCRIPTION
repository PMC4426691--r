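Package: eemparafac
Title: PARAFAC Modeling of Fluorescence Excitation-Emission Matrices
Version: 0.1.0
Authors@R:
    person("Analytics", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for decomposing fluorescence excitation-emission matrices
    (EEMs) of dissolved organic matter into trilinear PARAFAC components.
    Covers the full chemometric workflow: inner-filter correction, Raman-area
    normalization, scatter excision, per-sample total-signal normalization
    with exact score reversal, non-negative alternating least-squares PARAFAC
    with missing-data support, split-half and core-consistency validation,
    Tucker-congruence matching of components across models, and a
    peak-picking sensitivity analysis that regresses component maximum
    fluorescence against raw intensity at every wavelength pair. A synthetic
    EEM generator with Gaussian-band fluorophore libraries, inter-source peak
    shifts, scatter and cocktail contamination designs makes every stage
    testable without measured samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
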