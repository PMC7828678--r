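Package: immunopk
Title: Pharmacokinetics and Dosimetry of Chelator-Conjugated Radioimmunoconjugates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for lutetium-177 labelled antibody constructs
    carrying a variable number of DOTA chelators: chelator-to-antibody ratio
    (DAR) estimation from deconvoluted mass-spectrum peak lists, immunoreactive
    fraction estimation by the Lindmo cell-binding extrapolation, a linear
    multi-compartment biodistribution model whose liver, tumor, uterus, spleen
    and bone uptake rates are tied to DAR and immunoreactivity through linear
    covariate laws and fitted simultaneously across conjugates, and murine
    dosimetry (time-integrated activity coefficients and organ absorbed doses
    per unit injected activity). Includes synthetic-data generators that
    emulate a six-conjugate mouse biodistribution study design so that every
    stage can be exercised without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
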