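Package: metacascade
Title: Generation-Based Simulation of Gompertzian Tumour Growth and
    Metastasis Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the metastatic cascade on top of Gompertzian primary
    tumour growth using successive generations of tumour cells.  Two discrete
    engines approximate the Gompertz law (a metabolic-stagnation engine with
    stretching generation times and a generation-dependent-rates engine with
    decaying doubling excess), feeding an expected-value
    dissemination-circulation-colonization cascade with higher-order
    (metastasis-from-metastasis) recursion, Poisson sampling of randomized
    disease courses, a numerical colony-size reference model for calibration,
    and the parameter-fitting workflows for a hepatocellular carcinoma case
    and breast-cancer registry stage summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    withr,
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
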