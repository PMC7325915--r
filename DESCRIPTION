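Package: reriscan
Title: Additive Gene-Environment Interaction in Matched Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating additive-scale interaction between drug
    exposure and SNP genotype in individually matched (1:m) case-control
    studies. Implements the matched-set conditional logistic likelihood with
    an exact Newton-Raphson solver, four-category joint exposure-by-genotype
    odds ratios, the Relative Excess Risk due to Interaction (RERI) and the
    synergism index S with delta-method and stratum-bootstrap confidence
    intervals, Hardy-Weinberg equilibrium quality control on controls,
    change-in-estimate covariate selection with BIC backward elimination,
    and a matched-cohort simulator with known four-cell odds structure for
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
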