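Package: asdest
Title: Point Estimation After Adaptive Seamless Trials with Subpopulation
    Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Point estimation for two-stage adaptive seamless phase II/III
    trials in which stage-1 data select either a pre-specified subpopulation
    or the full population for stage-2 confirmation. Provides the naive
    two-stage estimators together with exact quadrature of their conditional
    selection bias, conditionally unbiased (UMVUE) estimators obtained by
    Rao-Blackwellization in closed form, variants for unknown subpopulation
    prevalence and for a binding interim futility rule, and a seeded Monte
    Carlo engine for conditional bias and mean squared error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
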