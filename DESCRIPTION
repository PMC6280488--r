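Package: pphloss
Title: Lognormal Analysis of Postpartum Blood Loss
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing measured postpartum blood-loss volumes as a
    continuous outcome instead of a dichotomised one. Fits two- and
    three-parameter (threshold) lognormal distributions by maximum likelihood
    or by quantile matching, estimates probabilities of haemorrhage events
    ("blood loss above 500 or 1000 mL") with delta-method confidence
    intervals, compares treatment arms through matched-row bootstrap relative
    risks, screens measurements for digit preference and limit-of-detection
    artefacts, computes two-arm trial sample sizes under binomial and
    lognormal analyses, and simulates realistic trial datasets including the
    measurement artefacts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
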