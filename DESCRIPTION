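Package: ordvasc
Title: Ordinal Versus Binary Analysis of Vascular Prevention Trial Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the statistical efficiency of ordinal (severity-graded)
    and binary analyses of vascular event outcomes in prevention trials. Provides
    ordered severity scales and deterministic outcome construction from
    participant-level records, a synthetic trial generator under a latent
    proportional-odds treatment effect, a fifteen-method analysis battery
    (chi-square, trend, rank, regression, win ratio and bootstrap tests), a
    p-value ranking engine with tie-adjusted Friedman ANOVA and Duncan's
    multiple range grouping, rank-based sample-size formulas with
    ordinal-versus-binary multiplier reports, and a bootstrap type-I-error
    assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    survival,
    yaml,
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
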