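Package: lpac
Title: Level of Preventive Action Risk Assessment for Construction Works
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Occupational risk assessment for construction sites with the
    Level of Preventive Action (L_pac) method, an extension of the William
    T. Fine multiplicative risk score.  Quantifies qualitative
    probability/consequence ratings on the characteristic-value scale
    {1, 3, 5, 9, 15, 25}, scores six preventive parameters (relative risk,
    borderline risk, degree of exposure, economic capacity, participative
    interest, level of satisfaction) from inspection rubrics and an on-site
    psychosocial survey with worker/assessor risk-perception congruence,
    and classifies each risk, each risk-combating technique, and the whole
    site into six preventive-action control levels under an exigency scale
    factor.  Includes YAML inspection records, a batch campaign mode, a
    seeded synthetic inspection generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
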