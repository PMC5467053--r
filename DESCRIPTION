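Package: upstatetools
Title: Cortical UP-State Detection and Mouse Phenotyping Battery Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing extracellular multiunit recordings and mouse
    behavioural phenotyping batteries of the kind used in preclinical fragile X
    (Fmr1 knockout) drug studies. Implements envelope-threshold detection of
    spontaneous cortical UP states (rectified, low-pass filtered traces with a
    5x RMS-noise threshold and 200 ms minimum-duration / 600 ms end-gap /
    600 ms merge rules), per-slice event summaries, behavioural battery derived
    measures (novel object recognition discrimination index, percent prepulse
    inhibition, ordinal audiogenic seizure scoring, locomotor interval binning,
    pERK/ERK ratio normalisation, dendritic spine segment profiles) with the
    published exclusion rules, the matching inferential toolkit (factorial and
    mixed-factor ANOVA with type III tests, exact Wilcoxon rank-sum by full
    enumeration with mid-ranks, Benjamini-Hochberg FDR pairwise families,
    one-tailed preplanned contrasts, control-group pooling), dose-equivalence
    arithmetic (calcium molar equivalence and body-surface-area human
    equivalent dose), and synthetic-data generators with ground truth so every
    stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    nlme,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
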