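Package: fpefam
Title: Female Protective Effect Analyses for Family Studies of Autism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the female protective effect (FPE) in autism
    spectrum disorder with family data. Provides a liability-threshold family
    simulator with sex-specific diagnostic thresholds, polygenic transmission
    and high-impact de novo variants; registry-style sibling-recurrence
    analysis with age- and sex-matched controls and Wald comparisons of odds
    ratios; polygenic-score group contrasts with principal-component
    adjustment and reference-population standardization; the polygenic
    transmission disequilibrium test (pTDT); and classification of high-impact
    de novo variants. All analyses run end to end on simulated cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
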