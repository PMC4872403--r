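Package: adaptrain
Title: Adaptive Signal-to-Noise Cognitive Training Trials in Silico
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates performance-adaptive cognitive training for children
    with attention deficit/hyperactivity disorder and the randomized
    controlled trial that evaluates it, entirely in silico. Provides
    3-down-1-up staircase controllers that hold exercise difficulty in a
    75-85 percent-correct band, a 25-exercise training registry with
    complexity-tier unveiling and a 30-hour curriculum scheduler, virtual
    subjects with logistic psychometric observers, latent traits, saturating
    learning and a symptom model coupling distractor suppression to parent
    ADHD ratings, the clinical assessment battery (continuous performance
    test halves scored by d-prime, spatial and verbal span response speed,
    Stroop interference, SWAN screening, ADHD-RS and CGI records), a blocked
    stratified trial engine, and the full nonparametric and mixed-ANOVA
    analysis pipeline implemented from formulas with exact small-sample
    null distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    car,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
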