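Package: isingseg
Title: Ising-Model Integration and Segregation Statistics for Parcellated Brain Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the balance between integrated (globally ordered) and
    segregated (locally disordered) brain dynamics by mapping binarized,
    region-parcellated fMRI signals onto a mean-field Ising model. Provides
    signal binarization and synchrony computation, exact mean-field synchrony
    distributions with an effective-region-count hyper-parameter, maximum-entropy
    coupling fits by moment matching, critical-point calibration of the synchrony
    threshold, segregation probabilities (Pseg/Pint), Metropolis-Hastings Ising
    dynamics on explicit connectome graphs with an edge-removal protocol, a
    synthetic cohort generator with planted effective dimension and age-dependent
    coupling schedules, and a cohort pipeline with quality-control rules and
    age-trend statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    broom,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
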