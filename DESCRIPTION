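Package: hallmarksim
Title: Hallmark-Driven Simulation of Cancer Clonal Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic, clone-tracked branching-process simulator of
    tumor evolution in which the mutational states of named tumor-related
    genes set cancer-hallmark variables through weighted linear
    combinations, and the hallmark variables interfere with per-cell fate
    trials (apoptosis, environmental death, division under logistic
    friction, replicative-limit immortalization, invasion/metastasis).
    Includes variant-allele-frequency summary statistics of simulated
    populations, rejection approximate Bayesian computation to calibrate
    the gene-to-hallmark weights against observed VAFs, maximum a
    posteriori weight extraction, and in-silico gene-nullification
    experiments that quantify each gene's contribution to tumor burden,
    metastasis and clonal diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
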