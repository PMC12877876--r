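Package: divphy
Title: Phylodynamic Inference for Division-Coupled Mutations in Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-based phylodynamic inference for populations of
    dividing cells in which mutations arise at discrete cell divisions rather
    than continuously in calendar time. Branch mutation counts follow a
    compound Poisson distribution driven by both visible and hidden divisions
    (divisions whose side lineages died out or were not sampled). The package
    provides the closed-form per-branch distributions, a dynamic-programming
    likelihood for mutation-annotated trees under incomplete extant sampling,
    a validated forward birth-death simulator with tree reconstruction,
    maximum-likelihood fitting of the relative death rate and per-division
    mutation mean, a constant-rate molecular-clock comparison model, and a
    clade-heterogeneity likelihood-ratio test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
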