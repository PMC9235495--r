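Package: dolvm
Title: Causal Query Estimation in Partially Observed Biomolecular Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and Bayesian estimation of interventional queries
    on gene-regulatory and signaling pathways where some components are
    unobserved. Provides acyclic directed mixed graphs with graph surgery
    (mutilation, d-separation, latent projection, confounded components),
    sound-and-complete do-calculus identification (back-door, front-door and
    the recursive district-based ID algorithm) returning do-free estimands,
    causal latent variable models over Gaussian, Bernoulli-logit, Gamma and
    Hill-sigmoid node families, MCMC posterior inference via JAGS, and
    estimation of P(Y|do(x')) and E[Y|do(x')] by graph mutilation plus
    posterior-predictive sampling.  Includes builders for eight benchmark
    pathway systems (feed-forward motifs, napkin motifs, an insulin-like
    growth factor signaling cascade simulated with the Gillespie algorithm,
    and a SARS-CoV-2 cytokine-storm network), plug-in adjustment estimators
    and closed-form linear-Gaussian oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    rjags,
    coda,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
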