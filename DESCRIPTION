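Package: naturalcausal
Title: Natural Causal Effects Between Interacting Dynamical Subsystems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to decide when the influence of one dynamical subsystem
    on another can be interpreted as a cause-and-effect relation (a
    "natural causal effect") and to quantify such effects with
    information-theoretic divergences. Provides exact probability
    machinery for finite-valued causal models (truncated-factorization
    interventions, back-door adjustment, d-separation), structural and
    numeric existence criteria for natural and conditional natural causal
    effects, time-series causal graphs at microscopic, mesoscopic and
    macroscopic scales, and two fully analytic worked model families: a
    bivariate binary stationary Markov process of order one (transfer
    entropy, Jensen-Shannon divergence of postinterventional
    distributions, mechanism-change divergence) and bivariate linear
    Gaussian stationary autoregressive processes (Gaussian transfer
    entropy, closed-form Kullback-Leibler divergences).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
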