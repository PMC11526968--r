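Package: gecnet
Title: Generative Effective Connectivity and Whole-Brain Dynamics with
    Competitive Interactions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits signed generative effective connectivity (GEC) from
    functional-connectivity statistics under a network of coupled stochastic
    Hopf (Stuart-Landau) oscillators, with and without competitive (negative)
    interactions, and quantifies the dynamical and computational consequences:
    Kuramoto order-parameter metastability, intrinsic-driven-ignition and
    temporal-irreversibility hierarchies, persistent synergy from Gaussian
    minimum-mutual-information integrated information decomposition (MMI-PhiID),
    differential identifiability, cognitive matching against a map bank, and
    connectome-based reservoir memory capacity. A synthetic-cohort generator
    provides ground-truth signed connectomes and simulated BOLD so the whole
    pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, TimeCourse, Software
RoxygenNote: 7.3.3
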