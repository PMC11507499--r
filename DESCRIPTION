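Package: fedsim
Title: Federated Learning Simulation with Attention Aggregation and
    Proximal Adam Local Updates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Single-process simulator for federated learning on statistically
    heterogeneous (non-IID) clients, built around two families of algorithms:
    server-side aggregation by sample-size weighted averaging or by
    attention weights derived from client-server parameter distances
    (FedAvg, FedAtt), and client-side local updates by SGD, perturbed
    (proximal) gradient descent, Adam, or proximally perturbed Adam
    (FedProx, FedPA, FedAvgS, FedProxP, FedAttS, FedPAP). Includes the
    parameterised synthetic(alpha, beta) heterogeneous classification data
    generator, multinomial logistic regression and LSTM sequence classifier
    clients with exact hand-derived gradients, a medical-dialogue JSON data
    path with a synthetic corpus fixture generator, experiment presets,
    tidy metrics, and ggplot2 training-curve plots.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
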