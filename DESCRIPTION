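Package: lagrace
Title: Single-Sample Gene-Program Dysregulation Scores from a Reference Regulatory Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a reference regulatory network over latent gene programs and
    clinical variables from control samples, predicts a pseudo-control outcome for
    every variable in each treatment or disease sample from its Markov blanket, and
    scores per-sample dysregulation as the divergence between observation and
    prediction. Includes identifiable overlapping latent-factor discovery from
    expression data (pure-variable based), greedy equivalence search with a
    degenerate-Gaussian score for mixed continuous/discrete data, Markov-blanket
    regression, graph-based clustering of divergence profiles, chance-adjusted
    clustering indices, and a mixed graphical-model simulator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
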