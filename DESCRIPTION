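Package: spacedrep
Title: Optimal Spaced-Repetition Scheduling with Marked Temporal Point Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling human memory and optimising review schedules.
    Implements an exponential forgetting-curve memory model whose forgetting
    rate jumps multiplicatively at each review, the provably optimal
    reviewing-intensity rule u(t) = q^(-1/2) (1 - m(t)) derived from stochastic
    optimal control of jump stochastic differential equations, exact sampling
    of review times by Poisson thinning, baseline schedulers (uniform and
    threshold-based), a learner simulator that generates synthetic review logs,
    half-life-regression style parameter estimation, closed-form point-process
    likelihoods, and a likelihood-matched natural-experiment evaluation of
    scheduler quality via the empirical forgetting rate.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
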