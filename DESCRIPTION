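Package: saltatory
Title: Hierarchical Model-Based Planning with Options in Gridworlds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying hierarchical model-based reinforcement
    learning in the classic rooms gridworld. Implements temporally abstract
    actions (options) with initiation sets, policies, termination functions
    and pseudo-rewards; exact and Monte-Carlo option models (joint
    distributions over termination state and duration plus expected
    discounted reward); three sample-based planners (flat, hierarchical, and
    saltatory planning that leaps to subgoals via option models); planning
    under per-step memory failure; semi-Markov value-iteration oracles; and
    successor-representation analyses that discover bottleneck states
    (doorways) by clustering predictive representations. Results are tidy
    tibbles with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
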