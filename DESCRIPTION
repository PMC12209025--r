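Package: negrowth
Title: Novel Exploration Growth Analysis for the Elevated Plus Maze
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies anxiety-like behaviour in the rodent elevated plus
    maze through novel exploration growth (NEG), the cumulative percentage
    of 1-cm maze segments receiving their first visit over time.  Provides
    trajectory discretisation onto a unidimensional occupancy grid,
    conventional open-arm measures, simulation of exploratory, delayed and
    avoidant behavioural phenotypes, Bayesian sigmoid change-point models
    with PSIS-LOO phase selection, time-resolved phenotype and arm-type
    effect estimation with ROPE-based equivalence decisions, and mapping of
    the fitted evidence to an ordinal anxiety-like-behaviour grade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    graphics,
    grDevices,
    mgcv,
    rjags,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
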