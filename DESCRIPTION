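Package: obsremedy
Title: Optimal Observation Remedies for Structural Identifiability of
    Directed Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Given a directed acyclic biological network modelled as a
    linear recursive structural equation model and a partial observation
    scheme, finds minimum sets of additional nodes to observe so that
    every edge coefficient becomes at least locally structurally
    identifiable. Implements Wright's path (trek) enumeration, symbolic
    identifiability equations as monomial sets, detour-path detection,
    graphical redundancy rules, the identifiability-gain edge-removal
    construction, and a stage/state dynamic program over candidate
    observation strategies, together with an independent generic
    Jacobian-rank oracle and exhaustive verifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
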