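Package: neuroresil
Title: Damage Resilience Analysis of In Vitro Neuronal Networks from Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how cultured neuronal networks respond to physical
    damage. The package simulates aggregated and homogeneous neuronal cultures
    (structural connectivity, spontaneous cascading bursts, calcium
    fluorescence at 50 frames/s), converts fluorescence traces to normalized
    dF/F and Schmitt-trigger binarized activity, detects network bursts and
    inter-burst intervals, infers directed effective connectivity with
    generalized transfer entropy (Markov order 2, instant feedback, joint
    distribution z-score significance), characterizes the resulting graphs
    (degrees, global efficiency, Louvain modularity, betweenness centrality),
    and orchestrates targeted-attack versus random-failure sequences as well
    as diametral-cut and recovery protocols with region-resolved activity and
    interaction summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
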