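Package: commdyn
Title: Dynamic Community Analysis of Fission-Fusion Animal Societies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers dynamic (time-varying) social communities from time-stamped
    group-sighting data by parsimonious community coloring: groups observed at
    consecutive sampling occasions are linked by Jaccard overlap and tracked by
    maximum-weight bipartite matching, and each individual's community
    affiliation over time is assigned by dynamic programming minimizing social
    costs of switching, visiting and absence. Provides static and temporal
    network summaries, per-group/community/individual dynamic community
    metrics, a feature-space statistical stage (PCA, Welch t-tests, Fisher
    exact test on switching, radial-SVM repeated holdout), a probabilistic
    fission-fusion society generator with planted communities for recovery
    evaluation, and an exhaustive small-instance oracle for the coloring
    optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
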