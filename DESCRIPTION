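Package: sdmnet
Title: Sex Differences in Zebrafish Aggression and Functional Connectivity of
    the Social Decision-Making Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sex differences in zebrafish intrasexual
    aggression and the associated neural activation of the social
    decision-making network (SDMN). Provides dyadic contest (ethogram)
    statistics with a Shapiro-Wilk-gated t/Mann-Whitney battery, principal
    component analysis of behavioral displays and a distance-based
    permutation MANOVA, per-region Kruskal-Wallis testing of pS6 activation
    counts with false discovery rate control and Dunn post hoc comparisons,
    subsample-bootstrapped signed correlation networks with density
    thresholding and excitation/inhibition subnetwork extraction,
    edge-weight distribution comparisons (Kolmogorov-Smirnov, Mann-Whitney,
    Cohen's d), and eigencentrality hub ranking with cross-sex intersection.
    A synthetic-data module generates ethogram and activation tables with
    known planted structure so every stage can be validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    igraph,
    jsonlite
Config/testthat/edition: 3
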