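Package: eaccd
Title: Ensemble Clustering of Cancer Patient Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters combinations of categorical prognostic factors (such as
    the T and N levels of the TNM staging system) by the survival experience of
    the patients they contain. An initial dissimilarity between two
    combinations is the value of a weighted two-sample survival test statistic
    (log-rank, Gehan-Wilcoxon or Tarone-Ware); a consensus dissimilarity is
    then learnt by repeatedly partitioning the combinations around random
    medoids with a randomly drawn number of clusters, counting how often two
    combinations are separated; hierarchical clustering of the learnt
    dissimilarity yields a dendrogram of prognostic groups. Also provides four
    simpler comparison approaches, a synthetic-cohort generator with planted
    outcome groups for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    survival,
    cluster,
    mclust,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
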