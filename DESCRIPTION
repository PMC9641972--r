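Package: assemblyscope
Title: Assembly Processes, Neutral Models and Co-Occurrence Networks for
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for comparing microbial communities
    across habitats: alpha and beta diversity with permutation tests,
    Levins niche breadth, the betaNTI / Raup-Crick (Bray-Curtis) null-model
    partitioning of community assembly into five ecological processes,
    the Sloan neutral community model, Mantel and partial Mantel
    environment association, and Spearman co-occurrence network analysis.
    Includes a synthetic-community generator with known assembly regimes
    (neutral, homogeneous selection, heterogeneous selection, dispersal
    limitation) so that every inference stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    igraph,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
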