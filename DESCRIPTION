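Package: tdmdscout
Title: Discovery and Scoring of Target-Directed microRNA Degradation Trigger Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterize candidate trigger sites for
    target-directed microRNA degradation (TDMD). Implements canonical seed-match
    scanning over 3' UTR and lncRNA sequences, a point-based scoring scheme for
    extensive complementarity between a target window and the microRNA 3' region
    with an optimal-configuration search, a reduced nearest-neighbor RNA-RNA
    duplex energy model as an orthogonal ranking metric, cross-species re-scoring
    of sites from multiple alignments with covariation detection, small-RNA read
    quantification by exact seed-prefix matching with within-cluster
    normalization, and a length-matched nontarget resampling statistic for
    microRNA target repression. Includes synthetic-data generators with planted
    ground truth so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
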