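Package: neps
Title: Reference Gene Selection from Digital Expression Counts by
    Permutation Scoring
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies stably expressed reference (housekeeping) genes from
    grouped digital expression libraries such as SAGE tag counts. Each gene is
    scored with a permutation statistic that standardizes the observed
    between-group difference in mean expression against its null distribution
    under random relabelling of the libraries; genes with near-zero scores and
    adequate raw abundance are nominated as references. The package also
    provides reference-gene based scale normalization of expression matrices
    (detection-call probe filtering, per-sample least-squares scaling factors)
    and stability ranking of candidate reference genes from paired qPCR Ct
    data by three metrics (dCt variance, geNorm M value, model-based
    NormFinder-style stability) aggregated by cumulative rank. Simulators for
    grouped multinomial tag-count libraries and paired Ct datasets with
    planted ground truth support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
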