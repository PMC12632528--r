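Package: phosphodia
Title: Perturbation Phosphoproteomics Analysis from DIA Search Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of data-independent-acquisition (DIA)
    proteomics and phosphoproteomics experiments with genetic perturbations:
    ingestion of long-format search-engine reports, PTM site collapse and
    Class-I localization filtering, replicate-presence filtering, median
    centering, mechanism-aware imputation of missing values (k-nearest
    neighbour and structured least-squares imputation for values missing at
    random, downshift sampling for values missing not at random),
    donor centering, time-matched differential statistics with plain and
    empirical-Bayes moderated t-tests, kinase-substrate enrichment analysis
    (KSEA), and empirical stimulation-signature derivation and scoring across
    knockout and base-edited conditions. Includes a synthetic-data generator
    that emulates the statistical structure of such experiments so that
    every stage of the pipeline can be benchmarked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
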