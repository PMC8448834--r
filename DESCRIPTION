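Package: plsassay
Title: Prognostic Liver Signature Assay: Enrichment-Based Status Calls,
    Reversal Screening and Connectivity Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a cell-culture companion assay for a prognostic
    liver gene-expression signature split into poor-prognosis and
    good-prognosis gene sets. Provides housekeeping-gene normalization for
    count matrices, a weighted Kolmogorov-Smirnov running-sum gene-set
    enrichment engine with permutation-based normalized enrichment scores
    and pooled false-discovery-rate estimates, classification of signature
    status (poor/good/indeterminate) for case-versus-reference comparisons,
    FDR-ranked drug-reversal screening, connectivity-map style scoring of
    compound perturbation profiles against an up/down query signature with
    tau percentiles, single-cell quality-control filters and viral-load
    correlation enrichment, and a seeded synthetic-data generator with
    ground-truth records for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), fgsea, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
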