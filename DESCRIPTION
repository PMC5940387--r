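Package: xtalksig
Title: Pathway Cross-Talk Gene Signatures from Expression and Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers compact diagnostic gene signatures by combining
    case/control expression profiles with protein-interaction networks and
    pathway gene sets. Differentially expressed genes (empirical-Bayes
    moderated t) seed a disease-specific subnetwork; each gene receives a
    state score W = E*D combining its expression deviation outside the
    control interval (E) with its subnetwork degree (D); enriched pathways
    of the up- and down-regulated important genes are scored per sample by
    a log-ratio of squared deviations; genes shared by two or more enriched
    pathways (cross-talk genes) are reduced to a signature by
    correlation-based feature subset selection; the signature is evaluated
    by a random-forest classifier with a random-gene-set permutation null
    and by Kaplan-Meier/log-rank survival stratification. A synthetic-data
    module generates expression matrices, scale-free-like networks,
    overlapping gene sets and clinical tables with planted truth so the
    whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    survival,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
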