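Package: elevnet
Title: Multi-Domain Soil Microbiome Diversity and Co-Occurrence Networks
    Along Elevational Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyses multi-domain (bacteria, archaea, eukaryota) soil
    amplicon OTU tables sampled along an elevational gradient: rarefaction
    and alpha-diversity estimation (Chao1, ACE, Shannon, Simpson, Good's
    coverage) with diversity-environment regressions; principal components
    analysis, redundancy analysis and adjusted-R-squared variance
    partitioning of community composition against climatic and edaphic
    covariates; compositional co-occurrence network construction by
    Spearman or SparCC correlation with signed, thresholded edges and
    per-domain topology; and domain-importance statistics based on
    correlation frequency under domain ablation and natural-connectivity
    robustness under node removal. Includes a synthetic multi-domain
    OTU-table generator with planted correlation structure for end-to-end
    validation against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
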