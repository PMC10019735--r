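Package: mopa
Title: Multi-Omics Pathway Activity Scoring via Non-Negative Tensor
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates matched mRNA, miRNA and DNA-methylation profiles into
    a gene x sample x omics tensor, decomposes it by non-negative CP
    (PARAFAC), and scores every pathway in every sample with a multi-omics
    enrichment score (mES) computed from a weighted Kolmogorov-Smirnov
    random walk over genes ranked by their latent multi-omics weight. A
    per-group omics contribution rate (OCR) apportions each pathway's
    activity across the omics layers. Downstream utilities stratify samples
    by pathway score for survival analysis, cluster samples on the score
    matrix, rank genes by group association, and export pathway-similarity
    networks. Includes synthetic-data generators with planted ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    survival,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
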