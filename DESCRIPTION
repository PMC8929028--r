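Package: hprep
Title: Reproducibility Metrics for HiChIP and PLAC-Seq Chromatin Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies reproducibility between HiChIP and PLAC-Seq
    (protein-centric chromatin conformation) samples. Non-zero bin-pair
    contact counts are normalized with a zero-truncated Poisson regression
    that absorbs effective fragment length, GC content, mappability and
    ChIP-enrichment biases; normalized contacts are arranged in an
    anchor-by-offset matrix, smoothed with a one-dimensional window, and
    compared between samples via a distance-stratified weighted Pearson
    correlation. Includes smoothing-parameter tuning by repeated
    subsampling, multinomial downsampling, pseudo-replicate generation by
    binomial splitting, similarity-based silhouette evaluation of sample
    clusterings, and a synthetic-study generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
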