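Package: spliceScore
Title: Correlation Scoring and Binding-Evidence Statistics for
    Splicing-Factor-Regulated Cassette Exons
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compares lists of differentially included cassette exons against a
    registry of splicing-factor (SF) knockdown datasets. Implements a
    permutation-based correlation query (Pearson correlation of delta-PSI on
    shared exons, directional empirical p-values and a composite confidence
    Score), a coordinate-only overlap randomization test with
    Benjamini-Hochberg correction, CLIP-peak enrichment log-ratios with
    logistic-regression tests over exon bodies and flanking 100-nt windows,
    and a sequence-level motif enrichment/depletion V statistic on exons
    extended by 200 nt. A seeded synthetic-data generator produces registries,
    annotations, CLIP peaks, genomes and motif-planted sequences with
    controlled overlap, correlation and planting rates, so the full analysis
    stack can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
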