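Package: bsascan
Title: Bulked Segregant Analysis Genome Scans with ED4 and G' Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and association analysis for bulked segregant
    sequencing (BSA-seq) of biparental crop populations. Simulates
    recombinant inbred line (RIL) populations, extreme-phenotype bulks
    and pooled sequencing allele depths; reads allele depths from VCF;
    computes per-locus Euclidean-distance (ED, ED^4) and G statistics
    between bulks with sliding-window and tricube (G') smoothing;
    calls candidate intervals from empirical-quantile thresholds with
    marker-count and effective-variant (HIGH/MODERATE impact) filters;
    intersects the two methods' intervals into consensus regions and
    reports genes per interval, together with phenotype-level sugar
    degradation metrics and candidate-gene expression screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
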