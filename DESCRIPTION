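Package: bsascan
Title: Bulked Segregant Analysis of Pooled Sequencing Data for QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seq-BSA (QTL-seq) association mapping from extreme-pool
    sequencing of biparental populations. Computes per-site SNP-index,
    delta(SNP-index) and Euclidean-distance (ED, ED^k) pool-contrast
    statistics, smooths them with a sliding-window genome scan, derives
    significance thresholds from Monte-Carlo simulation of the no-QTL null,
    calls and merges significant genomic regions, counts overlapping gene
    models and intersects regions with a marker-delimited QTL interval.
    Includes a recombinant inbred line (RIL) simulator with a planted QTL
    for power and calibration studies, descriptive phenotype statistics,
    haplotype grouping at candidate loci, and relative expression from
    qRT-PCR Ct values by the 2^-ddCt method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
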