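Package: venex
Title: Regional Gene-Expression Analysis of Muscle Cuts from RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for comparing bulk RNA-seq gene
    expression across anatomically defined muscle regions (venison cuts).
    Starting from a gene-level read-count matrix, it computes FPKM, counts
    expressed genes per region with shared and region-unique sets, filters
    to a retained analysis universe, detects region-specific genes by a
    three-criterion rule (fold dominance over other regions, a
    fraction-of-others floor, and top-quantile expression within the
    region), runs all-pairs differential expression with a transparent
    negative-binomial Wald stand-in test at FDR and fold-change
    thresholds, and compares curated gene panels (fatty-acid metabolism,
    muscle fiber structure) across regions with a Kruskal-Wallis
    stability statistic. A negative-binomial simulator with planted
    region effects and a truth table supports end-to-end parameter
    recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
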