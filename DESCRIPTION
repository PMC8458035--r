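Package: demuxbench
Title: Simulation Benchmark for Genetic Demultiplexing of Pooled Cancer scRNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-donor pooled single-cell RNA-seq allele-count data
    with cancer-specific distortions (somatic SNVs at a configurable tumor
    mutational burden, CNV-induced allele-fraction skew), applies in-silico
    doublet creation and ambient-RNA (cell debris) read redistribution,
    constructs genotype references under several strategies (matched-bulk
    calling, population SNP panels with 3' UTR filtering, SNP-array
    intersection, sites-only), and demultiplexes cells back to donors with
    either a genotype-aware binomial posterior model or a genotype-free EM
    mixture over donor allele fractions with doublet classes. Includes
    precision/recall evaluation against ground truth with donor-label
    matching, confusion tables distinguishing identifiable from same-donor
    doublets, a doublet-call purity metric, and a multiplexing cost-savings
    calculator for super-loading experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
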