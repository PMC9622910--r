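Package: methylTAD
Title: Integrative Expression-Methylation Analysis Within Topologically
    Associating Domains
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking DNA methylation to gene expression within
    topologically associating domains (TADs) in acute myeloid leukemia and
    related designs. Builds disjoint TAD partitions from called domains,
    discovers within-TAD Spearman correlations between CpG methylation and
    gene expression with genome-wide FDR control, profiles the architecture
    and retrotransposon content (MIR, Alu, L1) of correlated genes, evaluates
    DNA-binding-protein enrichment by Monte-Carlo interval shuffling,
    tests protein-protein-interaction bridging of correlated CpG-gene pairs,
    performs SAM permutation tests for differential methylation and
    expression, and projects disease expression profiles onto normal
    differentiation trajectories. A synthetic-data generator with planted
    effects supports calibration and power analysis of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: DNAMethylation, GeneExpression, Epigenetics, Transcriptomics,
    StatisticalMethod
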