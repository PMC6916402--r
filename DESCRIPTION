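Package: kelpmeth
Title: Life-Stage Methylome Analysis for Brown Algal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification and comparison of sparse cytosine DNA methylation
    across life-cycle stages of the kelp Saccharina japonica and similar
    low-methylation genomes. Implements site, fragment, component and
    whole-genome methylation-level statistics from per-cytosine bisulfite
    counts (MLmc, MLgf, MLgc, MLwg, NMLgc), lambda spike-in conversion-rate
    estimation, heterozygosity-aware site filtering, sliding-window
    differentially methylated site/region/promoter calling with an
    areaStat-style statistic, MeDIP-seq depth normalization (ARD/NARD) with
    input background removal, metaplot profiling over genomic elements,
    CpG-island and sequence-composition windows, and methylation-expression
    integration. Ships a deterministic synthetic-study generator (three
    stages, three replicates, CHH-dominated context mix, planted DMRs and
    expression coupling) so the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    vcfR,
    data.table,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, DNAMethylation, DifferentialMethylation, Software
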