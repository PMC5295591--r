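Package: compwalk
Title: Genomic Analysis of Compensatory Adaptation in Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream genomic analysis of evolve-and-resequence experiments on
    compensatory adaptation, modelled on fungicide-resistance cost compensation
    in Aspergillus nidulans. Cross-verifies variant calls from multiple callers,
    partitions variants into ancestral and derived sets, classifies derived
    mutations by genomic context and protein effect (including a
    conservative/radical amino-acid severity scheme and promoter/5'-UTR tagging),
    scans binned read depth for regions of anomalous coverage, tests GO-Slim
    functional enrichment with representation and fold filters under a
    Benjamini-Hochberg FDR, computes a pathway-subset parallelism probability,
    and compares fitness-inferred adaptive-step numbers with genomic mutation
    counts. Ships a self-consistent synthetic-cohort generator (reference, gene
    models, multi-caller VCFs, coverage tracks, GO table, step table) with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
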