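Package: bsaqtl
Title: Bulked-Segregant QTL Mapping from Pooled Whole-Genome Sequencing
Version: 0.1.0
Author: bsaqtl developers
Maintainer: bsaqtl developers <bsaqtl@example.org>
Description: A tested pipeline for mapping loci by bulked segregant analysis
    (BSA-seq) of a backcross population: screens multi-sample variant calls
    (two parents plus two phenotypic-extreme bulks) with GATK-style hard
    filters and genotype rules, computes three genome-scan statistics --
    the delta SNP-index with simulated confidence intervals, the smoothed
    G' statistic with false-discovery-rate control, and the fifth-power
    Euclidean distance with a Loess-based threshold -- calls QTL intervals
    from each scan plus their consensus, and intersects intervals with gene
    annotation. Includes a BC1 bulked-segregant simulator (Haldane map,
    categorical fertility-grade penetrance, pooled binomial read sampling)
    that emits VCF plus a ground-truth sidecar, so every stage is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    withr,
    optparse,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
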