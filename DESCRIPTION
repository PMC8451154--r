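Package: tandem5hmC
Title: Tandem Bisulfite/Oxidative-Bisulfite Analysis of 5-Hydroxymethylcytosine
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of paired bisulfite (BS) and oxidative
    bisulfite (OxBS) methylation-array data: three-state deconvolution of
    per-CpG cytosine proportions (unmethylated, 5mC, 5hmC), selection of
    highly hydroxymethylated loci, genomic-context and region-set
    enrichment with Fisher and Cochran-Mantel-Haenszel tests, per-CpG
    covariate-adjusted differential hydroxymethylation with
    Benjamini-Hochberg FDR control, recursively partitioned beta-mixture
    clustering of tumor 5hmC profiles, and Cox/Kaplan-Meier survival
    association of the resulting classes. Includes a synthetic-data
    generator that plants known proportions, differential loci, cluster
    structure and hazards, so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, data.table, S4Vectors, IRanges, GenomicRanges,
    MatrixGenerics,
    rtracklayer, survival, jsonlite
Suggests: testthat (>= 3.0.0), limma, mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: DNAMethylation, Epigenetics, DifferentialMethylation,
    Clustering, Survival
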