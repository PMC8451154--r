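# tandem5hmC

Analysis of 5-hydroxymethylcytosine (5hmC) from tandem bisulfite /
oxidative-bisulfite (BS/OxBS) methylation arrays.

Standard bisulfite conversion reads the *sum* of 5-methylcytosine (5mC)
and 5hmC at a CpG; oxidative bisulfite reads 5mC alone. Profiling both
treatments on aliquots of the same DNA therefore resolves, per CpG and
sample, the three cytosine states on the probability simplex:

    beta_BS   ~ p5mC + p5hmC
    beta_OxBS ~ p5mC
    pC + p5mC + p5hmC = 1

`tandem5hmC` implements the full downstream workflow used in tumor
5hmC studies, for researchers analyzing paired BS/OxBS beta matrices
(e.g., pediatric CNS tumor cohorts versus non-tumor tissue):

* **Deconvolution** — naive subtraction with simplex constraints
  (`deconvolveNaive`) and a per-cell beta-likelihood maximum-likelihood
  estimator (`deconvolveML`).
* **Locus selection and summaries** — per-sample medians with a Welch
  tumor/non-tumor comparison, selection of the top-5% "high-5hmC" CpGs
  by median tumor 5hmC (exactly floor(0.05 N); 37,173 on a 743,461-locus
  universe), per-CpG 5mC–5hmC Spearman correlations, and TSS-distance
  profiles.
* **Enrichment** — Fisher exact 2×2 tests against an explicit universe
  for CpG-island context, Cochran–Mantel–Haenszel tests stratified by
  Infinium probe type for regulatory features, BED region-set
  (e.g., super-enhancer) interval-join enrichment with BH q-values, gene
  scores by high-5hmC proportion, and locus-set overlap summaries.
* **Differential hydroxymethylation** — per-CpG OLS of 5hmC betas on
  group + age + sex (optional empirical-Bayes variance moderation),
  Benjamini–Hochberg FDR, and extraction of differentially
  hypo-hydroxymethylated CpGs ("DHMRs"), also stratified by tumor
  subtype.
* **Clustering and survival** — a recursively partitioned beta-mixture
  model (RPMM: per-locus beta mixtures, EM, BIC-gated recursive binary
  splits) over the most variable 5hmC loci, high/low-5hmC class
  labeling, multivariable Cox proportional-hazards models (Efron ties,
  Harrell concordance) and Kaplan–Meier/log-rank comparisons.
* **Synthetic studies** — `simulateStudy()` generates paired BS/OxBS
  matrices, CpG annotation, and sample metadata with *planted* truth
  (true proportions, DHMR set, tumor classes, hazards) so every stage is
  testable against known ground truth.

Data live in Bioconductor containers: `PairedBetaSet` and
`CytosineProportions` extend `RangedSummarizedExperiment` (assays =
beta/proportion matrices, `rowRanges` = CpG annotation, `colData` =
sample frame).

## Worked example

```r
library(tandem5hmC)

cfg   <- simConfig(n_cpg = 5000, n_tumor = 27, n_nontumor = 3,
                   n_genes = 400, seed = 1)
study <- simulateStudy(cfg)
props <- deconvolveNaive(study$paired)

sampleMedians(props)                     # per-sample medians + Welch test
sel <- selectHigh5hmC(props)             # top-5% high-5hmC CpGs
fisherContextEnrichment(sel$highLoci, rownames(props),
                        study$annotation, "island")
rows <- fitLocusModels(props, study$samples, loci = sel$highLoci)
dhmr <- extractDHMR(rows, fdr = 0.1)

tum  <- rownames(study$samples)[study$samples$group == "tumor"]
tree <- rpmmCluster(t(p5hmC(props)[topVariableLoci(props, tum, 300), tum]),
                    max_depth = 1)
lab  <- labelClusters(tree, props, study$samples)
coxFit(study$samples, "death", cluster = lab$labels)
```

This run prints:

```
median 5hmC: tumors 0.019, non-tumors 0.051 (Welch t = -30.05, p = 7.6e-23)
high-5hmC set: 250 loci, threshold median 0.059
island OR 0.048 (95% CI 0.015-0.149); open-sea OR 6.40 (4.56-8.99)
DHMRs (hypo, FDR < 0.1): 1 of 250 tested
RPMM: 2 leaves; class mean 5hmC 0.124 (high) vs 0.054 (low); Kruskal-Wallis p = 1.4e-05
Cox (death): low-5hmC HR 4.73 (95% CI 1.36-16.40), p = 0.014, concordance 0.68
log-rank p = 0.0086
```

Reading the output: tumors are globally depleted of 5hmC relative to
non-tumor tissue (medians ~2% vs ~5%); the high-5hmC set is strongly
depleted in CpG islands (odds ratio far below 1) and enriched in
open-sea regions; the linear model recovers planted differential loci
at FDR < 0.1; RPMM finds the two planted tumor classes, the low-5hmC
class having lower mean 5hmC and — in the Cox model adjusted for age,
sex and tumor type — a substantially elevated hazard of death (HR 4.7
here against a planted hazard ratio of 6.47 at n = 27).

`runPipeline(cfg, outdir)` executes the same chain end to end and
writes TSV/BED outputs plus a JSON run manifest.

## Documentation

The methods vignette (`vignettes/tandem5hmC-methods.Rmd`) describes the
measurement model, the estimators and their numerical choices, the RPMM
variant implemented here, the synthetic-data generator's design and its
limitations, and the parameters that matter with their defaults.
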