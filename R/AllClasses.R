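#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

## Central containers -------------------------------------------------------
##
## Both data classes extend SummarizedExperiment: rows are CpG loci (with a
## GRanges annotation), columns are samples (colData carries the sample
## frame: group, subtype, age, sex and survival outcomes).

#' Paired BS/OxBS beta-value container
#'
#' A \linkS4class{SummarizedExperiment} with exactly two assays,
#' \code{betaBS} (bisulfite treatment; reads 5mC + 5hmC) and
#' \code{betaOxBS} (oxidative bisulfite; reads 5mC only), over a common
#' CpG-by-sample grid. Row metadata holds the CpG annotation (genomic
#' position, island context, probe type, gene, TSS distance, regulatory
#' flags); column metadata holds the sample frame.
#'
#' @export
setClass("PairedBetaSet", contains = "RangedSummarizedExperiment")

setValidity("PairedBetaSet", function(object) {
    msg <- character()
    if (!all(c("betaBS", "betaOxBS") %in% assayNames(object)))
        msg <- c(msg, "assays must contain 'betaBS' and 'betaOxBS'")
    for (a in intersect(c("betaBS", "betaOxBS"), assayNames(object))) {
        x <- assay(object, a)
        if (anyNA(x))
            msg <- c(msg, sprintf("assay '%s' contains missing values (apply the missingness policy before construction)", a))
        else if (any(x < 0 | x > 1))
            msg <- c(msg, sprintf("assay '%s' has values outside [0, 1]", a))
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "locus IDs (rownames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Three-state cytosine proportion container
#'
#' A \linkS4class{SummarizedExperiment} with three assays \code{pC},
#' \code{p5mC} and \code{p5hmC} (unmethylated, methylated,
#' hydroxymethylated), constrained to the probability simplex in every
#' cell: all components in [0, 1] summing to 1 within 1e-9.
#'
#' @export
setClass("CytosineProportions", contains = "RangedSummarizedExperiment")

setValidity("CytosineProportions", function(object) {
    msg <- character()
    need <- c("pC", "p5mC", "p5hmC")
    if (!all(need %in% assayNames(object)))
        return("assays must contain 'pC', 'p5mC' and 'p5hmC'")
    tot <- assay(object, "pC") + assay(object, "p5mC") + assay(object, "p5hmC")
    if (anyNA(tot) || max(abs(tot - 1)) > 1e-9)
        msg <- c(msg, "proportions must sum to 1 per cell within 1e-9")
    for (a in need) {
        x <- assay(object, a)
        if (any(x < -1e-12 | x > 1 + 1e-12))
            msg <- c(msg, sprintf("assay '%s' has values outside [0, 1]", a))
    }
    if (length(msg)) msg else TRUE
})

#' Simulation ground truth
#'
#' Holds everything the synthetic-data generator planted: the true
#' per-cell cytosine proportions, the differentially hydroxymethylated
#' (DHMR) locus set, the true high-5hmC locus set, per-tumor cluster
#' labels, and the per-sample hazard rates used for survival times.
#' Downstream recovery tests compare estimates against this object.
#'
#' @slot proportions A \linkS4class{CytosineProportions} with the true values.
#' @slot dhmrLoci Character vector of planted DHMR locus IDs (subset of
#'   \code{highLociTrue}).
#' @slot highLociTrue Character vector of planted high-5hmC locus IDs.
#' @slot clusterLabels Named character vector over tumor samples with
#'   values \code{"high5hmC"} / \code{"low5hmC"}.
#' @slot hazardPerSample Named numeric vector of event rates (per year)
#'   for tumor samples.
#' @export
setClass("SimTruth",
    representation(proportions = "CytosineProportions",
                   dhmrLoci = "character",
                   highLociTrue = "character",
                   clusterLabels = "character",
                   hazardPerSample = "numeric"))

setValidity("SimTruth", function(object) {
    msg <- character()
    if (!all(object@dhmrLoci %in% object@highLociTrue))
        msg <- c(msg, "dhmrLoci must be a subset of highLociTrue")
    if (!all(object@clusterLabels %in% c("high5hmC", "low5hmC")))
        msg <- c(msg, "clusterLabels must be 'high5hmC' or 'low5hmC'")
    if (any(object@hazardPerSample <= 0))
        msg <- c(msg, "hazardPerSample must be positive")
    if (length(msg)) msg else TRUE
})

#' Recursively partitioned mixture model tree
#'
#' Binary tree produced by \code{\link{rpmmCluster}}. Each node records its
#' member samples, the fitted per-locus beta shape parameters, whether a
#' two-class split was accepted (BIC), and its children. Leaves partition
#' the sample set and define the clusters.
#'
#' @slot root The root node (a list; see \code{\link{rpmmCluster}}).
#' @slot samples Character vector of all clustered sample IDs.
#' @slot loci Character vector of the loci the model was fitted on.
#' @export
setClass("RPMMTree",
    representation(root = "list", samples = "character", loci = "character"))

setValidity("RPMMTree", function(object) {
    leaves <- rpmmLeaves(object)
    members <- unlist(lapply(leaves, `[[`, "samples"), use.names = FALSE)
    if (length(members) != length(object@samples) ||
        !setequal(members, object@samples) || anyDuplicated(members))
        return("leaves must partition the sample set")
    TRUE
})
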