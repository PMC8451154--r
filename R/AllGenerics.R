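## Constructors and accessors ------------------------------------------------

#' Construct a PairedBetaSet
#'
#' @param betaBS,betaOxBS Numeric matrices in [0, 1], loci in rows and
#'   samples in columns, identically dimnamed. \code{betaBS} is the
#'   bisulfite-treated signal (5mC + 5hmC), \code{betaOxBS} the oxidative
#'   bisulfite signal (5mC only).
#' @param rowRanges Optional \code{GRanges} CpG annotation aligned to rows.
#' @param colData Optional \code{DataFrame}/data.frame of per-sample
#'   covariates aligned to columns.
#' @param dropIncomplete Drop loci carrying any missing value in either
#'   treatment before construction (with a message giving the count).
#'   Loci with missing values are never imputed.
#' @return A \linkS4class{PairedBetaSet}.
#' @examples
#' bs  <- matrix(c(.6, .3), 1, 2, dimnames = list("cg1", c("s1", "s2")))
#' ox  <- matrix(c(.4, .5), 1, 2, dimnames = list("cg1", c("s1", "s2")))
#' PairedBetaSet(bs, ox)
#' @export
PairedBetaSet <- function(betaBS, betaOxBS, rowRanges = NULL, colData = NULL,
                          dropIncomplete = TRUE) {
    betaBS <- as.matrix(betaBS); betaOxBS <- as.matrix(betaOxBS)
    if (!identical(dim(betaBS), dim(betaOxBS)))
        stop("betaBS and betaOxBS must have identical dimensions")
    if (is.null(rownames(betaBS)))
        rownames(betaBS) <- rownames(betaOxBS) <- paste0("cg", seq_len(nrow(betaBS)))
    if (!identical(dimnames(betaBS), dimnames(betaOxBS)))
        stop("betaBS and betaOxBS must share locus and sample ordering")
    bad <- which(!stats::complete.cases(betaBS) | !stats::complete.cases(betaOxBS))
    if (length(bad)) {
        if (!dropIncomplete)
            stop(length(bad), " loci carry missing values; set dropIncomplete = TRUE")
        message("dropping ", length(bad), " loci with missing values")
        betaBS <- betaBS[-bad, , drop = FALSE]
        betaOxBS <- betaOxBS[-bad, , drop = FALSE]
        if (!is.null(rowRanges)) rowRanges <- rowRanges[-bad]
    }
    oob <- which(betaBS < 0 | betaBS > 1 | betaOxBS < 0 | betaOxBS > 1,
                 arr.ind = TRUE)
    if (nrow(oob))
        stop("beta value outside [0, 1] at locus '", rownames(betaBS)[oob[1, 1]],
             "', sample '", colnames(betaBS)[oob[1, 2]], "'")
    args <- list(assays = list(betaBS = betaBS, betaOxBS = betaOxBS),
                 rowRanges = if (is.null(rowRanges))
                     placeholderRanges(rownames(betaBS)) else rowRanges)
    if (!is.null(colData)) args$colData <- S4Vectors::DataFrame(colData)
    as(do.call(SummarizedExperiment, args), "PairedBetaSet")
}

#' Construct a CytosineProportions object
#'
#' @param pC,p5mC,p5hmC Aligned matrices of per-cell proportions of
#'   unmethylated, methylated and hydroxymethylated cytosine.
#' @param rowRanges,colData As in \code{\link{PairedBetaSet}}.
#' @return A \linkS4class{CytosineProportions}.
#' @export
CytosineProportions <- function(pC, p5mC, p5hmC, rowRanges = NULL, colData = NULL) {
    pC <- as.matrix(pC)
    if (is.null(rownames(pC)))
        rownames(pC) <- paste0("cg", seq_len(nrow(pC)))
    args <- list(assays = list(pC = pC, p5mC = as.matrix(p5mC),
                               p5hmC = as.matrix(p5hmC)),
                 rowRanges = if (is.null(rowRanges))
                     placeholderRanges(rownames(pC)) else rowRanges)
    if (!is.null(colData)) args$colData <- S4Vectors::DataFrame(colData)
    as(do.call(SummarizedExperiment, args), "CytosineProportions")
}

#' @describeIn PairedBetaSet BS-treatment beta matrix.
#' @param x A \code{PairedBetaSet}.
#' @export
betaBS <- function(x) assay(x, "betaBS")

#' @describeIn PairedBetaSet OxBS-treatment beta matrix.
#' @export
betaOxBS <- function(x) assay(x, "betaOxBS")

#' @describeIn CytosineProportions unmethylated proportion matrix.
#' @param x A \code{CytosineProportions}.
#' @export
pC <- function(x) assay(x, "pC")

#' @describeIn CytosineProportions 5-methylcytosine proportion matrix.
#' @export
p5mC <- function(x) assay(x, "p5mC")

#' @describeIn CytosineProportions 5-hydroxymethylcytosine proportion matrix.
#' @export
p5hmC <- function(x) assay(x, "p5hmC")

#' SimTruth accessors
#'
#' @param x A \linkS4class{SimTruth}.
#' @name SimTruth-accessors
NULL

#' @rdname SimTruth-accessors
#' @export
trueProportions <- function(x) x@proportions

#' @rdname SimTruth-accessors
#' @export
dhmrLoci <- function(x) x@dhmrLoci

#' @rdname SimTruth-accessors
#' @export
highLociTrue <- function(x) x@highLociTrue

#' @rdname SimTruth-accessors
#' @export
clusterLabels <- function(x) x@clusterLabels

#' @rdname SimTruth-accessors
#' @export
hazardPerSample <- function(x) x@hazardPerSample

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", nrow(object@proportions), "loci x",
        ncol(object@proportions), "samples\n")
    cat("  high-5hmC loci:", length(object@highLociTrue),
        " (DHMR:", length(object@dhmrLoci), ")\n")
    cat("  tumor classes:", sum(object@clusterLabels == "high5hmC"), "high /",
        sum(object@clusterLabels == "low5hmC"), "low 5hmC\n")
})

#' Leaves of an RPMM tree
#'
#' @param tree An \linkS4class{RPMMTree}.
#' @return A list of leaf nodes; each has elements \code{samples},
#'   \code{shape1}, \code{shape2}, \code{id}.
#' @export
rpmmLeaves <- function(tree) {
    root <- if (is(tree, "RPMMTree")) tree@root else tree
    collect <- function(node) {
        if (is.null(node$children)) return(list(node))
        c(collect(node$children[[1]]), collect(node$children[[2]]))
    }
    collect(root)
}

setMethod("show", "RPMMTree", function(object) {
    leaves <- rpmmLeaves(object)
    cat("RPMMTree:", length(object@samples), "samples,",
        length(object@loci), "loci,", length(leaves), "leaves\n")
    for (lf in leaves)
        cat("  leaf", lf$id, ":", length(lf$samples), "samples\n")
})
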