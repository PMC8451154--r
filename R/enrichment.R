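## Genomic-context and region-set enrichment ---------------------------------
##
## 2x2 machinery: query loci vs a feature over an explicit universe.
## Odds ratios are unconditional cross-product ratios with Woolf
## (log-normal) 95% CIs; p-values from Fisher's exact test (two-sided) or
## the Cochran-Mantel-Haenszel test when stratifying by probe type.
## Zero cells get a Haldane-Anscombe 0.5 correction for the OR/CI only,
## flagged in the output.

orWoolf <- function(a, b, c, d) {
    flag <- any(c(a, b, c, d) == 0)
    if (flag) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
    or <- (a * d) / (b * c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    list(or = or, ci_low = exp(log(or) - 1.96 * se),
         ci_high = exp(log(or) + 1.96 * se), continuity = flag)
}

enrichmentRow <- function(feature, a, b, c, d, p, test) {
    w <- orWoolf(a, b, c, d)
    data.frame(feature = feature, a = a, b = b, c = c, d = d,
               odds_ratio = w$or, ci_low = w$ci_low, ci_high = w$ci_high,
               p_value = p, test = test, continuity = w$continuity,
               stringsAsFactors = FALSE)
}

#' Fisher exact enrichment of a locus set in an annotation feature
#'
#' Builds the 2x2 table of (in query) x (in feature) over the universe
#' and tests association with a two-sided Fisher exact test. The feature
#' is either the name of a logical annotation column, a context level
#' (membership in \code{context == feature}), or a logical vector over
#' the universe.
#'
#' @param query Character vector of locus IDs, a subset of \code{universe}.
#' @param universe Character vector of locus IDs (the background).
#' @param ann \code{GRanges} annotation named by locus ID (used when
#'   \code{feature} is a column/level name).
#' @param feature Feature specification (see above).
#' @return One-row data.frame: feature, counts a--d, odds_ratio, ci_low,
#'   ci_high, p_value, test, continuity flag.
#' @export
fisherContextEnrichment <- function(query, universe, ann = NULL, feature) {
    if (!all(query %in% universe))
        stop("query must be a subset of the universe")
    if (length(query) == length(universe))
        stop("query equals the universe: no complement to compare against")
    inFeat <- featureIndicator(feature, universe, ann)
    if (all(inFeat) || !any(inFeat))
        stop("degenerate margin: feature covers ",
             if (all(inFeat)) "all" else "none", " of the universe")
    inQ <- universe %in% query
    a <- sum(inQ & inFeat); b <- sum(inQ & !inFeat)
    c <- sum(!inQ & inFeat); d <- sum(!inQ & !inFeat)
    p <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
    enrichmentRow(featureName(feature), a, b, c, d, p, "fisher")
}

featureIndicator <- function(feature, universe, ann) {
    if (is.logical(feature)) {
        if (length(feature) != length(universe))
            stop("logical feature must align with the universe")
        return(feature)
    }
    if (is.null(ann)) stop("annotation required for a named feature")
    ann <- ann[universe]
    md <- S4Vectors::mcols(ann)
    if (feature %in% colnames(md) && is.logical(md[[feature]]))
        return(md[[feature]])
    if (!is.null(md$context) && feature %in% levels(factor(md$context)))
        return(as.character(md$context) == feature)
    stop("unknown feature: ", feature)
}

featureName <- function(feature) if (is.character(feature)) feature else "custom"

#' Cochran-Mantel-Haenszel enrichment stratified by probe type
#'
#' As \code{\link{fisherContextEnrichment}} but stratified (default: by
#' Infinium probe design type, whose signal distributions differ), using
#' the Mantel-Haenszel common odds ratio, its CI, and the CMH chi-square
#' p-value. Strata with a zero margin are dropped with a message; with a
#' single informative stratum the common OR equals that stratum's sample
#' OR.
#'
#' @inheritParams fisherContextEnrichment
#' @param stratum Name of the annotation column to stratify by, or a
#'   vector of stratum labels over the universe.
#' @return One-row data.frame as in \code{\link{fisherContextEnrichment}},
#'   with test \code{"cmh"}.
#' @export
cmhEnrichment <- function(query, universe, ann = NULL, feature,
                          stratum = "probeType") {
    if (!all(query %in% universe))
        stop("query must be a subset of the universe")
    inFeat <- featureIndicator(feature, universe, ann)
    strat <- if (is.character(stratum) && length(stratum) == 1L) {
        if (is.null(ann)) stop("annotation required for a named stratum")
        as.character(S4Vectors::mcols(ann[universe])[[stratum]])
    } else as.character(stratum)
    inQ <- universe %in% query
    tabs <- list(); keep <- character()
    for (s in unique(strat)) {
        i <- strat == s
        t2 <- c(a = sum(inQ[i] & inFeat[i]), b = sum(inQ[i] & !inFeat[i]),
                c = sum(!inQ[i] & inFeat[i]), d = sum(!inQ[i] & !inFeat[i]))
        if ((t2["a"] + t2["b"]) == 0 || (t2["c"] + t2["d"]) == 0 ||
            (t2["a"] + t2["c"]) == 0 || (t2["b"] + t2["d"]) == 0) {
            message("dropping degenerate stratum '", s, "'")
            next
        }
        tabs[[s]] <- t2; keep <- c(keep, s)
    }
    if (!length(tabs)) stop("all strata degenerate")
    if (length(tabs) == 1L) {
        # single-stratum reduction: sample OR with Woolf CI and the
        # (uncorrected) Mantel-Haenszel chi-square p
        t2 <- tabs[[1]]
        a <- t2[["a"]]; b <- t2[["b"]]; c <- t2[["c"]]; d <- t2[["d"]]
        N <- a + b + c + d
        E <- (a + b) * (a + c) / N
        V <- (a + b) * (c + d) * (a + c) * (b + d) / (N^2 * (N - 1))
        p <- stats::pchisq((a - E)^2 / V, 1, lower.tail = FALSE)
        return(enrichmentRow(featureName(feature), a, b, c, d, p, "cmh"))
    }
    arr <- array(unlist(lapply(tabs, function(t2) c(t2["a"], t2["c"],
                                                    t2["b"], t2["d"]))),
                 dim = c(2, 2, length(tabs)))
    a <- sum(vapply(tabs, `[[`, 0, "a")); b <- sum(vapply(tabs, `[[`, 0, "b"))
    c <- sum(vapply(tabs, `[[`, 0, "c")); d <- sum(vapply(tabs, `[[`, 0, "d"))
    mh <- stats::mantelhaen.test(arr, exact = FALSE, correct = FALSE)
    row <- enrichmentRow(featureName(feature), a, b, c, d, mh$p.value, "cmh")
    row$odds_ratio <- unname(mh$estimate)
    row$ci_low <- mh$conf.int[1]; row$ci_high <- mh$conf.int[2]
    row
}

#' Region-set (BED collection) enrichment of a locus set
#'
#' A locus (single-base position) is inside a collection if it intersects
#' any of its intervals; membership is computed with a GenomicRanges
#' overlap join. Each collection gets a Fisher 2x2 against the universe,
#' and Benjamini-Hochberg q-values are computed across collections; rows
#' are sorted by q.
#'
#' @param query,universe Locus ID vectors (query a subset of universe).
#' @param ann \code{GRanges} giving locus coordinates, named by locus ID.
#' @param collections Named list of \code{GRanges} region collections
#'   (e.g., from \code{\link{readBed}}).
#' @return data.frame with one row per collection plus a \code{q_value}
#'   column.
#' @export
regionSetEnrichment <- function(query, universe, ann, collections) {
    if (is.null(names(collections)))
        names(collections) <- paste0("collection", seq_along(collections))
    annU <- ann[universe]
    chromA <- unique(as.character(GenomicRanges::seqnames(annU)))
    rows <- lapply(names(collections), function(nm) {
        gr <- collections[[nm]]
        chromB <- unique(as.character(GenomicRanges::seqnames(gr)))
        if (length(gr) > 0 && !any(chromB %in% chromA))
            stop("chromosome names in collection '", nm,
                 "' do not match the annotation: ",
                 paste(utils::head(chromB, 5), collapse = ", "))
        inFeat <- IRanges::overlapsAny(annU, gr, ignore.strand = TRUE)
        if (all(inFeat) || !any(inFeat)) {
            row <- enrichmentRow(nm, sum(universe %in% query & inFeat),
                                 sum(universe %in% query & !inFeat),
                                 sum(!(universe %in% query) & inFeat),
                                 sum(!(universe %in% query) & !inFeat),
                                 NA_real_, "fisher")
            row$continuity <- TRUE
            return(row)
        }
        fisherContextEnrichment(query, universe, feature = inFeat)
    })
    out <- do.call(rbind, rows)
    out$feature <- names(collections)
    out$q_value <- bhAdjust(ifelse(is.na(out$p_value), 1, out$p_value))
    out[order(out$q_value), , drop = FALSE]
}

#' Score genes by their proportion of high-5hmC CpGs
#'
#' For genes with at least \code{min_high} high-5hmC loci, reports the
#' percentage of the gene's measured loci that are high-5hmC, sorted
#' descending.
#'
#' @param highSet Character vector of high-5hmC locus IDs.
#' @param ann \code{GRanges} annotation with a \code{gene} column, named by
#'   locus ID.
#' @param min_high Minimum number of high-5hmC loci for a gene to be
#'   reported.
#' @return data.frame: gene, n_measured, n_high, percent_high.
#' @export
geneHigh5hmCScore <- function(highSet, ann, min_high = 10L) {
    gene <- S4Vectors::mcols(ann)$gene
    if (is.null(gene)) stop("annotation must map loci to genes")
    nMeas <- table(gene)
    nHigh <- table(gene[names(ann) %in% highSet])
    genes <- names(nHigh)[nHigh >= min_high]
    out <- data.frame(
        gene = genes,
        n_measured = as.integer(nMeas[genes]),
        n_high = as.integer(nHigh[genes]),
        stringsAsFactors = FALSE)
    out$percent_high <- 100 * out$n_high / out$n_measured
    out[order(-out$percent_high, out$gene), , drop = FALSE]
}

#' Overlap summary of two locus sets
#'
#' @param a,b Character vectors of locus IDs.
#' @return List: n_a, n_b, n_overlap, frac_a (|a n b| / |a|), frac_b.
#' @export
setOverlap <- function(a, b) {
    a <- unique(a); b <- unique(b)
    ov <- length(intersect(a, b))
    list(n_a = length(a), n_b = length(b), n_overlap = ov,
         frac_a = if (length(a)) ov / length(a) else NA_real_,
         frac_b = if (length(b)) ov / length(b) else NA_real_)
}

#' Most variable loci by standard deviation
#'
#' Per-locus sample standard deviation (n - 1 denominator) of a beta
#' matrix; selects loci with SD strictly above \code{sd_threshold}, or the
#' \code{top_n} largest SDs (deterministic locus-ID tie-break). Exactly
#' one selection rule must be given.
#'
#' @param betas Numeric matrix, loci x samples (>= 2 samples).
#' @param sd_threshold Select loci with SD > this value.
#' @param top_n Select this many loci with the largest SDs.
#' @return Character vector of selected locus IDs.
#' @export
variableCpGSet <- function(betas, sd_threshold = NULL, top_n = NULL) {
    if (!is.null(sd_threshold) && !is.null(top_n))
        stop("give either sd_threshold or top_n, not both")
    if (is.null(sd_threshold) && is.null(top_n))
        stop("give sd_threshold or top_n")
    if (ncol(betas) < 2) stop("need >= 2 samples")
    sds <- apply(betas, 1, stats::sd)
    if (!is.null(sd_threshold))
        return(rownames(betas)[sds > sd_threshold])
    if (top_n > nrow(betas)) stop("top_n exceeds the locus universe")
    rownames(betas)[order(-sds, rownames(betas))[seq_len(top_n)]]
}
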