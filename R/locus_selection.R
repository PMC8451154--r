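## Genome-wide 5hmC summaries and high-5hmC locus selection ------------------

#' Per-sample median 5hmC and 5mC, with a tumor vs non-tumor Welch test
#'
#' Computes each sample's median 5hmC and 5mC over all loci and compares
#' the per-sample medians between tumor and non-tumor groups with a
#' two-tailed Welch (unequal-variance) t test. With fewer than two
#' samples in a group, or zero variance in both groups, the test is
#' reported as degenerate (NA statistics with a reason) while the medians
#' are still returned.
#'
#' @param props A \linkS4class{CytosineProportions}.
#' @param samples Sample frame with a \code{group} column
#'   (\code{"tumor"}/\code{"nontumor"}); defaults to \code{colData(props)}.
#' @return A list with \code{medians} (data.frame: sample, group,
#'   median5hmC, median5mC) and \code{welch5hmC}, \code{welch5mC} (each a
#'   list: statistic, df, p.value, reason).
#' @export
sampleMedians <- function(props, samples = colData(props)) {
    stopifnot(is(props, "CytosineProportions"))
    samples <- as.data.frame(samples)
    med <- data.frame(
        sample = colnames(props),
        group = samples[colnames(props), "group"],
        median5hmC = MatrixGenerics::colMedians(p5hmC(props), useNames = FALSE),
        median5mC = MatrixGenerics::colMedians(p5mC(props), useNames = FALSE),
        row.names = NULL)
    welch <- function(v) {
        x <- v[med$group == "tumor"]; y <- v[med$group == "nontumor"]
        if (length(x) < 2 || length(y) < 2)
            return(list(statistic = NA_real_, df = NA_real_,
                        p.value = NA_real_, reason = "a group has < 2 samples"))
        if (stats::var(x) == 0 && stats::var(y) == 0)
            return(list(statistic = NA_real_, df = NA_real_,
                        p.value = NA_real_, reason = "zero variance in both groups"))
        tt <- stats::t.test(x, y, var.equal = FALSE)
        list(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p.value = tt$p.value, reason = NA_character_)
    }
    list(medians = med, welch5hmC = welch(med$median5hmC),
         welch5mC = welch(med$median5mC))
}

#' Select the most highly hydroxymethylated loci
#'
#' Ranks loci by their median 5hmC across tumor samples (pooled over
#' tumor types) and marks the top \code{floor(frac * N)} as high-5hmC.
#' Ties at the selection boundary are broken by lexicographic locus ID so
#' the selection is deterministic. The realized selection threshold (the
#' smallest selected median) is reported rather than hard-coded.
#'
#' @param props A \linkS4class{CytosineProportions}.
#' @param tumorIds Character vector of tumor sample IDs.
#' @param frac Fraction of the universe to select, in (0, 1).
#' @return A list with \code{summary} (data.frame: locus_id, median_5hmc_tumor,
#'   median_5mc_tumor, percentile_rank, is_high_5hmc), \code{highLoci}
#'   (selected IDs), \code{k} and \code{threshold}.
#' @export
selectHigh5hmC <- function(props, tumorIds = NULL, frac = 0.05) {
    stopifnot(is(props, "CytosineProportions"))
    checkFraction(frac, "frac")
    if (is.null(tumorIds))
        tumorIds <- colnames(props)[colData(props)$group == "tumor"]
    h <- p5hmC(props)[, tumorIds, drop = FALSE]
    m <- p5mC(props)[, tumorIds, drop = FALSE]
    medH <- MatrixGenerics::rowMedians(h, useNames = FALSE)
    medM <- MatrixGenerics::rowMedians(m, useNames = FALSE)
    N <- length(medH)
    k <- as.integer(floor(frac * N))
    if (k < 1)
        stop("floor(frac * N) = 0: enlarge the locus universe or frac")
    # descending median; lexicographic locus-ID tie-break applied only to
    # the boundary ties (sorting all IDs would dominate the runtime)
    # k-th largest via partial sort; lexicographic locus-ID tie-break
    # applied only to boundary ties (a full ID sort would dominate runtime)
    thr <- -sort.int(-medH, partial = k)[k]
    above <- which(medH > thr)
    tied <- which(medH == thr)
    tied <- tied[order(rownames(h)[tied])]
    sel <- c(above, tied[seq_len(k - length(above))])
    isHigh <- logical(N); isHigh[sel] <- TRUE
    summary <- data.frame(
        locus_id = rownames(h),
        median_5hmc_tumor = medH,
        median_5mc_tumor = medM,
        percentile_rank = data.table::frankv(medH, ties.method = "average") / N,
        is_high_5hmc = isHigh, row.names = NULL)
    list(summary = summary, highLoci = rownames(h)[sel], k = k,
         threshold = min(medH[sel]))
}

#' Per-CpG Spearman correlation between 5mC and 5hmC across tumors
#'
#' For each locus, the Spearman rank correlation between its 5mC and
#' 5hmC values across tumor samples (average ranks for ties). Loci with
#' zero variance in either variable get an undefined (NA) correlation and
#' are excluded from the returned empirical cumulative distribution, with
#' a count.
#'
#' @param props A \linkS4class{CytosineProportions}.
#' @param tumorIds Tumor sample IDs (>= 3 required).
#' @return List with \code{rho} (named numeric, NA where undefined),
#'   \code{ecdf} (an \code{ecdf} over defined values), \code{nUndefined}.
#' @export
perLocusCorrelation <- function(props, tumorIds = NULL) {
    stopifnot(is(props, "CytosineProportions"))
    if (is.null(tumorIds))
        tumorIds <- colnames(props)[colData(props)$group == "tumor"]
    if (length(tumorIds) < 3)
        stop("need >= 3 tumor samples for per-locus correlation")
    h <- p5hmC(props)[, tumorIds, drop = FALSE]
    m <- p5mC(props)[, tumorIds, drop = FALSE]
    rh <- MatrixGenerics::rowRanks(h, ties.method = "average", useNames = FALSE)
    rm_ <- MatrixGenerics::rowRanks(m, ties.method = "average", useNames = FALSE)
    rh <- rh - rowMeans(rh); rm_ <- rm_ - rowMeans(rm_)
    den <- sqrt(rowSums(rh^2) * rowSums(rm_^2))
    rho <- ifelse(den > 0, rowSums(rh * rm_) / den, NA_real_)
    names(rho) <- rownames(h)
    ok <- !is.na(rho)
    list(rho = rho, ecdf = stats::ecdf(rho[ok]), nUndefined = sum(!ok))
}

#' Median 5hmC/5mC profile around transcription start sites
#'
#' Bins loci by signed TSS distance (negative upstream on the annotated
#' strand) into half-open bins \code{[lo, hi)} spanning
#' \code{[-window_bp, +window_bp]}, and reports the per-bin median 5hmC
#' and 5mC separately for tumors and non-tumors. Empty bins give NA, not
#' zero.
#'
#' @param props A \linkS4class{CytosineProportions} whose rowRanges carry a
#'   \code{tssDist} column (or pass \code{ann}).
#' @param ann Optional \code{GRanges} annotation with \code{tssDist}.
#' @param samples Sample frame with \code{group}; defaults to colData.
#' @param window_bp Half-width of the profile window (bp).
#' @param bin_bp Bin width (bp).
#' @return data.frame: bin_lo, bin_hi, n_loci, median_5hmc_tumor,
#'   median_5mc_tumor, median_5hmc_nontumor, median_5mc_nontumor.
#' @export
tssProfile <- function(props, ann = rowRanges(props),
                       samples = colData(props),
                       window_bp = 10000L, bin_bp = 1000L) {
    stopifnot(is(props, "CytosineProportions"))
    if (is.null(ann$tssDist)) stop("annotation must provide signed 'tssDist'")
    d <- ann$tssDist
    edges <- seq(-window_bp, window_bp, by = bin_bp)
    if (edges[length(edges)] < window_bp) edges <- c(edges, window_bp)
    # half-open [lo, hi); the final edge is exclusive like the others
    binOf <- findInterval(d, edges, rightmost.closed = FALSE)
    binOf[d < -window_bp | d >= window_bp] <- NA
    grp <- as.data.frame(samples)$group
    tum <- colnames(props)[grp == "tumor"]
    non <- colnames(props)[grp == "nontumor"]
    nb <- length(edges) - 1L
    med <- function(mat, cols, b) {
        idx <- which(binOf == b)
        if (!length(idx) || !length(cols)) return(NA_real_)
        stats::median(mat[idx, cols])
    }
    h <- p5hmC(props); m <- p5mC(props)
    data.frame(
        bin_lo = edges[-length(edges)], bin_hi = edges[-1],
        n_loci = vapply(seq_len(nb), function(b) sum(binOf == b, na.rm = TRUE), 0L),
        median_5hmc_tumor = vapply(seq_len(nb), function(b) med(h, tum, b), 0),
        median_5mc_tumor = vapply(seq_len(nb), function(b) med(m, tum, b), 0),
        median_5hmc_nontumor = vapply(seq_len(nb), function(b) med(h, non, b), 0),
        median_5mc_nontumor = vapply(seq_len(nb), function(b) med(m, non, b), 0))
}

#' Total-5hmC index: high vs low group by mean 5hmC
#'
#' Each tumor's mean 5hmC over all loci; samples whose mean is strictly
#' greater than the median of the tumor means are labeled
#' \code{"high"}, the rest \code{"low"}. The threshold is reported.
#'
#' @param props A \linkS4class{CytosineProportions}.
#' @param tumorIds Tumor sample IDs (>= 2).
#' @return List with \code{means} (named numeric), \code{threshold} and
#'   \code{labels} (named character "high"/"low").
#' @export
total5hmCIndex <- function(props, tumorIds = NULL) {
    stopifnot(is(props, "CytosineProportions"))
    if (is.null(tumorIds))
        tumorIds <- colnames(props)[colData(props)$group == "tumor"]
    if (length(tumorIds) < 2) stop("need >= 2 tumor samples")
    mu <- colMeans(p5hmC(props)[, tumorIds, drop = FALSE])
    if (max(mu) == min(mu))
        stop("total-5hmC index undefined: all sample means identical")
    thr <- stats::median(mu)
    labels <- ifelse(mu > thr, "high", "low")   # strict 'greater than'
    list(means = mu, threshold = thr, labels = labels)
}
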