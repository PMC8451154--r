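## Per-CpG differential hydroxymethylation -----------------------------------
##
## Ordinary least squares of 5hmC beta values on group + covariates,
## vectorized across loci, with optional method-of-moments empirical-Bayes
## variance moderation and Benjamini-Hochberg FDR control.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone in sorted order, capped at 1).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same order as \code{p}.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] with no missing values")
    stats::p.adjust(p, method = "BH")
}

buildDesign <- function(samples, contrast = "group",
                        covariates = c("age", "sex")) {
    df <- as.data.frame(samples)
    cols <- c(contrast, covariates)
    miss <- setdiff(cols, colnames(df))
    if (length(miss))
        stop("sample frame lacks columns: ", paste(miss, collapse = ", "))
    df <- df[, cols, drop = FALSE]
    for (cl in cols)
        if (is.character(df[[cl]])) df[[cl]] <- factor(df[[cl]])
    if (contrast == "group" && "nontumor" %in% df$group)
        df$group <- stats::relevel(factor(df$group), ref = "nontumor")
    X <- stats::model.matrix(~ ., data = df)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("rank-deficient design; aliased columns: ",
             paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
                   collapse = ", "))
    X
}

# trigamma inverse by Newton iteration (for the moderated-variance prior)
trigammaInv <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2)
        y <- y + dif
        if (abs(dif / y) < 1e-8) break
    }
    y
}

#' Covariate-adjusted per-CpG differential hydroxymethylation
#'
#' Fits, for every locus, an ordinary least squares model of 5hmC beta
#' on group plus covariates (default age and sex), and reports the group
#' coefficient on the beta scale, its t statistic and two-sided p-value,
#' BH q-values across all tested loci, and separately the log2 ratio of
#' group mean 5hmC (floored at 1e-6). With \code{moderate = TRUE},
#' residual variances are shrunk toward a common prior (scaled
#' inverse-chi-square fitted by moment matching on the log scale) before
#' the t statistics are formed; coefficients are untouched by moderation.
#'
#' @param props A \linkS4class{CytosineProportions} (or a plain 5hmC beta
#'   matrix).
#' @param samples Sample frame with \code{group} and covariate columns;
#'   defaults to \code{colData(props)}.
#' @param loci Optional locus subset to test (e.g., the high-5hmC set).
#' @param covariates Covariate column names; default \code{c("age","sex")}.
#' @param moderate Apply empirical-Bayes variance moderation.
#' @return data.frame: locus_id, effect, log2_fc, t_stat, p_value,
#'   q_value, direction ("hypo" iff effect < 0), df.
#' @export
fitLocusModels <- function(props, samples = NULL, loci = NULL,
                           covariates = c("age", "sex"), moderate = FALSE) {
    if (is(props, "CytosineProportions")) {
        if (is.null(samples)) samples <- colData(props)
        Y <- p5hmC(props)
    } else Y <- as.matrix(props)
    if (is.null(samples)) stop("a sample frame is required")
    if (!is.null(loci)) Y <- Y[loci, , drop = FALSE]
    df <- as.data.frame(samples)
    X <- buildDesign(df, covariates = covariates)
    n <- nrow(X); p <- ncol(X)
    if (n <= p) stop("fewer samples (", n, ") than model parameters (", p, ")")
    Y <- Y[, rownames(df), drop = FALSE]

    XtXinv <- solve(crossprod(X))
    B <- Y %*% X %*% XtXinv                      # loci x coefficients
    R <- Y - B %*% t(X)
    dfRes <- n - p
    s2 <- rowSums(R^2) / dfRes
    gcol <- grep("^group", colnames(X))[1]
    if (is.na(gcol)) stop("no group coefficient in the design")
    cgg <- XtXinv[gcol, gcol]

    dfTot <- dfRes
    if (moderate) {
        ok <- s2 > 0
        z <- log(s2[ok])
        e <- z - digamma(dfRes / 2) + log(dfRes / 2)
        evar <- stats::var(e) - trigamma(dfRes / 2)
        if (is.na(evar) || evar <= 0) {
            d0 <- Inf
            s02 <- exp(mean(e))
        } else {
            d0 <- 2 * trigammaInv(evar)
            s02 <- exp(mean(e) + log(d0 / 2) - digamma(d0 / 2))
        }
        s2 <- if (is.infinite(d0)) rep(s02, length(s2))
              else (d0 * s02 + dfRes * s2) / (d0 + dfRes)
        dfTot <- dfRes + (if (is.infinite(d0)) 0 else d0)
    }

    tstat <- B[, gcol] / sqrt(s2 * cgg)
    tstat[s2 < 1e-24] <- NA                       # numerically zero variance
    pval <- 2 * stats::pt(-abs(tstat), df = dfTot)
    pval[is.na(pval)] <- 1                        # zero-variance loci: no evidence

    tum <- rownames(df)[df$group == "tumor"]
    non <- rownames(df)[df$group != "tumor"]
    eps <- 1e-6
    l2fc <- log2(pmax(rowMeans(Y[, tum, drop = FALSE]), eps) /
                 pmax(rowMeans(Y[, non, drop = FALSE]), eps))

    data.frame(locus_id = rownames(Y), effect = unname(B[, gcol]),
               log2_fc = unname(l2fc), t_stat = unname(tstat),
               p_value = unname(pval), q_value = bhAdjust(unname(pval)),
               direction = ifelse(B[, gcol] < 0, "hypo", "hyper"),
               df = dfTot, row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract differentially hydroxymethylated loci
#'
#' Loci with q-value strictly below \code{fdr} and the requested effect
#' direction (default \code{"hypo"}: tumor loss of 5hmC).
#'
#' @param rows Result of \code{\link{fitLocusModels}}.
#' @param fdr FDR threshold.
#' @param direction \code{"hypo"}, \code{"hyper"} or \code{"both"}.
#' @return Character vector of locus IDs.
#' @export
extractDHMR <- function(rows, fdr = 0.1, direction = "hypo") {
    keep <- rows$q_value < fdr
    if (direction != "both") keep <- keep & rows$direction == direction
    rows$locus_id[keep]
}

#' Subtype-stratified differential hydroxymethylation
#'
#' Runs \code{\link{fitLocusModels}} once per tumor subtype against the
#' non-tumor samples, on a stated locus universe. Subtypes with fewer
#' than two samples are skipped with a message.
#'
#' @param props A \linkS4class{CytosineProportions}.
#' @param samples Sample frame with \code{group} and \code{subtype}.
#' @param subtypes Subtypes to test; default all tumor subtypes present.
#' @param loci Locus universe for the tests (default all loci).
#' @param ... Passed to \code{\link{fitLocusModels}}.
#' @return Named list of result data.frames (skipped subtypes absent).
#' @export
stratifiedContrasts <- function(props, samples = colData(props),
                                subtypes = NULL, loci = NULL, ...) {
    df <- as.data.frame(samples)
    if (is.null(subtypes))
        subtypes <- unique(df$subtype[df$group == "tumor"])
    out <- list()
    for (st in subtypes) {
        ids <- rownames(df)[df$group == "tumor" & df$subtype == st]
        if (length(ids) < 2) {
            message("skipping subtype '", st, "': fewer than 2 samples")
            next
        }
        keep <- c(ids, rownames(df)[df$group != "tumor"])
        out[[st]] <- fitLocusModels(props, samples = df[keep, , drop = FALSE],
                                    loci = loci, ...)
    }
    out
}
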