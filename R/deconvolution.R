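## Three-state cytosine deconvolution ---------------------------------------
##
## The BS aliquot measures 5mC + 5hmC, the OxBS aliquot 5mC only; the
## difference estimates 5hmC. Two estimators are provided: the direct
## subtraction with non-negativity truncation, and a constrained
## maximum-likelihood estimator that models both observed betas as
## beta-distributed around their treatment means with a shared precision.

#' Naive subtraction deconvolution
#'
#' Per cell: \code{p5hmC = max(betaBS - betaOxBS, 0)},
#' \code{p5mC = min(betaOxBS, betaBS)} (the cap keeps the simplex when the
#' OxBS signal exceeds the BS signal), \code{pC} the remainder.
#'
#' @param paired A \linkS4class{PairedBetaSet}.
#' @return A \linkS4class{CytosineProportions} aligned to \code{paired}.
#' @examples
#' pb <- PairedBetaSet(matrix(0.6, 1, 1, dimnames = list("cg1", "s1")),
#'                     matrix(0.4, 1, 1, dimnames = list("cg1", "s1")))
#' p5hmC(deconvolveNaive(pb))   # 0.2
#' @export
deconvolveNaive <- function(paired) {
    stopifnot(is(paired, "PairedBetaSet"))
    bs <- betaBS(paired); ox <- betaOxBS(paired)
    h <- pmax(bs - ox, 0)
    m <- pmin(ox, bs)
    CytosineProportions(1 - m - h, m, h, rowRanges = rowRangesOrNull(paired),
                        colData = colData(paired))
}

# Per-cell constrained ML. The joint log-likelihood separates into a term
# in u = p5mC + p5hmC (mean of betaBS) and a term in v = p5mC (mean of
# betaOxBS), subject to 0 <= v <= u <= 1. Unconstrained 1-D maximizers are
# found first; if they violate v <= u the maximum lies on the boundary
# v = u, a single 1-D problem.
cellML <- function(bs, ox, precision, eps = 1e-6) {
    ll <- function(x, mu) stats::dbeta(x, clamp01(mu) * precision,
                                       (1 - clamp01(mu)) * precision, log = TRUE)
    fU <- function(u) ll(bs, u)
    fV <- function(v) ll(ox, v)
    oU <- stats::optimize(fU, c(eps, 1 - eps), maximum = TRUE, tol = 1e-9)
    oV <- stats::optimize(fV, c(eps, 1 - eps), maximum = TRUE, tol = 1e-9)
    if (oV$maximum <= oU$maximum) {
        u <- oU$maximum; v <- oV$maximum
    } else {
        ob <- stats::optimize(function(t) fU(t) + fV(t), c(eps, 1 - eps),
                              maximum = TRUE, tol = 1e-9)
        u <- v <- ob$maximum
    }
    c(p5mc = v, p5hmc = u - v)
}

#' Maximum-likelihood deconvolution
#'
#' Per cell, maximizes the joint likelihood of
#' \code{betaBS ~ Beta(mean = p5mC + p5hmC, precision)} and
#' \code{betaOxBS ~ Beta(mean = p5mC, precision)} over the probability
#' simplex. When the OxBS beta exceeds the BS beta the constrained optimum
#' has \code{p5hmC = 0} with \code{p5mC} pooled between the two readings;
#' in the high-precision limit on consistent inputs it agrees with
#' \code{\link{deconvolveNaive}}. Cells where the optimizer fails fall
#' back to the naive estimate (counted in a warning).
#'
#' @param paired A \linkS4class{PairedBetaSet}.
#' @param precision Shared beta-distribution precision (> 0); a single
#'   nuisance parameter, not estimated per locus.
#' @return A \linkS4class{CytosineProportions}.
#' @export
deconvolveML <- function(paired, precision = 200) {
    stopifnot(is(paired, "PairedBetaSet"))
    checkPositive(precision, "precision")
    bs <- betaBS(paired); ox <- betaOxBS(paired)
    h <- m <- matrix(NA_real_, nrow(bs), ncol(bs), dimnames = dimnames(bs))
    nFail <- 0L
    for (j in seq_len(ncol(bs))) {
        for (i in seq_len(nrow(bs))) {
            est <- tryCatch(cellML(bs[i, j], ox[i, j], precision),
                            error = function(e) NULL)
            if (is.null(est) || any(!is.finite(est))) {
                nFail <- nFail + 1L
                est <- c(p5mc = min(ox[i, j], bs[i, j]),
                         p5hmc = max(bs[i, j] - ox[i, j], 0))
            }
            m[i, j] <- est[["p5mc"]]; h[i, j] <- est[["p5hmc"]]
        }
    }
    if (nFail > 0)
        warning(nFail, " cells fell back to the naive estimate")
    CytosineProportions(1 - m - h, m, h, rowRanges = rowRangesOrNull(paired),
                        colData = colData(paired))
}
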