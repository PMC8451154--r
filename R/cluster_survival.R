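## RPMM clustering of 5hmC profiles and survival association -----------------
##
## The clustering model: at each node, samples are either one class or a
## two-class mixture of products of per-locus beta distributions (loci
## independent given class, class-specific shape pairs per locus). EM with
## fuzzy responsibilities and method-of-moments parameter updates; a split
## is accepted iff it improves BIC; accepted children are split
## recursively. Leaves are the clusters.

#' Top-n most variable loci across tumors
#'
#' Loci with the largest sample variance of 5hmC over tumor samples
#' (non-tumors excluded), with deterministic locus-ID tie-break.
#'
#' @param props A \linkS4class{CytosineProportions}.
#' @param tumorIds Tumor sample IDs; default from \code{colData(props)$group}.
#' @param n Number of loci to return (<= universe size).
#' @return Character vector of locus IDs.
#' @export
topVariableLoci <- function(props, tumorIds = NULL, n = 10000L) {
    stopifnot(is(props, "CytosineProportions"))
    if (is.null(tumorIds))
        tumorIds <- colnames(props)[colData(props)$group == "tumor"]
    h <- p5hmC(props)[, tumorIds, drop = FALSE]
    if (n > nrow(h)) stop("n exceeds the locus universe (", nrow(h), ")")
    v <- MatrixGenerics::rowVars(h, useNames = FALSE)
    rownames(h)[order(-v, rownames(h))[seq_len(n)]]
}

# Weighted method-of-moments beta shape estimates per locus (columns of X).
# Returns J x 2 matrix of (shape1, shape2).
betaMoM <- function(X, w) {
    w <- w / sum(w)
    m <- colSums(X * w)
    v <- colSums(sweep(X, 2, m)^2 * w)
    v <- pmin(pmax(v, 1e-8), m * (1 - m) * 0.999)
    s <- m * (1 - m) / v - 1
    cbind(shape1 = m * s, shape2 = (1 - m) * s)
}

# Row log-likelihood of each sample under per-locus beta shapes
betaRowLoglik <- function(X, sh) {
    colSums(stats::dbeta(t(X), sh[, 1], sh[, 2], log = TRUE))
}

fitOneClass <- function(X) {
    sh <- betaMoM(X, rep(1, nrow(X)))
    ll <- sum(betaRowLoglik(X, sh))
    list(shape = sh, loglik = ll, bic = -2 * ll + 2 * ncol(X) * log(nrow(X)))
}

fitTwoClass <- function(X, maxIter = 200L, tol = 1e-6) {
    n <- nrow(X); J <- ncol(X)
    # deterministic initialization: median split on the first principal
    # component (order-invariant), refined by one 2-means pass
    sc <- tryCatch(svd(scale(X, scale = FALSE), nu = 1, nv = 0)$u[, 1],
                   error = function(e) rowMeans(X))
    z <- as.integer(sc > stats::median(sc)) + 1L
    if (length(unique(z)) < 2) z[which.max(sc)] <- 3L - z[which.max(sc)]
    ctr <- rbind(colMeans(X[z == 1L, , drop = FALSE]),
                 colMeans(X[z == 2L, , drop = FALSE]))
    km <- tryCatch(stats::kmeans(X, centers = ctr), error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == 2) z <- km$cluster
    r <- cbind(as.numeric(z == 1), as.numeric(z == 2))
    r <- 0.9 * r + 0.05                       # soften hard init
    llOld <- -Inf; converged <- FALSE
    for (it in seq_len(maxIter)) {
        pi_ <- pmax(colMeans(r), 1e-8)
        sh1 <- betaMoM(X, r[, 1]); sh2 <- betaMoM(X, r[, 2])
        lf <- cbind(betaRowLoglik(X, sh1) + log(pi_[1]),
                    betaRowLoglik(X, sh2) + log(pi_[2]))
        mx <- pmax(lf[, 1], lf[, 2])
        ll <- sum(mx + log(exp(lf[, 1] - mx) + exp(lf[, 2] - mx)))
        r <- exp(lf - mx)
        r <- r / rowSums(r)
        if (is.finite(ll) && abs(ll - llOld) < tol * (abs(llOld) + 1)) {
            converged <- TRUE
            break
        }
        llOld <- ll
    }
    list(shapes = list(sh1, sh2), pi = pi_, resp = r, loglik = ll,
         bic = -2 * ll + (4 * J + 1) * log(n), converged = converged,
         assign = max.col(r))
}

#' Recursively partitioned beta-mixture clustering
#'
#' Recursive binary splitting of samples: at each node a one-class model
#' and a two-class per-locus beta mixture are fitted by EM; the split is
#' accepted iff the two-class BIC improves on the one-class BIC and both
#' children have at least \code{min_leaf} members; accepted children are
#' recursed into up to \code{max_depth}. Values are clamped to
#' (1e-6, 1 - 1e-6) before fitting. EM that fails to converge within
#' \code{maxIter} iterations leaves the node unsplit with a warning.
#'
#' @param betas Numeric matrix, samples x loci, values in (0, 1).
#' @param max_depth Maximum split depth (root = depth 0).
#' @param min_leaf Minimum samples per accepted child.
#' @param maxIter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return An \linkS4class{RPMMTree}.
#' @export
rpmmCluster <- function(betas, max_depth = 3L, min_leaf = 3L,
                        maxIter = 200L, tol = 1e-6) {
    X <- clamp01(as.matrix(betas))
    if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
    if (is.null(colnames(X))) colnames(X) <- paste0("cg", seq_len(ncol(X)))
    if (nrow(X) < 2 * min_leaf)
        stop("need at least 2 * min_leaf samples")
    grow <- function(ids, depth, label) {
        Xn <- X[ids, , drop = FALSE]
        one <- fitOneClass(Xn)
        node <- list(id = label, samples = ids, shape1 = one$shape[, 1],
                     shape2 = one$shape[, 2], loglik = one$loglik,
                     bic = one$bic, splitAccepted = FALSE, children = NULL)
        if (depth >= max_depth || length(ids) < 2 * min_leaf) return(node)
        two <- fitTwoClass(Xn, maxIter = maxIter, tol = tol)
        if (!two$converged) {
            warning("EM did not converge at node ", label, "; node retained unsplit")
            return(node)
        }
        sizes <- table(factor(two$assign, levels = 1:2))
        if (two$bic < one$bic && all(sizes >= min_leaf)) {
            node$splitAccepted <- TRUE
            node$children <- list(
                grow(ids[two$assign == 1], depth + 1, paste0(label, "L")),
                grow(ids[two$assign == 2], depth + 1, paste0(label, "R")))
        }
        node
    }
    new("RPMMTree", root = grow(rownames(X), 0L, "r"),
        samples = rownames(X), loci = colnames(X))
}

#' Label RPMM clusters as high- vs low-5hmC
#'
#' Requires a two-leaf tree; the leaf with the larger mean 5hmC over its
#' members and the clustered loci is labeled \code{"high5hmC"}. Also runs
#' a Kruskal-Wallis rank-sum test of per-sample mean 5hmC by class and,
#' when a \code{subtype} column is available, per-subtype Fisher exact
#' tests of class membership.
#'
#' @param tree An \linkS4class{RPMMTree} with exactly 2 leaves.
#' @param props The \linkS4class{CytosineProportions} the tree was built
#'   from (must contain the clustered samples and loci).
#' @param samples Optional sample frame with \code{subtype}.
#' @return List: \code{labels} (named character), \code{classMeans},
#'   \code{kruskal} (htest), \code{fisherSubtype} (data.frame or NULL).
#' @export
labelClusters <- function(tree, props, samples = colData(props)) {
    leaves <- rpmmLeaves(tree)
    if (length(leaves) != 2)
        stop("expected exactly 2 leaves, found ", length(leaves),
             "; review max_depth / locus selection")
    h <- p5hmC(props)[tree@loci, tree@samples, drop = FALSE]
    sampleMeans <- colMeans(h)
    classMeans <- vapply(leaves, function(lf) mean(sampleMeans[lf$samples]), 0)
    if (classMeans[1] == classMeans[2])
        stop("leaf mean 5hmC tie; cannot label clusters")
    lab <- c("low5hmC", "high5hmC")[order(order(classMeans))]
    labels <- stats::setNames(rep(lab, vapply(leaves, function(lf)
        length(lf$samples), 0L)),
        unlist(lapply(leaves, `[[`, "samples")))
    labels <- labels[tree@samples]
    kw <- stats::kruskal.test(sampleMeans[names(labels)],
                              factor(labels))
    fs <- NULL
    df <- as.data.frame(samples)
    if (!is.null(df$subtype)) {
        st <- df[names(labels), "subtype"]
        fs <- do.call(rbind, lapply(unique(st), function(s) {
            tab <- table(factor(st == s, levels = c(FALSE, TRUE)),
                         factor(labels, levels = c("high5hmC", "low5hmC")))
            ft <- stats::fisher.test(tab)
            data.frame(subtype = s, odds_ratio = unname(ft$estimate),
                       p_value = ft$p.value, stringsAsFactors = FALSE)
        }))
    }
    list(labels = labels, classMeans = stats::setNames(classMeans, lab),
         kruskal = kw, fisherSubtype = fs)
}

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood Cox model (Efron ties) of death or recurrence on
#' cluster class plus covariates, with Wald CIs and Harrell's concordance
#' index. Reference levels: female, glioma, high-5hmC. Subjects with
#' missing time or event are dropped with a message listing their IDs.
#' Monotone-likelihood (perfect separation) coefficients are flagged as
#' non-estimable.
#'
#' @param samples Sample frame with \code{timeDeath}/\code{eventDeath}
#'   (or Recurrence) and covariate columns.
#' @param outcome \code{"death"} or \code{"recurrence"}.
#' @param covariates Covariate columns; \code{"cluster"} refers to the
#'   \code{cluster} argument.
#' @param cluster Optional named character vector of cluster labels to
#'   attach as the \code{cluster} covariate.
#' @return List of class \code{"SurvivalFit"}: \code{table} (data.frame:
#'   term, coef, hr, ci_low, ci_high, p_value, estimable), \code{concordance},
#'   \code{nEvents}, \code{n}, and the underlying \code{coxph} fit.
#' @export
coxFit <- function(samples, outcome = c("death", "recurrence"),
                   covariates = c("age", "sex", "subtype", "cluster"),
                   cluster = NULL) {
    outcome <- match.arg(outcome)
    df <- as.data.frame(samples)
    if (!is.null(cluster)) df[names(cluster), "cluster"] <- cluster
    tcol <- if (outcome == "death") "timeDeath" else "timeRecurrence"
    ecol <- if (outcome == "death") "eventDeath" else "eventRecurrence"
    covariates <- intersect(covariates, colnames(df))
    drop <- rownames(df)[is.na(df[[tcol]]) | is.na(df[[ecol]])]
    if (length(drop)) {
        message("dropping ", length(drop), " subjects with missing follow-up: ",
                paste(utils::head(drop, 10), collapse = ", "))
        df <- df[setdiff(rownames(df), drop), , drop = FALSE]
    }
    if (sum(df[[ecol]]) < 1)
        stop("degenerate survival data: no events observed")
    if (all(df[[tcol]] <= 0))
        stop("degenerate survival data: all follow-up times are zero")
    for (cv in covariates) {
        if (cv == "sex") df$sex <- stats::relevel(factor(df$sex), "female")
        if (cv == "subtype" && "glioma" %in% df$subtype)
            df$subtype <- stats::relevel(factor(df$subtype), "glioma")
        if (cv == "cluster" && "high5hmC" %in% df$cluster)
            df$cluster <- stats::relevel(factor(df$cluster), "high5hmC")
    }
    fml <- stats::as.formula(paste0("survival::Surv(", tcol, ", ", ecol,
                                    ") ~ ", paste(covariates, collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = "efron")
    sm <- summary(fit)
    co <- sm$coefficients
    estimable <- is.finite(co[, "se(coef)"]) & co[, "se(coef)"] < 50 &
        abs(co[, "coef"]) < 50
    tab <- data.frame(term = rownames(co), coef = co[, "coef"],
                      hr = exp(co[, "coef"]),
                      ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                      ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                      p_value = co[, "Pr(>|z|)"], estimable = estimable,
                      row.names = NULL, stringsAsFactors = FALSE)
    if (any(!estimable))
        warning("monotone likelihood: ", sum(!estimable),
                " coefficient(s) flagged non-estimable")
    structure(list(table = tab, concordance = unname(sm$concordance[1]),
                   nEvents = sm$nevent, n = sm$n, fit = fit),
              class = "SurvivalFit")
}

#' @export
print.SurvivalFit <- function(x, ...) {
    cat("Cox proportional-hazards fit:", x$n, "subjects,", x$nEvents,
        "events; concordance =", round(x$concordance, 3), "\n")
    print(x$table, digits = 3)
    invisible(x)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param samples Sample frame with survival columns (see
#'   \code{\link{coxFit}}).
#' @param labels Named character vector of group labels over subjects.
#' @param outcome \code{"death"} or \code{"recurrence"}.
#' @return List: \code{fit} (a \code{survfit} with per-group KM curves),
#'   \code{chisq}, \code{p_value}, \code{nPerGroup}.
#' @export
kmLogrank <- function(samples, labels, outcome = c("death", "recurrence")) {
    outcome <- match.arg(outcome)
    df <- as.data.frame(samples)
    df <- df[names(labels), , drop = FALSE]
    df$grp <- factor(labels)
    if (any(table(df$grp) == 0)) stop("a group has no subjects")
    tcol <- if (outcome == "death") "timeDeath" else "timeRecurrence"
    ecol <- if (outcome == "death") "eventDeath" else "eventRecurrence"
    ok <- !is.na(df[[tcol]]) & !is.na(df[[ecol]])
    df <- df[ok, , drop = FALSE]
    if (sum(df[[ecol]]) < 1) stop("degenerate survival data: no events")
    fml <- stats::as.formula(paste0("survival::Surv(", tcol, ", ", ecol,
                                    ") ~ grp"))
    fit <- survival::survfit(fml, data = df)
    if (nlevels(droplevels(df$grp)) < 2) stop("need two non-empty groups")
    sd_ <- survival::survdiff(fml, data = df)
    p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
    list(fit = fit, chisq = unname(sd_$chisq), p_value = p,
         nPerGroup = table(df$grp))
}
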