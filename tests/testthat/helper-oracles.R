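# Independent reference implementations used as oracles by the tests.
# These deliberately avoid the package's own code paths.

# quadratic-time Benjamini-Hochberg reference
bhReference <- function(p) {
    n <- length(p)
    q <- numeric(n)
    for (i in seq_len(n)) {
        ri <- sum(p <= p[i])              # rank with max tie handling
        cand <- vapply(seq_len(n), function(j) {
            rj <- sum(p <= p[j])
            if (p[j] >= p[i]) n * p[j] / rj else Inf
        }, 0)
        q[i] <- min(1, min(cand))
    }
    q
}

# exhaustive grid search of the paired-beta deconvolution likelihood over
# the simplex lattice (step on each of p5mC and p5hmC), maximizing
# logBeta(bs | u) + logBeta(ox | v) with u = p5mC + p5hmC, v = p5mC <= u
gridDeconvOracle <- function(bs, ox, precision, step = 1e-3) {
    g <- seq(step, 1 - step, by = step)
    llu <- dbeta(bs, g * precision, (1 - g) * precision, log = TRUE)
    llv <- dbeta(ox, g * precision, (1 - g) * precision, log = TRUE)
    bestvIdx <- integer(length(g)); bestv <- numeric(length(g))
    best <- -Inf; bi <- 1L
    for (i in seq_along(g)) {             # v index <= u index: running max
        if (i == 1L || llv[i] > bestv[i - 1L]) {
            bestv[i] <- llv[i]; bestvIdx[i] <- i
        } else {
            bestv[i] <- bestv[i - 1L]; bestvIdx[i] <- bestvIdx[i - 1L]
        }
        tot <- llu[i] + bestv[i]
        if (tot > best) { best <- tot; bi <- i }
    }
    u <- g[bi]; v <- g[bestvIdx[bi]]
    c(p_c = 1 - u, p5mc = v, p5hmc = u - v)
}

# brute-force Cox partial likelihood (no ties) maximized by grid search
coxGridOracle <- function(time, event, x, grid = seq(-4, 4, by = 1e-4)) {
    stopifnot(!anyDuplicated(time[event == 1]))
    ll <- vapply(grid, function(b) {
        s <- 0
        for (i in which(event == 1)) {
            risk <- time >= time[i]
            s <- s + b * x[i] - log(sum(exp(b * x[risk])))
        }
        s
    }, 0)
    grid[which.max(ll)]
}

# Mantel-Haenszel common odds ratio, textbook formula
mhHand <- function(tables) {
    num <- sum(vapply(tables, function(t2)
        t2["a"] * t2["d"] / sum(t2), 0))
    den <- sum(vapply(tables, function(t2)
        t2["b"] * t2["c"] / sum(t2), 0))
    num / den
}

# small synthetic study shared across tests
smallStudy <- function(seed = 42, n_cpg = 1500, n_tumor = 12, n_nontumor = 4,
                       n_genes = 120, ...) {
    cfg <- simConfig(n_cpg = n_cpg, n_tumor = n_tumor, n_nontumor = n_nontumor,
                     n_genes = n_genes, seed = seed, ...)
    suppressWarnings(simulateStudy(cfg))
}

# two-class tumor-only proportions with beta-distributed, well separated
# class means; returns props plus truth labels
twoClassProps <- function(seed, n = 40, J = 200, nLow = round(0.4 * n),
                          muLowRange = c(0.05, 0.15),
                          muHighRange = c(0.4, 0.6), precision = 50) {
    set.seed(seed)
    isLow <- seq_len(n) %in% sample(n, nLow)
    muH <- runif(J, muHighRange[1], muHighRange[2])
    muL <- runif(J, muLowRange[1], muLowRange[2])
    mu <- matrix(muH, n, J, byrow = TRUE)
    mu[isLow, ] <- matrix(muL, sum(isLow), J, byrow = TRUE)
    X <- matrix(rbeta(n * J, mu * precision, (1 - mu) * precision), n, J,
                dimnames = list(sprintf("T%03d", seq_len(n)),
                                sprintf("cg%04d", seq_len(J))))
    h <- t(X); m <- (1 - h) * 0.6
    props <- CytosineProportions(1 - h - m, m, h,
        colData = S4Vectors::DataFrame(group = rep("tumor", n),
                                       row.names = colnames(h)))
    truth <- ifelse(isLow, "low5hmC", "high5hmC")
    names(truth) <- colnames(h)
    list(props = props, truth = truth, isLow = isLow)
}
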