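test_that("top variable loci follow the brute-force variance sort", {
    set.seed(6)
    h <- matrix(rbeta(100 * 8, 2, 10), 100, 8,
                dimnames = list(sprintf("cg%03d", 1:100), sprintf("T%02d", 1:8)))
    h[5, ] <- 0.2                                   # constant locus
    pr <- CytosineProportions(1 - h - 0.3, 0 * h + 0.3, h,
        colData = S4Vectors::DataFrame(group = rep("tumor", 8),
                                       row.names = colnames(h)))
    expect_length(topVariableLoci(pr, n = 100), 100L)
    vs <- apply(h, 1, var)
    expect_setequal(topVariableLoci(pr, n = 10),
                    names(sort(vs, decreasing = TRUE))[1:10])
    expect_false("cg005" %in% topVariableLoci(pr, n = 99))
    expect_error(topVariableLoci(pr, n = 101), "universe")
})

test_that("identical samples stay in a single leaf", {
    X <- matrix(rep(c(0.2, 0.4, 0.6), each = 10), 10, 3,
                dimnames = list(paste0("s", 1:10), paste0("cg", 1:3)))
    tree <- rpmmCluster(X)
    expect_length(rpmmLeaves(tree), 1L)
})

test_that("well-separated two-class data are recovered exactly", {
    tc <- twoClassProps(seed = 301, n = 40, J = 200)
    X <- t(p5hmC(tc$props))
    tree <- rpmmCluster(X)
    expect_length(rpmmLeaves(tree), 2L)
    lab <- labelClusters(tree, tc$props)
    expect_equal(mclust::adjustedRandIndex(lab$labels[names(tc$truth)],
                                           tc$truth), 1)
    # labels follow the class means
    expect_gt(lab$classMeans["high5hmC"], lab$classMeans["low5hmC"])
    expect_lt(lab$kruskal$p.value, 0.01)
})

test_that("one-class data reject the split in almost all seeded runs", {
    rejected <- vapply(1:100, function(r) {
        set.seed(5000 + r)
        X <- matrix(rbeta(20 * 80, 0.25 * 40, 0.75 * 40), 20, 80,
                    dimnames = list(paste0("s", 1:20), paste0("cg", 1:80)))
        length(rpmmLeaves(rpmmCluster(X))) == 1L
    }, TRUE)
    expect_gte(mean(rejected), 0.95)
})

test_that("clustering is invariant to sample and locus order", {
    tc <- twoClassProps(seed = 88, n = 30, J = 120)
    X <- t(p5hmC(tc$props))
    t1 <- rpmmCluster(X)
    set.seed(1); pi_ <- sample(nrow(X)); pj <- sample(ncol(X))
    t2 <- rpmmCluster(X[pi_, pj])
    part <- function(tr) {
        lv <- lapply(rpmmLeaves(tr), function(l) sort(l$samples))
        lv[order(vapply(lv, `[`, "", 1))]
    }
    expect_identical(part(t1), part(t2))
})

test_that("leaves always partition the sample set", {
    for (seed in c(1, 2, 3)) {
        tc <- twoClassProps(seed = seed, n = 24, J = 60)
        tree <- rpmmCluster(t(p5hmC(tc$props)))
        members <- sort(unlist(lapply(rpmmLeaves(tree), `[[`, "samples")))
        expect_identical(members, sort(tree@samples))
    }
})

test_that("labeling demands exactly two leaves", {
    X <- matrix(rep(c(0.2, 0.4, 0.6), each = 10), 10, 3,
                dimnames = list(paste0("s", 1:10), paste0("cg", 1:3)))
    tree <- rpmmCluster(X)
    pr <- CytosineProportions(1 - t(X) - 0.2, 0 * t(X) + 0.2, t(X),
        colData = S4Vectors::DataFrame(group = rep("tumor", 10),
                                       row.names = rownames(X)))
    expect_error(labelClusters(tree, pr), "exactly 2 leaves")
})

test_that("Cox coefficients match a brute-force partial-likelihood grid search", {
    time <- c(2, 5, 7, 11); event <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
    sf <- S4Vectors::DataFrame(group = rep("tumor", 4),
        cluster = ifelse(x == 1, "low5hmC", "high5hmC"),
        timeDeath = time, eventDeath = event,
        row.names = paste0("s", 1:4))
    fit <- coxFit(sf, "death", covariates = "cluster")
    oracle <- coxGridOracle(time, event, x)
    expect_lt(abs(fit$table$coef[1] - oracle), 1e-3)

    # 6-subject case with censoring
    time6 <- c(1, 3, 4, 6, 8, 9); event6 <- c(1, 0, 1, 1, 0, 1)
    x6 <- c(1, 1, 0, 1, 0, 0)
    sf6 <- S4Vectors::DataFrame(group = rep("tumor", 6),
        cluster = ifelse(x6 == 1, "low5hmC", "high5hmC"),
        timeDeath = time6, eventDeath = event6,
        row.names = paste0("s", 1:6))
    fit6 <- coxFit(sf6, "death", covariates = "cluster")
    expect_lt(abs(fit6$table$coef[1] - coxGridOracle(time6, event6, x6)), 1e-3)
})

test_that("Cox CIs cover a planted hazard ratio of 5 with censoring", {
    cover <- vapply(1:100, function(r) {
        set.seed(7000 + r)
        n <- 1000
        low <- rbinom(n, 1, 0.4)
        tt <- rexp(n, 0.1 * ifelse(low == 1, 5, 1))
        cens <- quantile(tt, 0.7)                 # ~30% censoring
        sf <- S4Vectors::DataFrame(group = rep("tumor", n),
            cluster = ifelse(low == 1, "low5hmC", "high5hmC"),
            timeDeath = pmin(tt, cens),
            eventDeath = as.integer(tt <= cens),
            row.names = paste0("s", seq_len(n)))
        fit <- coxFit(sf, "death", covariates = "cluster")
        row <- fit$table[1, ]
        row$ci_low <= 5 && row$ci_high >= 5
    }, TRUE)
    expect_gte(mean(cover), 0.90)
})

test_that("perfect separation is flagged as non-estimable", {
    sf <- S4Vectors::DataFrame(group = rep("tumor", 8),
        cluster = rep(c("low5hmC", "high5hmC"), each = 4),
        timeDeath = c(1, 2, 3, 4, 10, 11, 12, 13),
        eventDeath = c(1, 1, 1, 1, 1, 1, 1, 1),
        row.names = paste0("s", 1:8))
    w <- capture_warnings(fit <- coxFit(sf, "death", covariates = "cluster"))
    expect_true(any(grepl("monotone", w)))
    expect_false(fit$table$estimable[1])
})

test_that("log-rank behaves at the null and under complete separation", {
    # identical groups: observed = expected, p = 1
    sf <- S4Vectors::DataFrame(group = rep("tumor", 8),
        timeDeath = rep(c(1, 2, 3, 4), 2),
        eventDeath = rep(1L, 8),
        row.names = paste0("s", 1:8))
    lab <- setNames(rep(c("A", "B"), each = 4), rownames(sf))
    lab[] <- c("A", "A", "A", "A", "B", "B", "B", "B")
    res <- kmLogrank(sf, lab, "death")
    expect_equal(res$p_value, 1, tolerance = 1e-9)

    # all group-A events precede any in B
    sf2 <- S4Vectors::DataFrame(group = rep("tumor", 20),
        timeDeath = c(1:10, 101:110), eventDeath = rep(1L, 20),
        row.names = paste0("s", 1:20))
    lab2 <- setNames(rep(c("A", "B"), each = 10), rownames(sf2))
    res2 <- kmLogrank(sf2, lab2, "death")
    expect_lt(res2$p_value, 1e-4)
    expect_error(kmLogrank(sf2, lab2[1:10], "death"), "group")
})

test_that("Kaplan-Meier steps match the hand product-limit estimate", {
    # 6 subjects, one group: times 1,2+,3,4,5+,6 (+ censored)
    sf <- S4Vectors::DataFrame(group = rep("tumor", 9),
        timeDeath = c(1, 2, 3, 4, 5, 6, 2, 4, 6),
        eventDeath = c(1L, 0L, 1L, 1L, 0L, 1L, 1L, 1L, 0L),
        row.names = paste0("s", 1:9))
    lab <- setNames(rep(c("A", "B"), c(6, 3)), rownames(sf))
    res <- kmLogrank(sf, lab, "death")
    # hand product-limit for group A: S(1)=5/6, S(3)=5/6*3/4, S(4)=...*2/3,
    # S(6)=...*0; censoring at 2+ and 5+ leaves survival flat there
    hand <- c(5 / 6, 5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3,
              5 / 6 * 3 / 4 * 2 / 3, 0)
    sm <- summary(res$fit["grp=A"], times = 1:6)
    expect_equal(sm$surv, hand, tolerance = 1e-12)
})

test_that("the clustering-to-survival chain flags the planted low class", {
    hits <- vapply(1:20, function(r) {
        tc <- twoClassProps(seed = 9000 + r, n = 60, J = 120)
        tree <- rpmmCluster(t(p5hmC(tc$props)))
        if (length(rpmmLeaves(tree)) != 2) return(FALSE)
        lab <- labelClusters(tree, tc$props)
        set.seed(100 + r)
        tt <- rexp(60, 0.15 * ifelse(tc$isLow, 5, 1))
        sf <- S4Vectors::DataFrame(group = rep("tumor", 60),
            age = sample(1:18, 60, TRUE),
            sex = sample(c("female", "male"), 60, TRUE),
            timeDeath = pmin(tt, 8), eventDeath = as.integer(tt <= 8),
            row.names = colnames(p5hmC(tc$props)))
        fit <- coxFit(sf, "death", covariates = c("age", "sex", "cluster"),
                      cluster = lab$labels)
        row <- fit$table[fit$table$term == "clusterlow5hmC", ]
        nrow(row) == 1 && row$coef > 0
    }, TRUE)
    expect_gte(mean(hits), 0.9)
})
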