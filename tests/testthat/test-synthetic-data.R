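test_that("degenerate configurations produce the expected annotations", {
    cfg <- simConfig(n_cpg = 200, n_tumor = 4, n_nontumor = 2, n_genes = 10,
                     context_probs = c(island = 1, shore = 0, shelf = 0,
                                       open_sea = 0), seed = 1)
    ann <- simulateAnnotation(cfg)
    expect_true(all(ann$context == "island"))

    cfg1 <- simConfig(n_cpg = 200, n_tumor = 4, n_nontumor = 2, n_genes = 1,
                      seed = 1)
    expect_length(unique(simulateAnnotation(cfg1)$gene), 1L)
})

test_that("invalid configurations fail naming the offending field", {
    expect_error(simConfig(n_cpg = 50), "n_cpg")
    expect_error(simConfig(frac_high5hmc = 0), "frac_high5hmc")
    expect_error(simConfig(context_probs = c(island = 0.5, shore = 0.5,
                                             shelf = 0.2, open_sea = 0)),
                 "context_probs")
    expect_error(simConfig(noise_precision = -1), "noise_precision")
    expect_error(simConfig(n_tumor = 1), "n_tumor")
})

test_that("the whole generator is deterministic given the seed", {
    cfg <- simConfig(n_cpg = 300, n_tumor = 5, n_nontumor = 2, n_genes = 30,
                     seed = 77)
    a1 <- simulateAnnotation(cfg); a2 <- simulateAnnotation(cfg)
    expect_identical(a1, a2)
    t1 <- simulateTruth(cfg, a1); t2 <- simulateTruth(cfg, a1)
    expect_identical(p5hmC(trueProportions(t1)), p5hmC(trueProportions(t2)))
    expect_identical(clusterLabels(t1), clusterLabels(t2))
    o1 <- simulateObserved(t1, cfg); o2 <- simulateObserved(t1, cfg)
    expect_identical(betaBS(o1), betaBS(o2))
    expect_identical(betaOxBS(o1), betaOxBS(o2))
    s1 <- simulateSurvival(t1, cfg); s2 <- simulateSurvival(t1, cfg)
    expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("true proportions live on the simplex and respect the truth contracts", {
    for (seed in c(3, 9)) {
        st <- smallStudy(seed = seed, n_cpg = 500, n_tumor = 6, n_nontumor = 2,
                         n_genes = 40)
        pr <- trueProportions(st$truth)
        tot <- pC(pr) + p5mC(pr) + p5hmC(pr)
        expect_lt(max(abs(tot - 1)), 1e-9)
        expect_gte(min(pC(pr)), 0); expect_gte(min(p5hmC(pr)), 0)
        expect_true(all(dhmrLoci(st$truth) %in% highLociTrue(st$truth)))
    }
})

test_that("null planted effects leave DHMR loci balanced between groups", {
    cfg <- simConfig(n_cpg = 2000, n_tumor = 15, n_nontumor = 15, n_genes = 100,
                     delta_5hmc = 0, delta_5mc = 0, dhmr_frac = 0.5,
                     cluster_split = 0, tumor_depletion = 1, seed = 21)
    tr <- simulateTruth(cfg, simulateAnnotation(cfg))
    h <- p5hmC(trueProportions(tr))
    g <- colData(trueProportions(tr))$group
    d <- rowMeans(h[dhmrLoci(tr), g == "nontumor", drop = FALSE]) -
         rowMeans(h[dhmrLoci(tr), g == "tumor", drop = FALSE])
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d)), 3 * se + 1e-12)
})

test_that("tumor mean 5hmC at DHMR loci sits delta below non-tumors", {
    cfg <- simConfig(n_cpg = 10000, n_tumor = 27, n_nontumor = 3,
                     n_genes = 500, dhmr_frac = 0.2, seed = 9)
    tr <- suppressWarnings(simulateTruth(cfg, simulateAnnotation(cfg)))
    h <- p5hmC(trueProportions(tr))
    g <- colData(trueProportions(tr))$group
    d <- rowMeans(h[dhmrLoci(tr), g == "nontumor", drop = FALSE]) -
         rowMeans(h[dhmrLoci(tr), g == "tumor", drop = FALSE])
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - cfg$delta_5hmc), 3 * se)
})

test_that("increasing the planted decrement lowers tumor 5hmC at DHMRs", {
    means <- vapply(c(0.02, 0.05, 0.09), function(delta) {
        cfg <- simConfig(n_cpg = 4000, n_tumor = 20, n_nontumor = 3,
                         n_genes = 200, dhmr_frac = 0.3, delta_5hmc = delta,
                         seed = 5)
        tr <- suppressWarnings(simulateTruth(cfg, simulateAnnotation(cfg)))
        h <- p5hmC(trueProportions(tr))
        g <- colData(trueProportions(tr))$group
        mean(h[dhmrLoci(tr), g == "tumor"])
    }, 0)
    expect_true(all(diff(means) < 0))
})

test_that("cluster_split = 0 labels every tumor high-5hmC", {
    cfg <- simConfig(n_cpg = 300, n_tumor = 8, n_nontumor = 2, n_genes = 30,
                     cluster_split = 0, seed = 2)
    tr <- simulateTruth(cfg, simulateAnnotation(cfg))
    expect_true(all(clusterLabels(tr) == "high5hmC"))
})

test_that("observed betas follow the tandem measurement model", {
    cfg <- simConfig(n_cpg = 400, n_tumor = 6, n_nontumor = 2, n_genes = 40,
                     seed = 13)
    tr <- simulateTruth(cfg, simulateAnnotation(cfg))
    # noiseless limit: betas equal the treatment means exactly
    pb0 <- simulateObserved(tr, cfg, noNoise = TRUE)
    pr <- trueProportions(tr)
    expect_equal(betaBS(pb0), p5mC(pr) + p5hmC(pr))
    expect_equal(betaOxBS(pb0), p5mC(pr))
    # with noise: values in (0,1), means close to treatment means
    pb <- simulateObserved(tr, cfg)
    expect_true(all(betaBS(pb) > 0 & betaBS(pb) < 1))
    expect_lt(abs(mean(betaBS(pb) - (p5mC(pr) + p5hmC(pr)))), 0.003)
})

test_that("zero hydroxymethylation equalizes the two treatments in expectation", {
    cfg <- simConfig(n_cpg = 2000, n_tumor = 8, n_nontumor = 2, n_genes = 100,
                     seed = 31)
    tr <- simulateTruth(cfg, simulateAnnotation(cfg))
    pr <- trueProportions(tr)
    z <- matrix(0, nrow(pr), ncol(pr), dimnames = dimnames(p5hmC(pr)))
    tr0 <- new("SimTruth", proportions = CytosineProportions(
                   1 - p5mC(pr), p5mC(pr), z,
                   rowRanges = SummarizedExperiment::rowRanges(pr),
                   colData = SummarizedExperiment::colData(pr)),
               dhmrLoci = character(), highLociTrue = character(),
               clusterLabels = clusterLabels(tr),
               hazardPerSample = hazardPerSample(tr))
    pb <- simulateObserved(tr0, cfg)
    expect_lt(abs(mean(betaBS(pb)) - mean(betaOxBS(pb))), 0.002)
})

test_that("survival generation matches its configuration", {
    cfg <- simConfig(n_cpg = 150, n_tumor = 27, n_nontumor = 3, n_genes = 20,
                     seed = 4)
    tr <- simulateTruth(cfg, simulateAnnotation(cfg))
    sf <- simulateSurvival(tr, cfg)
    counts <- validateSampleFrame(sf)
    expect_identical(sum(counts), 27L)
    expect_identical(unname(counts[c("glioma", "ependymoma", "embryonal")]),
                     c(13L, 8L, 6L))
    tum <- sf[sf$group == "tumor", ]
    expect_true(all(tum$age >= 1 & tum$age <= 18))
    expect_true(all(tum$timeDeath <= cfg$censor_time))
    # administrative censoring at 0 censors everyone; Cox must refuse
    cfg0 <- simConfig(n_cpg = 150, n_tumor = 20, n_nontumor = 2, n_genes = 20,
                      censor_time = 0, seed = 4)
    tr0 <- simulateTruth(cfg0, simulateAnnotation(cfg0))
    sf0 <- simulateSurvival(tr0, cfg0)
    expect_true(all(sf0$eventDeath[sf0$group == "tumor"] == 0))
    expect_error(coxFit(sf0, "death", covariates = c("age", "sex")),
                 "degenerate")
})

test_that("planted hazard ratios are recovered by a Cox fit on the truth", {
    cfg <- simConfig(n_cpg = 150, n_tumor = 1000, n_nontumor = 1, n_genes = 20,
                     hazard_ratio_low = 5, censor_time = 1000, seed = 8)
    tr <- simulateTruth(cfg, simulateAnnotation(cfg))
    sf <- simulateSurvival(tr, cfg)
    fit <- coxFit(sf, "death", covariates = "cluster",
                  cluster = clusterLabels(tr))
    row <- fit$table[fit$table$term == "clusterlow5hmC", ]
    se <- (log(row$ci_high) - log(row$hr)) / 1.96
    expect_lt(abs(row$coef - log(5)), 3 * se)

    # null hazard ratio: estimate consistent with zero
    cfg1 <- simConfig(n_cpg = 150, n_tumor = 400, n_nontumor = 1, n_genes = 20,
                      hazard_ratio_low = 1, censor_time = 1000, seed = 8)
    tr1 <- simulateTruth(cfg1, simulateAnnotation(cfg1))
    sf1 <- simulateSurvival(tr1, cfg1)
    fit1 <- coxFit(sf1, "death", covariates = "cluster",
                   cluster = clusterLabels(tr1))
    row1 <- fit1$table[fit1$table$term == "clusterlow5hmC", ]
    se1 <- (log(row1$ci_high) - log(row1$hr)) / 1.96
    expect_lt(abs(row1$coef), 3 * se1)
})

test_that("most CpGs show negative 5mC-5hmC correlation across tumors", {
    st <- smallStudy(seed = 7, n_cpg = 2000, n_tumor = 27, n_nontumor = 3,
                     n_genes = 150)
    rho <- perLocusCorrelation(deconvolveNaive(st$paired))
    expect_gt(mean(rho$rho < 0, na.rm = TRUE), 0.5)
})
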