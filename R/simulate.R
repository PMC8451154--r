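## Synthetic tandem BS/OxBS study generator ---------------------------------
##
## Emulates the structure of a pediatric CNS tumor 5hmC study: a small
## fraction of CpGs carry appreciable hydroxymethylation, tumors are
## globally hypohydroxymethylated relative to non-tumor tissue, a planted
## subset of high-5hmC loci loses 5hmC and gains 5mC specifically in
## tumors (DHMRs), tumors split into a high- and a low-5hmC class, and the
## low class carries an elevated event hazard. All planted quantities are
## returned in a SimTruth so recovery can be scored exactly.

#' Simulation configuration
#'
#' Builds and validates the configuration driving the synthetic-data
#' generator. Defaults emulate the study design the package targets:
#' 27 tumors vs 3 non-tumor controls, ~5\% of loci with appreciable 5hmC,
#' 5hmC enriched in open-sea/enhancer contexts and depleted in CpG
#' islands, tumor-specific 5hmC loss with 5mC gain at DHMRs, a low-5hmC
#' tumor class with elevated hazard.
#'
#' @param n_cpg Number of CpG loci (>= 100).
#' @param n_tumor,n_nontumor Sample sizes (tumors >= 2, non-tumors >= 1).
#' @param frac_high5hmc Fraction of loci planted as high-5hmC.
#' @param context_probs Named probabilities over
#'   \code{c("island","shore","shelf","open_sea")}; must sum to 1.
#' @param enhancer_prob_by_context Named per-context enhancer probability.
#' @param n_genes Number of genes loci are clustered into.
#' @param tss_window_bp Half-width (bp) of the TSS window loci are placed in.
#' @param dhmr_frac Fraction of high-5hmC loci planted as differential.
#' @param delta_5hmc Mean tumor 5hmC decrement at DHMR loci (beta scale).
#' @param delta_5mc Mean tumor 5mC increment at DHMR loci (beta scale).
#' @param noise_precision Beta-distribution precision of observed betas.
#' @param cluster_split Fraction of tumors in the low-5hmC class (may be 0).
#' @param hazard_ratio_low Multiplicative hazard for the low-5hmC class.
#' @param baseline_hazard Event rate (per year) for the high-5hmC class.
#' @param censor_time Administrative censoring time (years).
#' @param tumor_depletion Multiplier (< 1) on 5hmC at non-high loci in all
#'   tumors; drives the global tumor hypohydroxymethylation. Set to 1 for
#'   a global null.
#' @param low_class_scale Additional 5hmC multiplier (< 1) applied to
#'   non-DHMR loci of low-class tumors.
#' @param seed Master RNG seed; all stages derive their own seed from it.
#' @return A validated \code{SimConfig} list.
#' @export
simConfig <- function(n_cpg = 50000L, n_tumor = 27L, n_nontumor = 3L,
                      frac_high5hmc = 0.05,
                      context_probs = c(island = 0.20, shore = 0.24,
                                        shelf = 0.10, open_sea = 0.46),
                      enhancer_prob_by_context = c(island = 0.05, shore = 0.10,
                                                   shelf = 0.15, open_sea = 0.25),
                      n_genes = 2000L, tss_window_bp = 10000L,
                      dhmr_frac = 0.02, delta_5hmc = 0.05, delta_5mc = 0.05,
                      noise_precision = 200, cluster_split = 0.4,
                      hazard_ratio_low = 6.47, baseline_hazard = 0.08,
                      censor_time = 10, tumor_depletion = 0.35,
                      low_class_scale = 0.4, seed = 1L) {
    cfg <- list(n_cpg = as.integer(n_cpg), n_tumor = as.integer(n_tumor),
                n_nontumor = as.integer(n_nontumor),
                frac_high5hmc = frac_high5hmc, context_probs = context_probs,
                enhancer_prob_by_context = enhancer_prob_by_context,
                n_genes = as.integer(n_genes),
                tss_window_bp = as.integer(tss_window_bp),
                dhmr_frac = dhmr_frac, delta_5hmc = delta_5hmc,
                delta_5mc = delta_5mc, noise_precision = noise_precision,
                cluster_split = cluster_split,
                hazard_ratio_low = hazard_ratio_low,
                baseline_hazard = baseline_hazard, censor_time = censor_time,
                tumor_depletion = tumor_depletion,
                low_class_scale = low_class_scale, seed = as.integer(seed))
    validateSimConfig(cfg)
    structure(cfg, class = "SimConfig")
}

validateSimConfig <- function(cfg) {
    checkCount(cfg$n_cpg, "n_cpg", min = 100L)
    checkCount(cfg$n_tumor, "n_tumor", min = 2L)
    checkCount(cfg$n_nontumor, "n_nontumor", min = 1L)
    checkCount(cfg$n_genes, "n_genes")
    checkCount(cfg$tss_window_bp, "tss_window_bp")
    checkFraction(cfg$frac_high5hmc, "frac_high5hmc")
    ctx <- c("island", "shore", "shelf", "open_sea")
    if (!identical(sort(names(cfg$context_probs)), sort(ctx)) ||
        any(cfg$context_probs < 0) ||
        abs(sum(cfg$context_probs) - 1) > 1e-12)
        stop("configuration error: 'context_probs' must be a probability ",
             "distribution over island/shore/shelf/open_sea summing to 1",
             call. = FALSE)
    if (!all(ctx %in% names(cfg$enhancer_prob_by_context)) ||
        any(cfg$enhancer_prob_by_context < 0 | cfg$enhancer_prob_by_context > 1))
        stop("configuration error: 'enhancer_prob_by_context' must give a ",
             "probability for each context", call. = FALSE)
    for (f in c("dhmr_frac", "cluster_split"))
        if (cfg[[f]] < 0 || cfg[[f]] >= 1)
            stop("configuration error: '", f, "' must be in [0, 1)", call. = FALSE)
    for (f in c("delta_5hmc", "delta_5mc"))
        if (cfg[[f]] < 0 || cfg[[f]] > 1)
            stop("configuration error: '", f, "' must be in [0, 1]", call. = FALSE)
    if (!(is.numeric(cfg$noise_precision) && cfg$noise_precision > 0))
        stop("configuration error: 'noise_precision' must be positive",
             call. = FALSE)
    checkPositive(cfg$hazard_ratio_low, "hazard_ratio_low")
    checkPositive(cfg$baseline_hazard, "baseline_hazard")
    if (cfg$censor_time < 0)
        stop("configuration error: 'censor_time' must be >= 0", call. = FALSE)
    for (f in c("tumor_depletion", "low_class_scale"))
        if (cfg[[f]] <= 0 || cfg[[f]] > 1)
            stop("configuration error: '", f, "' must be in (0, 1]", call. = FALSE)
    invisible(cfg)
}

#' Simulate a CpG annotation
#'
#' Loci are clustered into genes of varying size; each gene gets a
#' chromosome, strand and TSS, and its loci are placed within
#' \code{tss_window_bp} of the TSS. Island context is drawn from
#' \code{context_probs}; probe type I is more frequent in islands, as on
#' the array designs this emulates. Signed TSS distance is negative
#' upstream of the TSS on the annotated strand.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return A \code{GRanges} of length \code{n_cpg}, named by locus ID, with
#'   metadata columns \code{context}, \code{probeType}, \code{gene},
#'   \code{tssDist}, \code{enhancer}, \code{tfbs}, \code{utr5}.
#' @export
simulateAnnotation <- function(cfg) {
    validateSimConfig(cfg)
    set.seed(deriveSeed(cfg$seed, "annotation"))
    n <- cfg$n_cpg
    ng <- min(cfg$n_genes, n)

    # genes of varying CpG count (>= 1 each)
    w <- stats::rgamma(ng, shape = 1.2)
    sizes <- 1L + as.integer(stats::rmultinom(1, n - ng, prob = w))
    gene <- rep(sprintf("g%05d", seq_len(ng)), sizes)

    chromGene <- sample(paste0("chr", 1:22), ng, replace = TRUE)
    strandGene <- sample(c("+", "-"), ng, replace = TRUE)
    tssGene <- sample.int(2e8, ng, replace = TRUE) + 1e6

    offset <- sample.int(2L * cfg$tss_window_bp + 1L, n, replace = TRUE) -
        cfg$tss_window_bp - 1L
    pos <- tssGene[rep(seq_len(ng), sizes)] + offset
    strand <- strandGene[rep(seq_len(ng), sizes)]
    tssDist <- ifelse(strand == "+", offset, -offset)

    ctx <- sample(names(cfg$context_probs), n, replace = TRUE,
                  prob = cfg$context_probs)
    typeIProb <- c(island = 0.60, shore = 0.35, shelf = 0.20, open_sea = 0.15)
    probeType <- ifelse(stats::runif(n) < typeIProb[ctx], "I", "II")
    enhancer <- stats::runif(n) < cfg$enhancer_prob_by_context[ctx]
    tfbs <- stats::runif(n) < 0.15
    utr5 <- stats::runif(n) < 0.10

    gr <- GenomicRanges::GRanges(
        seqnames = chromGene[rep(seq_len(ng), sizes)],
        ranges = IRanges::IRanges(start = pos, width = 1L),
        strand = strand,
        context = factor(ctx, levels = names(cfg$context_probs)),
        probeType = probeType, gene = gene, tssDist = as.integer(tssDist),
        enhancer = enhancer, tfbs = tfbs, utr5 = utr5)
    names(gr) <- sprintf("cg%07d", seq_len(n))
    gr
}

#' Simulate ground-truth cytosine proportions
#'
#' Plants the study's effect structure on top of the annotation: high-5hmC
#' loci (preferentially open-sea/enhancer) receive elevated baseline 5hmC;
#' a DHMR subset receives a tumor-specific 5hmC decrement and 5mC
#' increment; all tumors lose 5hmC at non-high loci
#' (\code{tumor_depletion}); low-class tumors additionally scale 5hmC at
#' non-DHMR loci. Per-cell values jitter the locus archetype on the logit
#' scale, with the methylated and hydroxymethylated fractions sharing a
#' total-modification budget (which induces the predominantly negative
#' per-CpG 5mC--5hmC correlation seen on such arrays). Cells pushed below
#' zero by the planted decrements are clipped and renormalized, with a
#' warning giving the count.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param ann Annotation from \code{\link{simulateAnnotation}} with the
#'   same \code{n_cpg}.
#' @return A \linkS4class{SimTruth}.
#' @export
simulateTruth <- function(cfg, ann) {
    validateSimConfig(cfg)
    if (length(ann) != cfg$n_cpg)
        stop("annotation length does not match cfg$n_cpg")
    set.seed(deriveSeed(cfg$seed, "truth"))
    n <- cfg$n_cpg
    loci <- names(ann)
    nT <- cfg$n_tumor; nN <- cfg$n_nontumor
    samp <- c(sprintf("T%03d", seq_len(nT)), sprintf("N%03d", seq_len(nN)))
    group <- rep(c("tumor", "nontumor"), c(nT, nN))

    # planted high-5hmC loci, weighted toward open sea / enhancers
    k <- max(1L, floor(cfg$frac_high5hmc * n))
    ctxW <- c(island = 0.15, shore = 0.7, shelf = 1.2, open_sea = 3.0)
    wHigh <- ctxW[as.character(ann$context)] * (1 + 2 * ann$enhancer)
    highIdx <- sample.int(n, k, prob = wHigh)
    isHigh <- logical(n); isHigh[highIdx] <- TRUE
    m <- floor(cfg$dhmr_frac * k)
    dhmrIdx <- if (m > 0) sample(highIdx, m) else integer()
    isDhmr <- logical(n); isDhmr[dhmrIdx] <- TRUE

    # locus archetypes: 5mC depends on island context, 5hmC on high status
    mBase <- numeric(n)
    ctx <- as.character(ann$context)
    mBase[ctx == "island"] <- stats::rbeta(sum(ctx == "island"), 1.5, 12)
    mBase[ctx == "shore"]  <- stats::rbeta(sum(ctx == "shore"), 4, 4)
    mBase[ctx %in% c("shelf", "open_sea")] <-
        stats::rbeta(sum(ctx %in% c("shelf", "open_sea")), 8, 4)
    hBase <- numeric(n)
    hBase[isHigh] <- 0.09 + 0.12 * stats::rbeta(k, 2, 3)
    hBase[!isHigh] <- stats::rbeta(n - k, 5, 100)
    M <- pmin(mBase + hBase, 0.97)
    phi <- hBase / M

    nAll <- nT + nN
    Mcell <- matrix(jitterLogit(rep(M, nAll), 0.25), n, nAll)
    phiCell <- matrix(jitterLogit(rep(phi, nAll), 0.35), n, nAll)
    p5hmc <- Mcell * phiCell
    p5mc <- Mcell * (1 - phiCell)

    # tumor classes
    nLow <- round(cfg$cluster_split * nT)
    lowSamp <- sample.int(nT, nLow)
    classLab <- rep("high5hmC", nT); classLab[lowSamp] <- "low5hmC"
    names(classLab) <- samp[seq_len(nT)]

    tumorCols <- seq_len(nT)
    # global tumor hypohydroxymethylation at non-high loci
    p5hmc[!isHigh, tumorCols] <- p5hmc[!isHigh, tumorCols] * cfg$tumor_depletion
    # low-class scaling at non-DHMR loci
    if (nLow > 0)
        p5hmc[!isDhmr, lowSamp] <- p5hmc[!isDhmr, lowSamp] * cfg$low_class_scale
    # planted DHMR effects in tumors
    if (m > 0) {
        p5hmc[dhmrIdx, tumorCols] <- p5hmc[dhmrIdx, tumorCols] - cfg$delta_5hmc
        p5mc[dhmrIdx, tumorCols] <- p5mc[dhmrIdx, tumorCols] + cfg$delta_5mc
    }

    nClip <- sum(p5hmc < 0) + sum(p5mc > 1)
    p5hmc[p5hmc < 0] <- 0
    p5mc[p5mc > 1] <- 1
    pc <- 1 - p5mc - p5hmc
    neg <- pc < 0
    if (any(neg)) {
        nClip <- nClip + sum(neg)
        tot <- p5mc + p5hmc
        p5mc[neg] <- p5mc[neg] / tot[neg]
        p5hmc[neg] <- p5hmc[neg] / tot[neg]
        pc[neg] <- 0
    }
    if (nClip > 0)
        warning(nClip, " cells clipped to the simplex after planted effects")

    dimnames(pc) <- dimnames(p5mc) <- dimnames(p5hmc) <- list(loci, samp)
    props <- CytosineProportions(pc, p5mc, p5hmc, rowRanges = ann,
                                 colData = S4Vectors::DataFrame(
                                     group = group, row.names = samp))
    haz <- cfg$baseline_hazard *
        ifelse(classLab == "low5hmC", cfg$hazard_ratio_low, 1)
    new("SimTruth", proportions = props, dhmrLoci = loci[dhmrIdx],
        highLociTrue = loci[highIdx], clusterLabels = classLab,
        hazardPerSample = haz)
}

#' Simulate observed BS/OxBS beta values
#'
#' Inverts the tandem measurement model: the BS aliquot reads
#' 5mC + 5hmC, the OxBS aliquot reads 5mC only. Observed betas are drawn
#' from beta distributions with those means and a common precision
#' \code{noise_precision} (independent draws per treatment). Means of
#' exactly 0 or 1 are nudged by 1e-6 before sampling. With
#' \code{noNoise = TRUE} (or infinite precision) the observed betas equal
#' the means exactly.
#'
#' @param truth A \linkS4class{SimTruth}.
#' @param cfg The \code{\link{simConfig}} used to build it.
#' @param noNoise Skip the beta noise entirely (infinite-precision limit).
#' @return A \linkS4class{PairedBetaSet}.
#' @export
simulateObserved <- function(truth, cfg, noNoise = FALSE) {
    validateSimConfig(cfg)
    props <- trueProportions(truth)
    muBS <- p5mC(props) + p5hmC(props)
    muOx <- p5mC(props)
    if (noNoise || is.infinite(cfg$noise_precision)) {
        bs <- muBS; ox <- muOx
    } else {
        set.seed(deriveSeed(cfg$seed, "observed"))
        prec <- cfg$noise_precision
        draw <- function(mu) {
            mu <- clamp01(mu)          # nudge exact 0/1 means
            matrix(stats::rbeta(length(mu), mu * prec, (1 - mu) * prec),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
        }
        bs <- draw(muBS); ox <- draw(muOx)
    }
    PairedBetaSet(bs, ox, rowRanges = rowRangesOrNull(props),
                  colData = colData(props))
}

#' Simulate sample metadata and survival outcomes
#'
#' Event times for death and recurrence are drawn independently from
#' exponential distributions with rate
#' \code{baseline_hazard * hazard_ratio_low^{[low class]}}, with
#' administrative censoring at \code{censor_time}. Ages are integer
#' uniform on 1--18, sex Bernoulli(0.5). For a 27-tumor cohort, subtypes
#' are apportioned 13 gliomas, 8 ependymomas and 6 embryonal tumors (the
#' cohort structure the generator emulates); other sizes use the same
#' proportions by largest-remainder apportionment.
#'
#' @param truth A \linkS4class{SimTruth} (provides class labels).
#' @param cfg The matching \code{\link{simConfig}}.
#' @return A \code{DataFrame} (one row per sample) with columns
#'   \code{group}, \code{subtype}, \code{age}, \code{sex},
#'   \code{cluster_true}, \code{timeDeath}, \code{eventDeath},
#'   \code{timeRecurrence}, \code{eventRecurrence}.
#' @export
simulateSurvival <- function(truth, cfg) {
    validateSimConfig(cfg)
    set.seed(deriveSeed(cfg$seed, "survival"))
    props <- trueProportions(truth)
    samp <- colnames(props)
    group <- colData(props)$group
    nT <- sum(group == "tumor"); nAll <- length(samp)

    subtypeProps <- c(glioma = 13, ependymoma = 8, embryonal = 6) / 27
    counts <- floor(subtypeProps * nT)
    rem <- nT - sum(counts)
    if (rem > 0) {
        frac <- subtypeProps * nT - counts
        counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
            counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
    }
    subtype <- c(sample(rep(names(counts), counts)),
                 rep("non-tumor", nAll - nT))

    haz <- hazardPerSample(truth)
    tDeath <- stats::rexp(nT, haz)
    tRec <- stats::rexp(nT, haz)
    cens <- cfg$censor_time
    pad <- function(x) c(x, rep(NA_real_, nAll - nT))
    S4Vectors::DataFrame(
        group = group, subtype = subtype,
        age = sample(1:18, nAll, replace = TRUE),
        sex = sample(c("female", "male"), nAll, replace = TRUE),
        cluster_true = c(clusterLabels(truth), rep(NA_character_, nAll - nT)),
        timeDeath = pad(pmin(tDeath, cens)),
        eventDeath = pad(as.integer(tDeath <= cens)),
        timeRecurrence = pad(pmin(tRec, cens)),
        eventRecurrence = pad(as.integer(tRec <= cens)),
        row.names = samp)
}

#' Simulate a complete tandem BS/OxBS study
#'
#' Runs annotation, truth, observed-beta and survival generation in order
#' and attaches the sample metadata to the paired beta set.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param noNoise Passed to \code{\link{simulateObserved}}.
#' @return A list with elements \code{config}, \code{annotation},
#'   \code{truth}, \code{paired} (a \linkS4class{PairedBetaSet} with sample
#'   metadata in its \code{colData}) and \code{samples}.
#' @examples
#' study <- simulateStudy(simConfig(n_cpg = 500, n_tumor = 6, n_nontumor = 2))
#' study$paired
#' @export
simulateStudy <- function(cfg, noNoise = FALSE) {
    ann <- simulateAnnotation(cfg)
    truth <- simulateTruth(cfg, ann)
    paired <- simulateObserved(truth, cfg, noNoise = noNoise)
    samples <- simulateSurvival(truth, cfg)
    colData(paired) <- samples
    list(config = cfg, annotation = ann, truth = truth, paired = paired,
         samples = samples)
}

#' Validate a sample frame
#'
#' Checks the bookkeeping of a sample metadata table: groups are known,
#' subtype counts within the tumor group sum to the tumor-group size,
#' ages positive, survival columns consistent (event implies finite
#' time). Returns the tumor subtype counts invisibly.
#'
#' @param samples A sample frame as produced by
#'   \code{\link{simulateSurvival}} (or read from file).
#' @return (invisibly) named integer vector of tumor subtype counts.
#' @export
validateSampleFrame <- function(samples) {
    samples <- as.data.frame(samples)
    if (!all(c("group", "subtype", "age", "sex") %in% colnames(samples)))
        stop("sample frame must have group, subtype, age, sex columns")
    if (!all(samples$group %in% c("tumor", "nontumor")))
        stop("unknown group labels: ",
             paste(setdiff(samples$group, c("tumor", "nontumor")), collapse = ", "))
    tum <- samples[samples$group == "tumor", ]
    counts <- table(tum$subtype)
    if (sum(counts) != nrow(tum))
        stop("tumor subtype counts do not sum to the tumor-group size")
    if (any(samples$age <= 0)) stop("ages must be positive")
    for (oc in c("Death", "Recurrence")) {
        tcol <- paste0("time", oc); ecol <- paste0("event", oc)
        if (tcol %in% colnames(samples)) {
            ev <- samples[[ecol]]; tt <- samples[[tcol]]
            if (any(!is.na(ev) & ev == 1 & (is.na(tt) | tt < 0)))
                stop("event indicated without a valid ", tcol)
        }
    }
    invisible(stats::setNames(as.integer(counts), names(counts)))
}
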