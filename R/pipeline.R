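## End-to-end orchestration and standard-format IO ---------------------------

#' Read a BED file as genomic intervals
#'
#' Validates BED3+ records (comment, track and browser lines tolerated)
#' and imports them via rtracklayer. BED coordinates are 0-based
#' half-open on disk; the returned \code{GRanges} uses the usual 1-based
#' closed convention, so \code{start(gr) - 1} / \code{end(gr)} recover
#' the on-disk interval.
#'
#' @param path Path to a BED file.
#' @return A \code{GRanges}, sorted within chromosomes.
#' @export
readBed <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    for (i in which(keep)) {
        f <- strsplit(lines[i], "\t")[[1]]
        if (length(f) < 3)
            stop("BED parse error at line ", i, ": fewer than 3 fields")
        s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
        if (is.na(s) || is.na(e) || s != round(s) || e != round(e))
            stop("BED parse error at line ", i, ": non-integer coordinates")
        if (s >= e)
            stop("BED parse error at line ", i, ": start >= end")
    }
    if (!any(keep))
        return(GenomicRanges::GRanges())
    clean <- tempfile(fileext = ".bed")   # strip header/track lines for import
    on.exit(unlink(clean))
    writeLines(lines[keep], clean)
    gr <- rtracklayer::import(clean, format = "BED")
    GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write genomic intervals (or CpG loci) as BED
#'
#' @param gr A \code{GRanges}; width-1 CpG loci become single-base BED
#'   records. Conversion to BED's 0-based half-open coordinates is
#'   handled by rtracklayer.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Write a locus subset as BED (e.g., for external enrichment tools)
#'
#' @param ann \code{GRanges} annotation named by locus ID.
#' @param loci Locus IDs to export.
#' @param path Output path.
#' @export
writeLociBed <- function(ann, loci, path) {
    gr <- ann[loci]
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = loci)
    writeBed(gr, path)
}

writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

matrixTsv <- function(m, path, idCol = "locus_id") {
    df <- data.frame(rownames(m), m, check.names = FALSE)
    colnames(df)[1] <- idCol
    writeTsv(df, path)
}

#' Run the full tandem BS/OxBS analysis pipeline
#'
#' Executes simulate (or ingest) - deconvolve - summarize/select -
#' enrich - differential - cluster/survival in order, writing per-stage
#' TSV/BED outputs, a JSON run manifest (package version, seed, parameter
#' hash, row counts) and a human-readable summary. Any stage error aborts
#' with the stage name; outputs of completed stages persist.
#'
#' @param cfg A \code{\link{simConfig}} describing the synthetic study, or
#'   a list with elements \code{paired} (a \linkS4class{PairedBetaSet}
#'   whose colData is the sample frame) and \code{annotation} for
#'   pre-existing data.
#' @param outdir Output directory (created if needed).
#' @param frac High-5hmC selection fraction.
#' @param fdr FDR threshold for DHMR extraction.
#' @param top_n Loci for RPMM clustering (capped at the universe size).
#' @param min_high Minimum high-5hmC CpGs for the gene score table.
#' @param deconvMethod \code{"naive"} or \code{"ml"}.
#' @param regionCollections Optional named list of \code{GRanges} for
#'   region-set enrichment (defaults to none; context/regulatory-flag
#'   enrichment always runs).
#' @return The run manifest (a list), invisibly written to
#'   \code{manifest.json}.
#' @export
runPipeline <- function(cfg, outdir, frac = 0.05, fdr = 0.1, top_n = 10000L,
                        min_high = 10L, deconvMethod = c("naive", "ml"),
                        regionCollections = NULL) {
    deconvMethod <- match.arg(deconvMethod)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    params <- list(frac = frac, fdr = fdr, top_n = top_n, min_high = min_high,
                   deconvMethod = deconvMethod)
    counts <- list()

    ## stage: simulate / ingest
    dat <- stage("simulate", {
        if (inherits(cfg, "SimConfig")) simulateStudy(cfg)
        else {
            if (is.null(cfg$paired) || is.null(cfg$annotation))
                stop("cfg must be a SimConfig or carry 'paired' and 'annotation'")
            cfg
        }
    })
    paired <- dat$paired; ann <- dat$annotation
    samples <- colData(paired)
    validateSampleFrame(samples)
    matrixTsv(betaBS(paired), file.path(outdir, "beta_bs.tsv"))
    matrixTsv(betaOxBS(paired), file.path(outdir, "beta_oxbs.tsv"))
    writeTsv(data.frame(locus_id = names(ann),
                        chrom = as.character(GenomicRanges::seqnames(ann)),
                        pos0 = GenomicRanges::start(ann) - 1L,
                        as.data.frame(S4Vectors::mcols(ann))),
             file.path(outdir, "annotation.tsv"))
    writeTsv(data.frame(sample = rownames(samples), as.data.frame(samples)),
             file.path(outdir, "samples.tsv"))
    counts$n_loci <- nrow(paired); counts$n_samples <- ncol(paired)

    ## stage: deconvolve
    props <- stage("deconvolve", {
        if (deconvMethod == "naive") deconvolveNaive(paired)
        else deconvolveML(paired)
    })
    matrixTsv(p5hmC(props), file.path(outdir, "p5hmc.tsv"))
    matrixTsv(p5mC(props), file.path(outdir, "p5mc.tsv"))

    ## stage: select
    sel <- stage("select", {
        med <- sampleMedians(props, samples)
        hi <- selectHigh5hmC(props, frac = frac)
        rho <- perLocusCorrelation(props)
        prof <- tssProfile(props)
        list(med = med, hi = hi, rho = rho, prof = prof)
    })
    writeTsv(sel$med$medians, file.path(outdir, "sample_medians.tsv"))
    writeTsv(sel$hi$summary, file.path(outdir, "locus_summary.tsv"))
    writeTsv(sel$prof, file.path(outdir, "tss_profile.tsv"))
    writeLociBed(ann, sel$hi$highLoci, file.path(outdir, "high_5hmc.bed"))
    counts$n_high <- sel$hi$k

    ## stage: enrich
    enr <- stage("enrich", {
        uni <- rownames(props)
        ctxRows <- do.call(rbind, lapply(
            c("island", "shore", "shelf", "open_sea"), function(f)
                fisherContextEnrichment(sel$hi$highLoci, uni, ann, f)))
        regRows <- do.call(rbind, lapply(
            c("enhancer", "tfbs", "utr5"), function(f)
                cmhEnrichment(sel$hi$highLoci, uni, ann, f)))
        tab <- rbind(ctxRows, regRows)
        tab$q_value <- bhAdjust(tab$p_value)
        if (!is.null(regionCollections))
            tab <- rbind(tab, regionSetEnrichment(sel$hi$highLoci, uni, ann,
                                                  regionCollections))
        genes <- geneHigh5hmCScore(sel$hi$highLoci, ann, min_high = min_high)
        list(tab = tab, genes = genes)
    })
    writeTsv(enr$tab, file.path(outdir, "enrichment.tsv"))
    writeTsv(enr$genes, file.path(outdir, "gene_high5hmc.tsv"))
    counts$n_genes_scored <- nrow(enr$genes)

    ## stage: differential
    diffRes <- stage("differential", {
        rows <- fitLocusModels(props, samples, loci = sel$hi$highLoci)
        dhmr <- extractDHMR(rows, fdr = fdr, direction = "hypo")
        list(rows = rows, dhmr = dhmr)
    })
    writeTsv(diffRes$rows, file.path(outdir, "differential.tsv"))
    if (length(diffRes$dhmr))
        writeLociBed(ann, diffRes$dhmr, file.path(outdir, "dhmr.bed"))
    counts$n_dhmr <- length(diffRes$dhmr)

    ## stage: cluster/survival
    surv <- stage("cluster_survival", {
        tum <- colnames(props)[samples$group == "tumor"]
        nTop <- min(top_n, nrow(props))
        loci <- topVariableLoci(props, tum, nTop)
        tree <- rpmmCluster(t(p5hmC(props)[loci, tum, drop = FALSE]))
        labs <- NULL; cox <- NULL; km <- NULL
        if (length(rpmmLeaves(tree)) == 2) {
            lab <- labelClusters(tree, props, samples)
            labs <- lab$labels
            cox <- coxFit(samples, "death", cluster = labs)
            km <- kmLogrank(samples[tum, ], labs, "death")
        }
        list(tree = tree, labels = labs, cox = cox, km = km)
    })
    if (!is.null(surv$labels))
        writeTsv(data.frame(sample = names(surv$labels),
                            cluster = surv$labels),
                 file.path(outdir, "clusters.tsv"))
    if (!is.null(surv$cox))
        writeTsv(surv$cox$table, file.path(outdir, "cox_death.tsv"))
    counts$n_leaves <- length(rpmmLeaves(surv$tree))

    manifest <- list(
        package = "tandem5hmC",
        version = as.character(utils::packageVersion("tandem5hmC")),
        seed = if (inherits(cfg, "SimConfig")) cfg$seed else NA,
        parameter_hash = fnv1a(paste(deparse(params), collapse = "")),
        counts = counts)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    summaryLines <- c(
        sprintf("tandem5hmC pipeline run (seed %s)", manifest$seed),
        sprintf("  loci: %d, samples: %d", counts$n_loci, counts$n_samples),
        sprintf("  high-5hmC loci selected: %d (threshold %.4f)",
                counts$n_high, sel$hi$threshold),
        sprintf("  DHMRs at FDR < %g: %d", fdr, counts$n_dhmr),
        sprintf("  RPMM leaves: %d", counts$n_leaves))
    writeLines(summaryLines, file.path(outdir, "summary.txt"))
    invisible(manifest)
}
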