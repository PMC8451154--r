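## Internal helpers ----------------------------------------------------------

# Derive a stage-specific RNG seed from the master seed so each simulator
# stage can be regenerated independently and deterministically.
deriveSeed <- function(seed, stage) {
    stages <- c(annotation = 1L, truth = 2L, observed = 3L, survival = 4L,
                pipeline = 5L)
    off <- stages[[stage]]
    as.integer((as.double(seed) * 2654435761 + off * 97003) %% 2147483647)
}

clamp01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

# logit-normal jitter of a proportion
jitterLogit <- function(p, sd) stats::plogis(stats::qlogis(clamp01(p)) + stats::rnorm(length(p), 0, sd))

checkFraction <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
        stop("configuration error: '", name, "' must be a fraction in (0, 1)",
             call. = FALSE)
    invisible(x)
}

checkCount <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != round(x))
        stop("configuration error: '", name, "' must be an integer >= ", min,
             call. = FALSE)
    invisible(x)
}

checkPositive <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
        stop("configuration error: '", name, "' must be positive", call. = FALSE)
    invisible(x)
}

# FNV-1a hash of a character scalar; used for run-manifest parameter hashes.
fnv1a <- function(x) {
    bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
    h <- 2166136261
    for (b in bytes) {
        h <- bitwXor(as.integer(h %% 2^31), b)
        h <- (h * 16777619) %% 2^31
    }
    sprintf("%08x", as.integer(h))
}

# rowRanges if genuinely present (SE -> RangedSE coercion yields a
# zero-length placeholder), else NULL
rowRangesOrNull <- function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    if (length(rr) == nrow(x)) rr else NULL
}

# placeholder coordinates (seqname "unassigned") so containers without a
# real annotation still carry locus IDs through rowRanges
placeholderRanges <- function(ids) {
    gr <- GenomicRanges::GRanges("unassigned",
                                 IRanges::IRanges(seq_along(ids), width = 1L))
    names(gr) <- ids
    gr
}

# Column names of tumor samples from a colData-like frame
tumorIds <- function(samples) {
    rownames(samples)[samples$group == "tumor"]
}
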