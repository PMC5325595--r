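## Shared fixtures and independent oracles for the test suite.

## A minimal one-group experiment whose 12 values per gene are given
## directly (ordered: replicate set 1 at ascending ZT, then set 2).
makeSeriesExperiment <- function(series, zt = seq(2, 22, by = 4),
                                 group = "LNv") {
    m <- do.call(rbind, series)
    rownames(m) <- names(series)
    sd <- data.frame(group = group, replicate_set = rep(1:2, each = 6),
                     zt = rep(zt, 2))
    CircadianExperiment(m, sd)
}

## Multi-group experiment with per-group constant means (genes x groups),
## optionally with iid lognormal noise of the given CV.
makeGroupExperiment <- function(meansByGroup, cv = 0, seed = NULL,
                                grids = defaultZtGrids()) {
    if (!is.null(seed)) set.seed(seed)
    groups <- colnames(meansByGroup)
    cols <- list(); meta <- list()
    sdlog <- sqrt(log(1 + cv^2))
    for (g in groups) for (rs in 1:2) for (zt in sort(grids[[g]])) {
        mu <- meansByGroup[, g]
        val <- if (cv > 0) mu * rlnorm(length(mu), -sdlog^2 / 2, sdlog)
               else mu
        cols[[length(cols) + 1L]] <- val
        meta[[length(meta) + 1L]] <- data.frame(
            sample_id = sprintf("%s_r%d_ZT%02d", g, rs, zt),
            group = g, replicate_set = rs, zt = zt)
    }
    m <- do.call(cbind, cols)
    rownames(m) <- rownames(meansByGroup)
    sd <- do.call(rbind, meta)
    colnames(m) <- sd$sample_id
    CircadianExperiment(m, sd)
}

## Independent DFT oracle for the 24-h component: least-squares projection
## of the series onto cos/sin of a 24-h period over the 48-h time vector.
oracleF24 <- function(values, zt) {
    tt <- c(zt, zt + 24)
    fit <- lm(values ~ cos(2 * pi * tt / 24) + sin(2 * pi * tt / 24))
    a <- unname(coef(fit)[2]); b <- unname(coef(fit)[3])
    phase <- (atan2(b, a) * 24 / (2 * pi)) %% 24
    list(phase = phase, amp = sqrt(a^2 + b^2))
}

## Brute-force Kendall S between two vectors (pairs tied in either
## vector contribute 0).
oracleKendallS <- function(x, y) {
    n <- length(x)
    s <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
        s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    s
}

## Circular distance between two ZT phases, hours in [0, 12].
phaseDist <- function(a, b) abs(((a - b + 12) %% 24) - 12)

## All permutations of a small vector (for exhaustive null checks).
allPerms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (p in allPerms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
}

## Write a GeneModels object as GTF and BED12 text files.
writeModelsGTF <- function(models, path) {
    ex <- exonsByTranscript(models)
    tg <- txToGene(models)
    lines <- character()
    for (t in names(ex)) {
        gr <- ex[[t]]
        for (i in seq_along(gr))
            lines <- c(lines, paste(
                as.character(GenomicRanges::seqnames(gr))[i], "sim", "exon",
                GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i], ".",
                as.character(GenomicRanges::strand(gr))[i], ".",
                sprintf('gene_id "%s"; transcript_id "%s";', tg[[t]], t),
                sep = "\t"))
    }
    writeLines(lines, path)
}

writeModelsBED12 <- function(models, path) {
    ex <- exonsByTranscript(models)
    lines <- character()
    for (t in names(ex)) {
        gr <- ex[[t]]
        st <- min(GenomicRanges::start(gr)) - 1L
        en <- max(GenomicRanges::end(gr))
        bs <- GenomicRanges::start(gr) - 1L - st
        bw <- GenomicRanges::width(gr)
        lines <- c(lines, paste(
            as.character(GenomicRanges::seqnames(gr))[1], st, en, t, 0,
            as.character(GenomicRanges::strand(gr))[1], st, en, "0",
            length(gr), paste0(paste(bw, collapse = ","), ","),
            paste0(paste(bs, collapse = ","), ","), sep = "\t"))
    }
    writeLines(lines, path)
}

## Single-transcript GeneModels from exon start/end vectors (1-based
## closed coordinates).
singleTxModel <- function(starts, ends, strand = "+", gene = "gA",
                          tx = "gA.1", chrom = "chr2L") {
    gl <- GenomicRanges::GRangesList(stats::setNames(list(
        GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                               strand = strand)), tx))
    GeneModels(gl, stats::setNames(gene, tx))
}
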