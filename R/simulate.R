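#' @include AllClasses.R
#' @importFrom stats rnbinom rexp rlnorm rnorm runif rbinom setNames
NULL

.drawPhases <- function(n, dist, param) {
    wrap <- function(x) x %% 24
    switch(dist,
        uniform  = runif(n, 0, 24),
        unimodal = wrap(rnorm(n, param[1], param[2])),
        bimodal  = {
            pick <- runif(n) < 0.5
            wrap(ifelse(pick, rnorm(n, param[1], param[3]),
                              rnorm(n, param[2], param[3])))
        })
}

#' Simulate a circadian expression time course with ground truth
#'
#' Draws per-gene baselines from a log-normal, programs a configurable
#' fraction of cyclers per group with a 24-h cosine mean (peak at the
#' programmed phase, peak/trough ratio equal to the programmed amplitude
#' fold), restricts a fraction of genes to a random subset of groups, keeps
#' a fraction below the 10-RPM enrichment filter, samples raw counts with
#' negative-binomial noise at the configured library size, and normalizes
#' each library to reads per million.
#'
#' The mean of a cycler at zeitgeber time `t` is
#' `b * (1 + m * cos(2*pi*(t - phase)/24))` with `m = (a-1)/(a+1)`, so the
#' time-averaged level stays at the baseline `b` and the peak/trough ratio
#' is exactly the amplitude fold `a`.  The two replicate sets are two
#' independent days: identical mean model, independent noise.  With
#' `dispersion = 0` no sampling (and no library renormalization) occurs:
#' the mean model itself is returned on the RPM scale, so programmed
#' amplitudes and phases are exact.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `experiment` (a [CircadianExperiment-class]) and
#'   `truth` (data.frame: `gene_id`, `group`, `expressed`, `is_cycler`,
#'   `phase`, `amplitude_fold`, `baseline`).
#' @examples
#' sim <- simulateExpression(SimulationConfig(n_genes = 50, seed = 1))
#' dim(sim$experiment)
#' @export
simulateExpression <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    if (!is.na(config@seed)) set.seed(config@seed)
    ng <- config@n_genes
    groups <- config@groups
    genes <- sprintf("gene_%04d", seq_len(ng))

    baseline <- rlnorm(ng, config@baseline_meanlog, config@baseline_sdlog)
    low <- runif(ng) < config@frac_low_expression
    baseline[low] <- runif(sum(low), 0.5, 8)

    ## group-restricted genes: expressed in a random nonempty proper subset
    expressed <- matrix(TRUE, ng, length(groups),
                        dimnames = list(genes, groups))
    restricted <- runif(ng) < config@frac_group_restricted
    for (i in which(restricted)) {
        k <- sample(seq_len(length(groups) - 1), 1)
        expressed[i, ] <- FALSE
        expressed[i, sample(groups, k)] <- TRUE
    }
    off_baseline <- 0.5  # RPM for groups a gene is not expressed in

    is_cycler <- matrix(FALSE, ng, length(groups),
                        dimnames = list(genes, groups))
    phase <- matrix(NA_real_, ng, length(groups),
                    dimnames = list(genes, groups))
    for (g in groups) {
        cyc <- expressed[, g] & runif(ng) < config@frac_cyclers[[g]]
        is_cycler[, g] <- cyc
        phase[cyc, g] <- .drawPhases(sum(cyc), config@phase_dist,
                                     config@phase_param)
    }

    a <- config@amplitude_fold
    m <- (a - 1) / (a + 1)
    cols <- list()
    meta <- list()
    for (g in groups) {
        zt <- sort(config@zt_grids[[g]])
        b <- ifelse(expressed[, g], baseline, off_baseline)
        mu <- outer(seq_len(ng), seq_along(zt), function(i, j) {
            ph <- phase[i, g]
            mod <- ifelse(is_cycler[i, g],
                          1 + m * cos(2 * pi * (zt[j] - ph) / 24), 1)
            b[i] * mod
        })
        for (rs in 1:2) for (j in seq_along(zt)) {
            muj <- mu[, j]
            if (config@dispersion > 0) {
                lam <- muj / sum(muj) * config@library_size
                cnt <- rnbinom(ng, mu = lam, size = 1 / config@dispersion)
                val <- cnt / sum(cnt) * 1e6
            } else {
                ## noiseless mode: the mean model itself, on the RPM scale
                val <- muj
            }
            cols[[length(cols) + 1L]] <- val
            meta[[length(meta) + 1L]] <- data.frame(
                sample_id = sprintf("%s_r%d_ZT%02d", g, rs, zt[j]),
                group = g, replicate_set = rs, zt = zt[j])
        }
    }
    rpmMat <- do.call(cbind, cols)
    rownames(rpmMat) <- genes
    sd <- do.call(rbind, meta)
    colnames(rpmMat) <- sd$sample_id
    truth <- do.call(rbind, lapply(groups, function(g) data.frame(
        gene_id = genes, group = g, expressed = expressed[, g],
        is_cycler = is_cycler[, g], phase = phase[, g],
        amplitude_fold = ifelse(is_cycler[, g], a, 1),
        baseline = ifelse(expressed[, g], baseline, off_baseline),
        row.names = NULL)))
    list(experiment = CircadianExperiment(rpmMat, sd), truth = truth)
}

#' Simulate 3'-biased read positions for one library
#'
#' Places single-read 3'-position records for each gene: the read count is
#' multinomial with probability proportional to the gene's target RPM, the
#' isoform is drawn uniformly, and the distance of the read 3' end from the
#' isoform 3' end follows an exponential with the configured decay length
#' (truncated to the spliced transcript length), emulating the 3' bias of
#' oligo-dT-primed low-input libraries.  Positions are projected through
#' the exon structure, so every record lies inside an exon.
#'
#' @param models a [GeneModels-class].
#' @param target_rpm named numeric vector of per-gene target RPM.
#' @param config a [SimulationConfig-class]; `library_size` and
#'   `three_prime_bias` (decay length, bp) are used.
#' @return width-1 stranded `GRanges` of read 3' positions, metadata column
#'   `gene_id` recording the source gene.
#' @export
simulateReads <- function(models, target_rpm, config) {
    if (!is.na(config@seed)) set.seed(config@seed)
    missing <- setdiff(names(target_rpm), geneNames(models))
    if (length(missing))
        stop("no gene model for: ", paste(missing, collapse = ", "))
    tg <- txToGene(models)
    lens <- txLengths(models)
    prob <- target_rpm / sum(target_rpm)
    counts <- as.vector(stats::rmultinom(1, config@library_size, prob))
    names(counts) <- names(target_rpm)
    out <- list()
    for (gene in names(counts)[counts > 0]) {
        n <- counts[[gene]]
        txs <- names(tg)[tg == gene]
        tx <- txs[sample.int(length(txs), n, replace = TRUE)]
        d <- floor(rexp(n, rate = 1 / config@three_prime_bias))
        for (t in unique(tx)) {
            sel <- tx == t
            dt <- d[sel] %% lens[[t]]   # truncate to transcript length
            ex <- exonsByTranscript(models)[[t]]
            w <- GenomicRanges::width(ex)
            minus <- as.character(GenomicRanges::strand(ex))[1] == "-"
            ## cumulative spliced bp, counted from the 3' end
            ord <- if (minus) seq_along(w) else rev(seq_along(w))
            cw <- cumsum(w[ord])
            idx <- findInterval(dt, c(0, cw), rightmost.closed = FALSE)
            off <- dt - c(0, cw)[idx]   # bp into that exon, from its 3' side
            exi <- ord[idx]
            pos <- if (minus) GenomicRanges::start(ex)[exi] + off
                   else       GenomicRanges::end(ex)[exi] - off
            out[[length(out) + 1L]] <- GenomicRanges::GRanges(
                GenomicRanges::seqnames(ex)[1],
                IRanges::IRanges(pos, width = 1),
                strand = if (minus) "-" else "+", gene_id = gene)
        }
    }
    if (!length(out))
        return(GenomicRanges::GRanges())
    unname(do.call(c, out))
}

#' Simulate a large- vs small-cell expression-ratio table
#'
#' For every LNv cycler in `truth`, draws a log2 l-LNv/s-LNv expression
#' ratio: morning-phase cyclers are shifted by `-effect_log2 / 2` (higher
#' in s-LNvs, ratio < 1), evening-phase cyclers by `+effect_log2 / 2`
#' (higher in l-LNvs), others centred at 0, each with normal noise
#' `sd_log2`.  `effect_log2 = 0` gives identical distributions in both
#' phase bins.
#'
#' @param truth truth table from [simulateExpression()].
#' @param effect_log2 programmed morning-vs-evening separation (log2 units).
#' @param sd_log2 per-gene noise SD (log2 units).
#' @param morning,evening closed phase intervals (ZT hours) defining the
#'   morning and evening bins.
#' @param group group whose cyclers receive ratios (default `"LNv"`).
#' @return data.frame with `gene_id` and `ratio` (> 0, l-LNv over s-LNv).
#' @export
simulateLsRatios <- function(truth, effect_log2 = 1, sd_log2 = 1,
                             morning = c(3, 8), evening = c(14, 19),
                             group = "LNv") {
    tr <- truth[truth$group == group & truth$is_cycler, ]
    if (!nrow(tr))
        stop("truth contains no ", group, " cyclers")
    shift <- rep(0, nrow(tr))
    shift[tr$phase >= morning[1] & tr$phase <= morning[2]] <-
        -effect_log2 / 2
    shift[tr$phase >= evening[1] & tr$phase <= evening[2]] <-
        +effect_log2 / 2
    data.frame(gene_id = tr$gene_id,
               ratio = 2^(shift + rnorm(nrow(tr), 0, sd_log2)))
}

#' Simulate gene models on a toy chromosome
#'
#' Lays out `n_genes` non-overlapping genes along one chromosome with
#' random strand, 1-4 exons (widths 100-1000 bp, introns 50-500 bp) and,
#' with probability `p_alt_end`, a second isoform whose terminal exon is
#' shortened so the two isoforms have distinct 3' ends (the
#' alternative-3'UTR situation isoform-resolved windows exist for).
#'
#' @param n_genes number of genes.
#' @param p_alt_end probability of a second isoform with a shorter 3' UTR
#'   (default 0.3).
#' @param chrom chromosome name (default `"chrS"`).
#' @param seed optional integer seed.
#' @return A [GeneModels-class]; gene ids `gene_0001`, ... match
#'   [simulateExpression()].
#' @export
simulateGeneModels <- function(n_genes, p_alt_end = 0.3, chrom = "chrS",
                               seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    exl <- list()
    txg <- character()
    cursor <- 1000L
    for (i in seq_len(n_genes)) {
        gene <- sprintf("gene_%04d", i)
        nex <- sample(1:4, 1)
        ws <- sample(100:1000, nex, replace = TRUE)
        gaps <- if (nex > 1) sample(50:500, nex - 1, replace = TRUE) else
            integer(0)
        st <- cursor + cumsum(c(0L, ws[-nex] + gaps))
        en <- st + ws - 1L
        strand <- sample(c("+", "-"), 1)
        tx1 <- paste0(gene, ".1")
        exl[[tx1]] <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(st, en), strand = strand)
        txg[tx1] <- gene
        if (runif(1) < p_alt_end) {
            ## shorten the terminal exon by 150-450 bp (kept >= 50 bp)
            cut <- min(sample(150:450, 1), ws[if (strand == "+") nex else 1] - 50L)
            st2 <- st; en2 <- en
            if (strand == "+") en2[nex] <- en2[nex] - cut
            else st2[1] <- st2[1] + cut
            tx2 <- paste0(gene, ".2")
            exl[[tx2]] <- GenomicRanges::GRanges(chrom,
                IRanges::IRanges(st2, en2), strand = strand)
            txg[tx2] <- gene
        }
        cursor <- en[nex] + sample(500:2000, 1)
    }
    GeneModels(GenomicRanges::GRangesList(exl), txg)
}
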