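#' @include AllClasses.R cycling.R
#' @importFrom stats t.test quantile median
NULL

.selectCyclers <- function(cyc, group, confidence) {
    r <- cyc[cyc$group == group & cyc$confidence %in% confidence, ]
    r[!is.na(r$phase), ]
}

#' Phase histogram of cycling transcripts
#'
#' Bins cycler phases (the F24 peak phase) over the circular day [0, 24)
#' and reports the percentage of cyclers per bin.  Bins are aligned to ZT0
#' and binning is circular: a phase of 23.9 h and one of 0.1 h land in
#' adjacent wrap-around bins, never pooled.
#'
#' @param cyc a [CyclingResults][results-classes] table.
#' @param group group to summarize.
#' @param bin_width bin width in hours (default 2; must divide 24).
#' @param confidence confidence classes to include: `"HC"` or
#'   `c("HC", "LC")`.
#' @return data.frame with `bin_start`, `bin_end`, `count` and `percent`
#'   (percentages sum to 100 over cyclers with defined phase); zero rows
#'   with a warning when no cycler qualifies.
#' @export
phaseHistogram <- function(cyc, group, bin_width = 2,
                           confidence = "HC") {
    stopifnot(24 %% bin_width == 0)
    r <- .selectCyclers(cyc, group, confidence)
    edges <- seq(0, 24, by = bin_width)
    if (!nrow(r)) {
        warning("no ", paste(confidence, collapse = "/"),
                " cyclers with defined phase in group ", group)
        return(data.frame(bin_start = utils::head(edges, -1),
                          bin_end = edges[-1], count = 0, percent = NA_real_))
    }
    idx <- findInterval(r$phase %% 24, edges, rightmost.closed = FALSE)
    cnt <- tabulate(idx, nbins = length(edges) - 1L)
    data.frame(bin_start = utils::head(edges, -1), bin_end = edges[-1],
               count = cnt, percent = 100 * cnt / sum(cnt))
}

#' Circular mean of phases
#'
#' @param phases numeric vector of ZT hours.
#' @return circular mean in [0, 24), `NA` for an empty input or a
#'   resultant of length ~0 (perfectly antipodal phases).
#' @examples
#' circularMeanPhase(c(23, 1))  # 0, not 12
#' @export
circularMeanPhase <- function(phases) {
    phases <- phases[!is.na(phases)]
    if (!length(phases)) return(NA_real_)
    th <- phases * 2 * pi / 24
    x <- mean(cos(th)); y <- mean(sin(th))
    if (sqrt(x^2 + y^2) < 1e-12) return(NA_real_)
    (atan2(y, x) * 24 / (2 * pi)) %% 24
}

#' Mean phase of the core clock genes
#'
#' Circular mean of the fitted phases of the canonical CLK/CYC target
#' transcripts in one group.  Genes absent from the results (or without a
#' defined phase) are dropped with a message.
#'
#' @param cyc a [CyclingResults][results-classes] table.
#' @param group group label.
#' @param genes core clock gene ids (default `vri`, `Pdp1`, `per`, `tim`).
#' @return circular mean phase in ZT hours.
#' @export
coreClockPhase <- function(cyc, group,
                           genes = c("vri", "Pdp1", "per", "tim")) {
    r <- cyc[cyc$group == group & cyc$gene_id %in% genes, ]
    have <- r$gene_id[!is.na(r$phase)]
    miss <- setdiff(genes, have)
    if (length(miss))
        message("core clock phase for ", group, " computed without: ",
                paste(miss, collapse = ", "))
    if (!length(have))
        stop("no core clock phases available for group ", group)
    circularMeanPhase(r$phase[!is.na(r$phase)])
}

#' Cross-group overlap of cycling transcripts
#'
#' Intersects per-group cycler sets (at the requested confidence) and
#' reports pairwise and higher-order intersection counts plus the number
#' of genes cycling in exactly k of the groups.  With a
#' [CircadianExperiment-class] supplied, genes cycling in exactly one
#' group are additionally split by whether they are expressed (group mean
#' > 5 RPM) in any of the other groups.
#'
#' @param cyc a [CyclingResults][results-classes] table.
#' @param groups groups to intersect (default: all in `cyc`).
#' @param confidence confidence classes to include (default `"HC"`).
#' @param ce optional [CircadianExperiment-class] for the
#'   expressed-elsewhere annotation.
#' @return list with `sets` (per-group gene-id vectors), `pairwise`
#'   (data.frame of pair counts), `intersection_all` (genes cycling in all
#'   groups), `exactly_k` (named count vector, k = 1..length(groups)) and
#'   optionally `single_group_not_expressed_elsewhere`.
#' @export
overlapAnalysis <- function(cyc, groups = NULL, confidence = "HC",
                            ce = NULL) {
    if (is.null(groups)) groups <- unique(cyc$group)
    if (length(groups) < 2) stop("need at least two groups")
    sets <- lapply(groups, function(g)
        unique(cyc$gene_id[cyc$group == g & cyc$confidence %in% confidence]))
    names(sets) <- groups
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    pairwise <- do.call(rbind, lapply(pairs, function(p) data.frame(
        group1 = p[1], group2 = p[2],
        n = length(intersect(sets[[p[1]]], sets[[p[2]]])))))
    all_genes <- unique(unlist(sets))
    k <- rowSums(vapply(sets, function(s) all_genes %in% s,
                        logical(length(all_genes))))
    exactly_k <- vapply(seq_along(groups), function(i) sum(k == i),
                        integer(1))
    names(exactly_k) <- paste0("in_", seq_along(groups), "_groups")
    out <- list(sets = sets, pairwise = pairwise,
                intersection_all = Reduce(intersect, sets),
                exactly_k = exactly_k)
    if (!is.null(ce)) {
        single <- all_genes[k == 1]
        home <- vapply(single, function(g)
            groups[vapply(sets, function(s) g %in% s, logical(1))][1],
            character(1))
        expr <- vapply(groups, function(g) isExpressed(ce, g),
                       logical(nrow(ce)))
        elsewhere <- vapply(seq_along(single), function(i) {
            oth <- setdiff(groups, home[i])
            any(expr[single[i], oth])
        }, logical(1))
        out$single_group_not_expressed_elsewhere <-
            sum(!elsewhere)
        out$single_group_total <- length(single)
    }
    out
}

#' Morning- versus evening-phase expression-ratio test
#'
#' Assigns each cycler of a group to the morning or evening phase bin
#' (closed intervals, default ZT3-8 and ZT14-19; cyclers outside both are
#' excluded) and compares the large-cell/small-cell expression ratios of
#' the two bins on the log2 scale with a two-sample t-test (Welch by
#' default).  Ratio semantics: a value below 1 means higher expression in
#' the small cells.
#'
#' @param cyc a [CyclingResults][results-classes] table.
#' @param ratios data.frame with `gene_id` and `ratio` (> 0).
#' @param group group whose cyclers are tested (default `"LNv"`).
#' @param confidence confidence classes to include (default `"HC"`).
#' @param morning,evening closed ZT intervals of the two bins.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return list with `t`, `p`, `df`, `n` (per bin), and `bin_summary`
#'   (median and quartiles of the raw ratio per bin).
#' @export
morningEveningRatioTest <- function(cyc, ratios, group = "LNv",
        confidence = "HC", morning = c(3, 8), evening = c(14, 19),
        var_equal = FALSE) {
    r <- .selectCyclers(cyc, group, confidence)
    r <- merge(as.data.frame(r[, c("gene_id", "phase")]), ratios,
               by = "gene_id")
    bin <- ifelse(r$phase >= morning[1] & r$phase <= morning[2], "morning",
           ifelse(r$phase >= evening[1] & r$phase <= evening[2], "evening",
                  NA))
    r <- r[!is.na(bin), ]
    bin <- bin[!is.na(bin)]
    n <- c(morning = sum(bin == "morning"), evening = sum(bin == "evening"))
    if (any(n < 2))
        stop("phase bin with fewer than 2 genes: test undefined (",
             paste(names(n), n, sep = "=", collapse = ", "), ")")
    lr <- log2(r$ratio)
    tt <- t.test(lr[bin == "morning"], lr[bin == "evening"],
                 var.equal = var_equal)
    qs <- function(x) stats::setNames(
        quantile(x, c(0.25, 0.5, 0.75)), c("q1", "median", "q3"))
    list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), n = n,
         bin_summary = rbind(morning = qs(r$ratio[bin == "morning"]),
                             evening = qs(r$ratio[bin == "evening"])))
}
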