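#' @include AllClasses.R accessors.R
#' @importFrom stats aov TukeyHSD p.adjust
NULL

#' Per-group expression filter (10 RPM in both replicate sets)
#'
#' A gene passes for a group when its average RPM is at least `min_avg` in
#' each of the two independent six-timepoint experiments -- both sets must
#' clear the threshold, and the comparison is inclusive (`>=`).  Genes
#' failing the filter are flagged "LR" (low reads) downstream and do not
#' take part in enrichment comparisons for that group.
#'
#' @param ce a [CircadianExperiment-class].
#' @param group group label.
#' @param min_avg RPM threshold (default 10).
#' @return named logical vector over genes.
#' @export
expressionFilter <- function(ce, group, min_avg = 10) {
    checkDesign(ce, group)
    sel <- sampleGroup(ce) == group
    m1 <- rowMeans(rpm(ce)[, sel & replicateSet(ce) == 1L, drop = FALSE])
    m2 <- rowMeans(rpm(ce)[, sel & replicateSet(ce) == 2L, drop = FALSE])
    m1 >= min_avg & m2 >= min_avg
}

#' Is a gene expressed in a group?
#'
#' Expression is defined as a group-mean RPM strictly above `min_rpm`
#' (default 5) over all 12 samples of the group.
#'
#' @inheritParams expressionFilter
#' @param min_rpm strict RPM threshold (default 5).
#' @return named logical vector over genes.
#' @export
isExpressed <- function(ce, group, min_rpm = 5) {
    sel <- sampleGroup(ce) == group
    rowMeans(rpm(ce)[, sel, drop = FALSE]) > min_rpm
}

#' Group mean expression
#'
#' @param ce a [CircadianExperiment-class].
#' @return matrix genes x groups of mean RPM over each group's samples.
#' @export
groupMeans <- function(ce) {
    gs <- groupNames(ce)
    vapply(gs, function(g)
        rowMeans(rpm(ce)[, sampleGroup(ce) == g, drop = FALSE]),
        numeric(nrow(ce)))
}

## log2 fold change of group means; a zero denominator gets a 0.1-RPM
## pseudo-value (and only then), recorded by the caller.
.log2Fold <- function(num, den) log2(num / ifelse(den == 0, 0.1, den))

#' ANOVA, Tukey HSD and Benjamini-Hochberg across neuron groups
#'
#' Genes are pre-screened for a 2-fold change between some pair of group
#' means (on raw RPM), then each pre-screened gene is tested by one-way
#' ANOVA across the groups on log2(RPM + 1) values (variance
#' stabilization; the overdispersion of count-derived RPM grows with the
#' mean).  ANOVA p-values are Benjamini-Hochberg adjusted over the tested
#' set, and Tukey's HSD provides pairwise p-values.  A gene whose values
#' are constant within every group has an undefined F statistic; it is
#' reported with `NA` p-values and excluded from the adjustment.
#'
#' @param ce a [CircadianExperiment-class].
#' @param genes optional subset of gene ids to consider.
#' @param fold_prescreen pre-screen fold threshold on group means
#'   (default 2; `0` disables).
#' @return `DataFrame` over pre-screened genes: `gene_id`, `anova_p`,
#'   `bh_q`, and one `tukey_<A>.<B>` column per group pair.
#' @export
anovaTukeyBH <- function(ce, genes = NULL, fold_prescreen = 2) {
    gs <- groupNames(ce)
    if (length(gs) < 2)
        stop("need at least two groups")
    gm <- groupMeans(ce)
    if (is.null(genes)) genes <- rownames(ce)
    gm <- gm[genes, , drop = FALSE]
    if (fold_prescreen > 0) {
        mx <- apply(gm, 1, max)
        mn <- apply(gm, 1, min)
        keep <- mx / ifelse(mn == 0, 0.1, mn) >= fold_prescreen
        genes <- genes[keep]
    }
    grp <- factor(sampleGroup(ce), levels = gs)
    Y <- log2(rpm(ce)[genes, , drop = FALSE] + 1)
    pairNames <- utils::combn(sort(gs), 2, FUN = paste, collapse = ".")
    res <- matrix(NA_real_, length(genes), 1 + length(pairNames),
                  dimnames = list(genes, c("anova_p", pairNames)))
    for (i in seq_along(genes)) {
        y <- Y[i, ]
        if (all(tapply(y, grp, function(v) max(v) - min(v)) < 1e-12))
            next  # constant within every group: F undefined
        fit <- aov(y ~ grp)
        an <- summary(fit)[[1]]
        res[i, "anova_p"] <- an[["Pr(>F)"]][1]
        tk <- TukeyHSD(fit)$grp
        ## TukeyHSD names pairs "B-A"; normalize to our "A.B" order
        nm <- strsplit(rownames(tk), "-", fixed = TRUE)
        for (j in seq_along(nm))
            res[i, paste(sort(nm[[j]]), collapse = ".")] <- tk[j, "p adj"]
    }
    dropped <- genes[is.na(res[, "anova_p"])]
    if (length(dropped))
        message(length(dropped),
                " gene(s) with zero within-group variance excluded: ",
                paste(utils::head(dropped, 5), collapse = ", "))
    DataFrame(gene_id = genes, anova_p = res[, "anova_p"],
              bh_q = p.adjust(res[, "anova_p"], method = "BH"),
              as.data.frame(res[, pairNames, drop = FALSE]))
}

#' Common-circadian enrichment rule
#'
#' A transcript is enriched in circadian neurons when, for at least
#' `min_groups` of the circadian groups, its log2 fold enrichment over the
#' outgroup reaches `log2(fold_threshold)` and the comparison is
#' statistically supported.  `NA` cells of `lfc` mark groups where the
#' transcript failed the expression filter (LR, low reads); they never
#' qualify but do not disqualify the gene either.
#'
#' @param lfc numeric matrix genes x circadian groups of log2 fold
#'   enrichment versus the outgroup; `NA` = LR.
#' @param significant optional logical matrix of the same shape: is the
#'   (group, outgroup) comparison statistically significant?  `NULL`
#'   assumes significance for every cell (rule-only application, e.g. to
#'   a printed enrichment table).
#' @param fold_threshold enrichment fold (default 5; applied as
#'   `lfc >= log2(fold_threshold)`).
#' @param min_groups minimum number of qualifying circadian groups
#'   (default 2).
#' @return named logical vector over the rows of `lfc`.
#' @examples
#' lfc <- rbind(cry = c(4.04, 2.78, 4.11), dist = c(1.58, -1, -1))
#' classifyCommonCircadian(lfc)
#' @export
classifyCommonCircadian <- function(lfc, significant = NULL,
                                    fold_threshold = 5, min_groups = 2) {
    lfc <- as.matrix(lfc)
    if (is.null(significant))
        significant <- matrix(TRUE, nrow(lfc), ncol(lfc))
    qual <- !is.na(lfc) & lfc >= log2(fold_threshold) & significant
    stats::setNames(rowSums(qual) >= min_groups, rownames(lfc))
}

#' Group-specific enrichment rule
#'
#' A transcript is specifically enriched in circadian group `g` when it
#' passes the expression filter in `g`, is more than `fold_high`-fold
#' higher than one of the other circadian groups and more than
#' `fold_low`-fold higher than the remaining one, with both pairwise
#' comparisons statistically significant.  Because `fold_high` exceeds
#' 1 in both directions of a pair, a gene can satisfy the rule for at most
#' one group; this is asserted.
#'
#' @param means matrix genes x circadian groups of mean RPM.
#' @param passes_filter logical matrix of the same shape (expression
#'   filter per group).
#' @param significant optional named list of logical vectors, one per
#'   unordered pair `"A.B"` (sorted labels): is the pair significant for
#'   each gene?  `NULL` assumes significance.
#' @param fold_high,fold_low the two fold thresholds (defaults 5 and 2,
#'   both strict `>`).
#' @return named character vector over genes: the group a gene is specific
#'   to, or `NA`.
#' @export
classifyGroupSpecific <- function(means, passes_filter, significant = NULL,
                                  fold_high = 5, fold_low = 2) {
    means <- as.matrix(means)
    gs <- colnames(means)
    ng <- nrow(means)
    if (is.null(significant)) {
        significant <- lapply(utils::combn(sort(gs), 2, FUN = paste,
                                           collapse = "."),
                              function(p) rep(TRUE, ng))
        names(significant) <- utils::combn(sort(gs), 2, FUN = paste,
                                           collapse = ".")
    }
    out <- rep(NA_character_, ng)
    names(out) <- rownames(means)
    for (g in gs) {
        others <- setdiff(gs, g)
        f1 <- means[, g] / ifelse(means[, others[1]] == 0, 0.1,
                                  means[, others[1]])
        f2 <- means[, g] / ifelse(means[, others[2]] == 0, 0.1,
                                  means[, others[2]])
        s1 <- significant[[paste(sort(c(g, others[1])), collapse = ".")]]
        s2 <- significant[[paste(sort(c(g, others[2])), collapse = ".")]]
        hit <- passes_filter[, g] & s1 & s2 &
            ((f1 > fold_high & f2 > fold_low) |
             (f1 > fold_low & f2 > fold_high))
        clash <- hit & !is.na(out)
        if (any(clash))
            stop("gene specific to two groups; fold rule violated for: ",
                 paste(names(out)[clash], collapse = ", "))
        out[hit] <- g
    }
    out
}

#' Full enrichment analysis across neuron groups
#'
#' Runs the expression filter, fold-change computation, pre-screened
#' ANOVA / Tukey HSD / Benjamini-Hochberg chain, and both classification
#' rules (common-circadian enrichment versus the outgroup; specific
#' enrichment within the circadian groups).  A pairwise comparison counts
#' as significant when `bh_q < alpha` and the pair's Tukey p `< alpha`.
#'
#' @param ce a [CircadianExperiment-class] containing the circadian groups
#'   and the outgroup.
#' @param outgroup label of the non-circadian outgroup (default `"TH"`).
#' @param fold_common enrichment fold versus the outgroup (default 5).
#' @param fold_specific two folds of the specificity rule (default
#'   `c(5, 2)`).
#' @param alpha significance level for BH-adjusted ANOVA and Tukey
#'   (default 0.05).
#' @param fold_prescreen pre-screen fold (default 2).
#' @param min_filter RPM threshold of the expression filter (default 10).
#' @return An [EnrichmentResults][results-classes] table over pre-screened
#'   genes: group means, replicate-set means, log2 folds for ordered
#'   pairs, `anova_p`, `bh_q`, Tukey p per pair, LR flags, and the class
#'   labels (`common_circadian` logical; `specific` = group or `NA`).
#' @export
runEnrichment <- function(ce, outgroup = "TH", fold_common = 5,
                          fold_specific = c(5, 2), alpha = 0.05,
                          fold_prescreen = 2, min_filter = 10) {
    gs <- groupNames(ce)
    if (!outgroup %in% gs)
        stop("outgroup '", outgroup, "' not present")
    circ <- setdiff(gs, outgroup)
    filt <- vapply(gs, function(g) expressionFilter(ce, g, min_filter),
                   logical(nrow(ce)))
    stats <- anovaTukeyBH(ce, fold_prescreen = fold_prescreen)
    genes <- stats$gene_id
    gm <- groupMeans(ce)[genes, , drop = FALSE]
    filt <- filt[genes, , drop = FALSE]

    ## ordered-pair log2 folds
    lfc <- list()
    for (a in gs) for (b in setdiff(gs, a))
        lfc[[paste0("lfc_", a, ".", b)]] <- .log2Fold(gm[, a], gm[, b])

    pairSig <- function(a, b) {
        key <- paste(sort(c(a, b)), collapse = ".")
        if (is.null(stats[[key]]))
            stop("internal: no Tukey column for pair ", key)
        stats$bh_q < alpha & stats[[key]] < alpha &
            !is.na(stats$bh_q) & !is.na(stats[[key]])
    }

    ## common-circadian: fold vs outgroup, LR cells masked
    lfcOut <- vapply(circ, function(g) {
        v <- lfc[[paste0("lfc_", g, ".", outgroup)]]
        v[!filt[, g]] <- NA_real_
        v
    }, numeric(length(genes)))
    rownames(lfcOut) <- genes
    sigOut <- vapply(circ, pairSig, b = outgroup, logical(length(genes)))
    common <- classifyCommonCircadian(lfcOut, sigOut, fold_common)

    sigList <- lapply(utils::combn(sort(circ), 2, simplify = FALSE),
                      function(p) pairSig(p[1], p[2]))
    names(sigList) <- utils::combn(sort(circ), 2, FUN = paste,
                                   collapse = ".")
    specific <- classifyGroupSpecific(gm[, circ, drop = FALSE],
        filt[, circ, drop = FALSE], sigList,
        fold_high = fold_specific[1], fold_low = fold_specific[2])

    rsMeans <- do.call(cbind, lapply(gs, function(g) {
        sel <- sampleGroup(ce) == g
        cbind(rowMeans(rpm(ce)[genes, sel & replicateSet(ce) == 1L,
                               drop = FALSE]),
              rowMeans(rpm(ce)[genes, sel & replicateSet(ce) == 2L,
                               drop = FALSE]))
    }))
    colnames(rsMeans) <- paste0("mean_", rep(gs, each = 2), "_set",
                                rep(1:2, length(gs)))

    res <- DataFrame(gene_id = genes)
    for (g in gs) res[[paste0("mean_", g)]] <- gm[, g]
    res <- cbind(res, DataFrame(rsMeans), DataFrame(lfc))
    res$anova_p <- stats$anova_p
    res$bh_q <- stats$bh_q
    for (key in setdiff(colnames(stats), c("gene_id", "anova_p", "bh_q")))
        res[[paste0("tukey_", key)]] <- stats[[key]]
    for (g in gs) res[[paste0("low_reads_", g)]] <- !filt[, g]
    res$common_circadian <- unname(common)
    res$specific <- unname(specific)
    metadata(res) <- list(outgroup = outgroup, alpha = alpha,
        fold_common = fold_common, fold_specific = fold_specific,
        fold_prescreen = fold_prescreen, n_prescreened = length(genes),
        pseudo_rpm = 0.1)
    new("EnrichmentResults", res)
}

#' Flag short intronless enriched transcripts as neuropeptide candidates
#'
#' Neuropeptide genes are typically short and intron-poor; this flags
#' genes that are enriched versus a reference, whose longest isoform is at
#' most `max_length` spliced bp, and (optionally) whose isoforms are all
#' single-exon.
#'
#' @param models a [GeneModels-class].
#' @param enriched character vector of enriched gene ids.
#' @param max_length maximum spliced transcript length in bp
#'   (default 2000).
#' @param require_intronless require all isoforms single-exon
#'   (default TRUE).
#' @return character vector of candidate gene ids.
#' @export
flagCandidateNeuropeptides <- function(models, enriched, max_length = 2000,
                                       require_intronless = TRUE) {
    tg <- txToGene(models)
    lens <- txLengths(models)
    nex <- S4Vectors::elementNROWS(exonsByTranscript(models))
    perGene <- split(seq_along(tg), unname(tg))
    keep <- vapply(perGene, function(ix) {
        max(lens[ix]) <= max_length &&
            (!require_intronless || all(nex[ix] == 1))
    }, logical(1))
    intersect(enriched, names(perGene)[keep])
}
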