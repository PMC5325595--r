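test_that("the 10-RPM filter requires both replicate sets; 5-RPM is strict", {
    mk <- function(set1, set2) {
        m <- matrix(c(rep(set1, 6), rep(set2, 6)), nrow = 1,
                    dimnames = list("g1", NULL))
        CircadianExperiment(m, data.frame(group = "LNv",
            replicate_set = rep(1:2, each = 6), zt = rep(seq(2, 22, 4), 2)))
    }
    expect_true(expressionFilter(mk(12, 11), "LNv"))
    expect_false(expressionFilter(mk(12, 9), "LNv"))   # both sets required
    expect_true(expressionFilter(mk(10, 10), "LNv"))   # inclusive boundary

    expect_false(isExpressed(mk(5, 5), "LNv"))         # strict >
    expect_true(isExpressed(mk(5.1, 5.1), "LNv"))
    expect_false(isExpressed(mk(0, 0), "LNv"))
})

test_that("the common-circadian rule matches its printed worked examples", {
    lfc <- rbind(cry = c(4.04, 2.78, 4.11),     # all three qualify
                 Dh31 = c(4.08, 0.28, 4.04),    # qualifies via two groups
                 onegrp = c(3.0, log2(0.5), log2(0.5)),  # only one: out
                 lr2 = c(2.34, NA, 3.01))       # LR cell does not block
    colnames(lfc) <- c("LNv", "LNd", "DN1")
    got <- classifyCommonCircadian(lfc, fold_threshold = 5)
    expect_identical(got, c(cry = TRUE, Dh31 = TRUE, onegrp = FALSE,
                            lr2 = TRUE))

    ## non-significant cells do not count toward the two groups
    sig <- matrix(TRUE, 4, 3)
    sig[1, c(1, 3)] <- FALSE
    expect_false(classifyCommonCircadian(lfc, sig)[["cry"]])
})

test_that("the group-specific rule applies the 5x / 2x folds", {
    mk <- function(v) matrix(v, 1, 3,
        dimnames = list("g", c("LNv", "LNd", "DN1")))
    filt <- matrix(TRUE, 1, 3, dimnames = list("g", c("LNv", "LNd", "DN1")))
    ## 100 vs 15 and 40: 6.7x and 2.5x -> specific
    expect_identical(unname(classifyGroupSpecific(mk(c(100, 15, 40)), filt)),
                     "LNv")
    ## 100 vs 15 and 60: only 1.67x vs the second -> not specific
    expect_identical(unname(classifyGroupSpecific(mk(c(100, 15, 60)), filt)),
                     NA_character_)
    ## PDF-like: high in LNv, ~0 elsewhere (pseudo-value on denominators)
    expect_identical(unname(classifyGroupSpecific(mk(c(500, 0, 0)), filt)),
                     "LNv")
    ## failing the expression filter in the candidate group blocks the call
    filt0 <- filt; filt0[1, "LNv"] <- FALSE
    expect_identical(unname(classifyGroupSpecific(mk(c(100, 15, 40)), filt0)),
                     NA_character_)
})

test_that("ANOVA/Tukey/BH behaves on constructed group differences", {
    set.seed(31)
    ## 40 null genes plus 10 genes where DN1 is shifted far up
    means <- matrix(50, 50, 4,
                    dimnames = list(sprintf("g%02d", 1:50),
                                    c("LNv", "LNd", "DN1", "TH")))
    means[41:50, "DN1"] <- 50 * 2^6   # >> 10 SD on the log scale
    ce <- makeGroupExperiment(means, cv = 0.2, seed = 31)
    st <- anovaTukeyBH(ce, fold_prescreen = 0)
    shifted <- st$gene_id %in% sprintf("g%02d", 41:50)
    ## shifted genes: the three DN1 pairs significant, others not
    expect_true(all(st$bh_q[shifted] < 0.05))
    for (p in c("DN1.LNd", "DN1.LNv", "DN1.TH"))
        expect_true(all(st[[p]][shifted] < 0.05))
    for (p in c("LNd.LNv", "LNv.TH", "LNd.TH"))
        expect_gt(mean(st[[p]][shifted] > 0.05), 0.9)
    ## BH is monotone in the raw p-values
    o <- order(st$anova_p)
    expect_true(!is.unsorted(st$bh_q[o]))
    ## and never smaller than the raw p
    expect_true(all(st$bh_q >= st$anova_p))
})

test_that("constant genes are excluded from testing with a note", {
    means <- matrix(c(10, 20), 2, 4,
                    dimnames = list(c("flat", "var"),
                                    c("LNv", "LNd", "DN1", "TH")))
    ce <- makeGroupExperiment(means, cv = 0)      # zero variance everywhere
    expect_message(st <- anovaTukeyBH(ce, fold_prescreen = 0),
                   "zero within-group variance")
    expect_true(all(is.na(st$anova_p)))
})

test_that("classification is invariant under sample-column permutation", {
    sim <- simulateExpression(SimulationConfig(n_genes = 120,
        frac_cyclers = 0, dispersion = 0.04, frac_group_restricted = 0.4,
        frac_low_expression = 0, seed = 14))
    ce <- sim$experiment
    set.seed(1)
    perm <- sample(ncol(ce))
    ce2 <- CircadianExperiment(rpm(ce)[, perm],
        as.data.frame(colData(ce))[perm, ])
    e1 <- as.data.frame(suppressMessages(runEnrichment(ce)))
    e2 <- as.data.frame(suppressMessages(runEnrichment(ce2)))
    e2 <- e2[match(e1$gene_id, e2$gene_id), ]
    expect_equal(e1$common_circadian, e2$common_circadian)
    expect_equal(e1$specific, e2$specific)
})

test_that("group-specific genes are recovered from simulation truth", {
    sim <- simulateExpression(SimulationConfig(n_genes = 400,
        frac_cyclers = 0, dispersion = 0.04, frac_group_restricted = 0.3,
        frac_low_expression = 0, seed = 8))
    e <- as.data.frame(suppressMessages(runEnrichment(sim$experiment)))
    tr <- sim$truth
    circ <- c("LNv", "LNd", "DN1")
    expr <- do.call(cbind, lapply(circ, function(g)
        stats::setNames(tr$expressed[tr$group == g],
                        tr$gene_id[tr$group == g])))
    colnames(expr) <- circ
    truthSpec <- rownames(expr)[rowSums(expr) == 1]
    tg <- apply(expr[truthSpec, , drop = FALSE], 1,
                function(r) circ[which(r)])
    called <- stats::setNames(e$specific, e$gene_id)
    hit <- !is.na(called[truthSpec]) & called[truthSpec] == tg
    expect_gt(mean(hit), 0.9)
    others <- setdiff(e$gene_id, truthSpec)
    expect_lt(mean(!is.na(called[others])), 0.05)
})

test_that("neuropeptide candidates are short, intronless and enriched", {
    gl <- GenomicRanges::GRangesList(
        "short.1" = GenomicRanges::GRanges("c", IRanges::IRanges(1, 800),
                                           strand = "+"),
        "multi.1" = GenomicRanges::GRanges("c",
            IRanges::IRanges(c(2001, 2601), c(2300, 2900)), strand = "+"),
        "long.1" = GenomicRanges::GRanges("c",
            IRanges::IRanges(5001, 9000), strand = "+"))
    gm <- GeneModels(gl, c(short.1 = "short", multi.1 = "multi",
                           long.1 = "long"))
    enr <- c("short", "multi", "long")
    expect_identical(flagCandidateNeuropeptides(gm, enr, max_length = 2000),
                     "short")
    ## with introns allowed the 2-exon gene qualifies by length
    expect_setequal(flagCandidateNeuropeptides(gm, enr, max_length = 2000,
                                               require_intronless = FALSE),
                    c("short", "multi"))
    ## non-enriched genes are never flagged
    expect_length(flagCandidateNeuropeptides(gm, character(), 2000), 0)
})
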