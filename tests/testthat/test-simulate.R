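test_that("the default configuration reproduces the study design", {
    sim <- simulateExpression(SimulationConfig(n_genes = 10, seed = 1))
    ce <- sim$experiment
    expect_equal(dim(ce), c(10L, 4L * 2L * 6L))
    expect_setequal(groupNames(ce), c("LNv", "LNd", "DN1", "TH"))
    expect_equal(checkDesign(ce, "LNv"), seq(2, 22, by = 4))
    expect_equal(checkDesign(ce, "DN1"), seq(3, 23, by = 4))  # +1 h offset
    expect_equal(nrow(sim$truth), 40L)  # every gene in every group
})

test_that("identical config and seed give identical output", {
    cfg <- SimulationConfig(n_genes = 40, seed = 77)
    s1 <- simulateExpression(cfg)
    s2 <- simulateExpression(cfg)
    expect_identical(rpm(s1$experiment), rpm(s2$experiment))
    expect_identical(s1$truth, s2$truth)
})

test_that("every simulated library is normalized to one million", {
    sim <- simulateExpression(SimulationConfig(n_genes = 100, seed = 3))
    expect_true(all(abs(colSums(rpm(sim$experiment)) - 1e6) < 1e-3))
})

test_that("the noiseless mean model is exact", {
    ## no cyclers, no noise: constant 12-point series per gene and group
    cfg0 <- SimulationConfig(n_genes = 20, frac_cyclers = 0, dispersion = 0,
                             frac_group_restricted = 0,
                             frac_low_expression = 0, seed = 4)
    sim0 <- simulateExpression(cfg0)
    for (g in groupNames(sim0$experiment)) {
        V <- rpm(sim0$experiment)[, sampleGroup(sim0$experiment) == g]
        expect_true(all(apply(V, 1, function(v) max(v) - min(v)) < 1e-9))
    }

    ## phase programmed on a grid point (ZT10): the per-ZT peak/trough
    ## ratio equals the amplitude fold exactly and the peak sits there
    cfgG <- SimulationConfig(n_genes = 10, frac_cyclers = 1,
                             amplitude_fold = 4, dispersion = 0,
                             phase_dist = "unimodal",
                             phase_param = c(10, 0),
                             frac_group_restricted = 0,
                             frac_low_expression = 0, seed = 5)
    simG <- simulateExpression(cfgG)
    ceG <- simG$experiment
    sel <- sampleGroup(ceG) == "LNv" & replicateSet(ceG) == 1L
    V <- rpm(ceG)[, sel][, order(sampleZT(ceG)[sel])]
    zt <- sort(sampleZT(ceG)[sel])
    for (i in seq_len(nrow(V))) {
        expect_equal(max(V[i, ]) / min(V[i, ]), 4, tolerance = 1e-6)
        expect_equal(zt[which.max(V[i, ])], 10)
    }

    ## random phases: the peak lands on the grid point nearest the
    ## programmed phase
    cfg1 <- SimulationConfig(n_genes = 10, frac_cyclers = 1,
                             amplitude_fold = 4, dispersion = 0,
                             frac_group_restricted = 0,
                             frac_low_expression = 0, seed = 5)
    sim1 <- simulateExpression(cfg1)
    ce <- sim1$experiment
    tr <- sim1$truth
    sel <- sampleGroup(ce) == "LNv" & replicateSet(ce) == 1L
    V <- rpm(ce)[, sel][, order(sampleZT(ce)[sel])]
    zt <- sort(sampleZT(ce)[sel])
    for (i in seq_len(nrow(V))) {
        ph <- tr$phase[tr$group == "LNv" & tr$gene_id == rownames(V)[i]]
        dist <- abs(((zt - ph + 12) %% 24) - 12)
        expect_equal(unname(which.max(V[i, ])), which.min(dist))
    }
})

test_that("parameter recovery: cycling detection finds programmed cyclers", {
    ## moderate size here; the full-scale recovery run lives in the
    ## acceptance suite
    cfg <- SimulationConfig(n_genes = 300, frac_cyclers = 0.2,
                            amplitude_fold = 4, dispersion = 0.04,
                            frac_group_restricted = 0,
                            frac_low_expression = 0, seed = 21)
    sim <- simulateExpression(cfg)
    cyc <- as.data.frame(runCycling(sim$experiment, groups = "LNv"))
    tr <- sim$truth[sim$truth$group == "LNv", ]
    m <- merge(cyc, tr, by = "gene_id")
    hc <- m$confidence == "HC"
    expect_gt(mean(hc[m$is_cycler]), 0.8)
    expect_lt(mean(hc[!m$is_cycler]), 0.05)
    det <- m[hc & m$is_cycler, ]
    perr <- abs(((det$phase.x - det$phase.y + 12) %% 24) - 12)
    expect_gt(mean(perr <= 2), 0.9)
})

test_that("read placement respects targets, exons and the 3' bias", {
    gm <- simulateGeneModels(40, seed = 6)
    genes <- geneNames(gm)
    cfg <- SimulationConfig(n_genes = 40, library_size = 2e5,
                            three_prime_bias = 30, seed = 12)
    target <- stats::setNames(rep(1e6 / (length(genes) - 1), length(genes)),
                              genes)
    target[genes[1]] <- 0   # zero target -> zero reads
    reads <- simulateReads(gm, target, cfg)
    expect_equal(sum(reads$gene_id == genes[1]), 0)
    expect_equal(length(reads), 2e5)

    ## every read 3' position falls inside an exon of its gene
    ex <- exonsByTranscript(gm)
    expect_true(all(IRanges::overlapsAny(reads, unlist(ex))))

    ## decay length << 300 bp: >= 95% of reads inside the 3' windows
    ## (brute-force membership via the window set)
    win <- buildWindows(gm, 300)
    expect_gt(mean(IRanges::overlapsAny(reads, win)), 0.95)

    ## missing model is an error naming the gene
    expect_error(simulateReads(gm, c(target, ghost = 5), cfg), "ghost")
})

test_that("programmed morning/evening ratio shifts are recoverable", {
    ## truth with 50 morning- and 50 evening-phase LNv cyclers
    mkTruth <- function() data.frame(
        gene_id = sprintf("g%03d", 1:120), group = "LNv", expressed = TRUE,
        is_cycler = TRUE,
        phase = c(runif(50, 3, 8), runif(50, 14, 19), runif(20, 9, 13)),
        amplitude_fold = 4, baseline = 50)
    pOne <- function(effect) {
        tr <- mkTruth()
        rt <- simulateLsRatios(tr, effect_log2 = effect, sd_log2 = 1)
        m <- merge(tr, rt)
        morn <- m$phase >= 3 & m$phase <= 8
        eve <- m$phase >= 14 & m$phase <= 19
        t.test(log2(m$ratio[morn]), log2(m$ratio[eve]))$p.value
    }
    set.seed(99)
    pNull <- replicate(200, pOne(0))
    expect_lt(mean(pNull < 0.05), 0.12)          # ~5% under no effect
    pShift <- replicate(200, pOne(1))
    expect_gte(mean(pShift < 0.01), 0.95)        # 1-log2 shift detected

    ## semantics: morning-phase genes sit below 1 (higher in small cells)
    set.seed(100)
    tr <- mkTruth()
    rt <- simulateLsRatios(tr, effect_log2 = 2, sd_log2 = 0.1)
    m <- merge(tr, rt)
    expect_lt(median(m$ratio[m$phase >= 3 & m$phase <= 8]), 1)
    expect_gt(median(m$ratio[m$phase >= 14 & m$phase <= 19]), 1)
})

test_that("configuration invariants are enforced", {
    expect_error(SimulationConfig(frac_cyclers = 1.2), "fractions")
    expect_error(SimulationConfig(amplitude_fold = 0.5), "amplitude")
    expect_error(SimulationConfig(
        zt_grids = list(LNv = c(2, 6, 10, 14, 18),
                        LNd = seq(2, 22, 4), DN1 = seq(3, 23, 4),
                        TH = seq(2, 22, 4))), "6 points")
})
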