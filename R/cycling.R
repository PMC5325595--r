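#' @include AllClasses.R accessors.R
#' @importFrom stats fft setNames
NULL

## ---------------------------------------------------------------------
## max-normalization

#' Normalize a 12-point series to the maximum of each replicate set
#'
#' Each 6-timepoint replicate set is divided by its own maximum, putting
#' the two independent days on a common 0-1 scale before Fourier scoring.
#' An all-zero set maps to all zeros.
#'
#' @param values numeric vector of 12 RPM values ordered (replicate set 1
#'   at ascending ZT, then set 2 at ascending ZT).
#' @return numeric vector of 12 normalized values.
#' @examples
#' maxNormalize(c(2, 4, 6, 8, 10, 12, 1, 2, 3, 4, 5, 10))
#' @export
maxNormalize <- function(values) {
    stopifnot(length(values) == 12)
    out <- values
    for (s in list(1:6, 7:12)) {
        m <- max(values[s])
        out[s] <- if (m > 0) values[s] / m else 0
    }
    out
}

## ---------------------------------------------------------------------
## F24: 24-h Fourier score and phase

#' F24 score and phase of a normalized 12-point series
#'
#' The two max-normalized 6-point sets are treated as two consecutive 24-h
#' days sampled every 4 h, i.e. one 12-point series spanning 48 h.  Its
#' discrete Fourier transform has the 24-h component at harmonic 2 (of 12);
#' the F24 score is the power at that harmonic over the total power of
#' harmonics 1-6 (all non-DC frequencies, Nyquist counted once), so F24 is
#' 1 for a pure 24-h cosine repeated identically on both days and 0 for a
#' constant or a pure 12-h oscillation.  The phase is the zeitgeber time at
#' which the fitted 24-h cosine peaks, computed from the argument of the
#' harmonic-2 coefficient in absolute ZT (so groups sampled on an offset
#' grid are directly comparable).
#'
#' @param values 12 normalized values, ordered (set 1 ascending ZT, set 2
#'   ascending ZT); see [maxNormalize()].
#' @param zt the group's 6-point ZT grid (hours), ascending.
#' @return list with `f24` (in \[0, 1\]) and `phase` (ZT hours in
#'   \[0, 24), `NA` when the series has no AC power).
#' @examples
#' zt <- seq(2, 22, by = 4)
#' v <- rep(0.5 + 0.5 * cos(2 * pi * (zt - 8) / 24), 2)
#' f24Score(v, zt)
#' @export
f24Score <- function(values, zt) {
    stopifnot(length(values) == 12, length(zt) == 6)
    X <- fft(values)
    pw <- Mod(X[2:7])^2
    tot <- sum(pw)
    if (tot < 1e-300)
        return(list(f24 = 0, phase = NA_real_))
    f24 <- pw[2] / tot
    phase <- (zt[1] - Arg(X[3]) * 24 / (2 * pi)) %% 24
    if (Mod(X[3]) < 1e-12) phase <- NA_real_
    list(f24 = f24, phase = phase)
}

#' Peak/trough amplitude fold of a raw 12-point series
#'
#' Averages the two replicate values at each ZT of the grid and returns
#' the ratio of the largest to the smallest per-ZT mean, with a 0.1-RPM
#' floor on the denominator.  Computed on unnormalized RPM: per-set max
#' normalization would erase cross-set amplitude information.
#'
#' @inheritParams f24Score
#' @param values 12 raw RPM values (set 1 ascending ZT, then set 2).
#' @return amplitude fold (>= 1 up to the denominator floor).
#' @export
amplitudeFold <- function(values, zt) {
    stopifnot(length(values) == 12)
    perZT <- (values[1:6] + values[7:12]) / 2
    max(perZT) / max(min(perZT), 0.1)
}

## ---------------------------------------------------------------------
## JTK-style rank test with exact null
##
## The observed 12-point series is compared, via Kendall's S, to cosine
## reference waveforms of the target period evaluated on the doubled ZT
## grid, one reference per lag.  References carry ties (each ZT appears in
## both replicate sets, and cosine symmetry adds more), so the exact null
## distribution of S under random orderings of the observations is the
## distribution of cross-group inversions of a random permutation with the
## reference's tie-group sizes -- the coefficients of the Gaussian
## (q-)multinomial, computed here by polynomial convolution.

.polyMul <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a))
        out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
    out
}

## Gaussian binomial coefficient [m choose k]_q as a coefficient vector
## over q^0 .. q^{k(m-k)}; recurrence [m,k] = [m-1,k-1] + q^k [m-1,k].
.qBinomPoly <- function(m, k) {
    row <- vector("list", k + 1L)
    row[[1L]] <- 1
    for (i in seq_len(m)) {
        new <- vector("list", k + 1L)
        new[[1L]] <- 1
        for (j in seq_len(min(i, k))) {
            a <- row[[j]]
            b <- if (j + 1L <= length(row)) row[[j + 1L]] else NULL
            if (is.null(b)) { new[[j + 1L]] <- a; next }
            bq <- c(numeric(j), b)
            L <- max(length(a), length(bq))
            new[[j + 1L]] <- c(a, numeric(L - length(a))) +
                             c(bq, numeric(L - length(bq)))
        }
        row <- new
    }
    row[[k + 1L]]
}

#' Exact null distribution of Kendall's S against a tied reference
#'
#' For a reference ranking with tie-group sizes `tieSizes` (summing to n)
#' and observations without ties, the number of discordant pairs D of a
#' uniformly random ordering is distributed as the coefficients of the
#' Gaussian multinomial \eqn{[n; t_1,\dots,t_g]_q}; S = K - 2D with K the
#' number of reference-untied pairs.  Returns the exact distribution,
#' from which upper-tail p-values of S are read off.
#'
#' @param tieSizes integer vector of reference tie-group sizes.
#' @return list with `K` (max attainable S), `d` (0..K), `count`
#'   (number of orderings with that many discordant pairs) and `ptail`
#'   (`ptail[d+1]` = P(D <= d) = P(S >= K - 2d)).
#' @examples
#' jtkNullDistribution(c(2, 4, 4, 2))  # a 12-point cosine reference
#' @export
jtkNullDistribution <- function(tieSizes) {
    t <- as.integer(tieSizes)
    stopifnot(all(t >= 1))
    s <- cumsum(t)
    poly <- 1
    for (b in seq_along(t)[-1L])
        poly <- .polyMul(poly, .qBinomPoly(s[b], t[b]))
    K <- sum(outer(t, t)[upper.tri(outer(t, t))])
    stopifnot(length(poly) == K + 1L)
    list(K = K, d = 0:K, count = poly, ptail = cumsum(poly) / sum(poly))
}

.jtkRefs <- function(zt, period = 24, lag_step = 4) {
    lags <- seq(0, period - lag_step, by = lag_step)
    refs <- lapply(lags, function(l)
        round(rep(cos(2 * pi * (zt - l) / period), 2), 9))
    sig <- vapply(refs, function(r)
        paste(rank(r, ties.method = "min"), collapse = ","), character(1))
    keep <- !duplicated(sig)
    list(lags = lags, refs = refs, distinct = keep,
         n_distinct = sum(keep))
}

.kendallS <- function(values, ref) {
    n <- length(values)
    ut <- upper.tri(matrix(0, n, n))
    so <- sign(outer(values, values, FUN = function(a, b) b - a))
    sr <- sign(outer(ref, ref, FUN = function(a, b) b - a))
    sum(so[ut] * sr[ut])
}

#' JTK-style rhythmicity test for one series
#'
#' Compares the observed 12-point series with cosine references of the
#' given period at every lag on the lag grid via Kendall's S, evaluates
#' each lag's exact one-sided p-value P(S >= s) under the reference's
#' tie-aware null (see [jtkNullDistribution()]), and Bonferroni-multiplies
#' the best lag's p by the number of rank-distinct references.  The lag
#' grid covers all phases including the antiphase, which is why the
#' per-lag tail is one-sided.  As a rank statistic the p-value is
#' invariant under strictly monotone transforms of the observations;
#' a constant series scores S = 0 at every lag and returns p = 1.
#'
#' @param values 12 RPM values ordered (set 1 ascending ZT, then set 2).
#' @param zt the group's 6-point ZT grid, ascending.
#' @param period reference period in hours (default 24).
#' @param lag_step lag grid step in hours (default the 4-h sampling
#'   interval).
#' @return list with `p` (Bonferroni-adjusted, capped at 1), `best_lag`
#'   (hours), `n_refs` (Bonferroni factor) and `per_lag` (data.frame of
#'   lag, S, exact p).
#' @examples
#' zt <- seq(2, 22, by = 4)
#' jtkTest(rep(cos(2 * pi * (zt - 8) / 24), 2) + 2, zt)
#' @export
jtkTest <- function(values, zt, period = 24, lag_step = 4) {
    stopifnot(length(values) == 12, length(zt) == 6)
    rf <- .jtkRefs(zt, period, lag_step)
    res <- lapply(seq_along(rf$lags), function(i) {
        ref <- rf$refs[[i]]
        tie <- as.integer(table(ref))
        null <- jtkNullDistribution(tie)
        S <- .kendallS(values, ref)
        d <- min(floor((null$K - S) / 2), null$K)
        c(S = S, p = null$ptail[d + 1L])
    })
    tab <- data.frame(lag = rf$lags,
                      S = vapply(res, `[[`, numeric(1), "S"),
                      p = vapply(res, `[[`, numeric(1), "p"))
    i <- which.min(tab$p)
    list(p = min(1, rf$n_distinct * tab$p[i]), best_lag = tab$lag[i],
         n_refs = rf$n_distinct, per_lag = tab)
}

## ---------------------------------------------------------------------
## whole-matrix cycling analysis

## fast path: S for all genes at once, one reference
.kendallSMatrix <- function(V, ref) {
    n <- length(ref)
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sr <- sign(ref[pr[, 2]] - ref[pr[, 1]])
    keep <- sr != 0
    pr <- pr[keep, , drop = FALSE]
    sr <- sr[keep]
    SO <- sign(V[, pr[, 2], drop = FALSE] - V[, pr[, 1], drop = FALSE])
    as.vector(SO %*% sr)
}

#' Detect cycling transcripts in every neuron group
#'
#' For each requested group the 12 samples are ordered by replicate set
#' and ZT, each replicate set is max-normalized, and every gene is scored
#' by both methods: the Fourier F24 score with fitted phase, and the
#' JTK-style exact rank test.  A gene passes the Fourier criterion when
#' `f24 > f24_min`, amplitude fold `> amp_min` and mean RPM `> mean_min`;
#' it passes the JTK criterion when `jtk_p < jtk_alpha` with the same
#' amplitude and expression cutoffs.  Genes passing both are
#' high-confidence (HC) cyclers, genes passing exactly one low-confidence
#' (LC), all others non-cycling.
#'
#' @param ce a [CircadianExperiment-class] with a complete 2 x 6 design
#'   per group.
#' @param groups groups to analyse (default all present).
#' @param f24_min,amp_min,mean_min,jtk_alpha the cycling cutoffs
#'   (defaults 0.5, 2, 5, 0.05).
#' @param period reference period, hours.
#' @return A [CyclingResults][results-classes] table with one row per gene
#'   per group: `gene_id`, `group`, `f24`, `phase`, `amplitude_fold`,
#'   `mean_rpm`, `jtk_p`, `jtk_lag`, `fourier_pass`, `jtk_pass`,
#'   `confidence` (`"HC"`, `"LC"` or `"none"`).  `metadata()` records the
#'   cutoffs and a per-group summary with HC/LC counts and the overlap
#'   fraction of the two methods.
#' @export
runCycling <- function(ce, groups = NULL, f24_min = 0.5, amp_min = 2,
                       mean_min = 5, jtk_alpha = 0.05, period = 24) {
    if (is.null(groups)) groups <- groupNames(ce)
    out <- list()
    for (g in groups) {
        zt <- checkDesign(ce, g)
        sel <- which(sampleGroup(ce) == g)
        ord <- sel[order(replicateSet(ce)[sel], sampleZT(ce)[sel])]
        V <- rpm(ce)[, ord, drop = FALSE]
        ng <- nrow(V)

        ## max-normalize each replicate set rowwise
        N <- V
        for (s in list(1:6, 7:12)) {
            mx <- apply(V[, s, drop = FALSE], 1, max)
            N[, s] <- V[, s, drop = FALSE] / pmax(mx, .Machine$double.xmin)
            N[mx == 0, s] <- 0
        }

        ## F24 on all genes at once
        X <- t(stats::mvfft(t(N)))
        pw <- Mod(X[, 2:7, drop = FALSE])^2
        tot <- rowSums(pw)
        f24 <- ifelse(tot > 1e-300, pw[, 2] / tot, 0)
        phase <- (zt[1] - Arg(X[, 3]) * 24 / (2 * pi)) %% 24
        phase[tot <= 1e-300 | Mod(X[, 3]) < 1e-12] <- NA_real_

        perZT <- (V[, 1:6, drop = FALSE] + V[, 7:12, drop = FALSE]) / 2
        amp <- apply(perZT, 1, max) / pmax(apply(perZT, 1, min), 0.1)
        meanRpm <- rowMeans(V)

        ## JTK across all genes: distinct references share a cached null
        rf <- .jtkRefs(zt, period)
        pmin_ <- rep(Inf, ng)
        blag <- rep(NA_real_, ng)
        nullCache <- list()
        for (i in which(rf$distinct)) {
            ref <- rf$refs[[i]]
            key <- paste(sort(table(ref)), collapse = ",")
            if (is.null(nullCache[[key]]))
                nullCache[[key]] <- jtkNullDistribution(as.integer(table(ref)))
            null <- nullCache[[key]]
            S <- .kendallSMatrix(V, ref)
            d <- pmin(floor((null$K - S) / 2), null$K)
            p <- null$ptail[d + 1L]
            upd <- p < pmin_
            blag[upd] <- rf$lags[i]
            pmin_[upd] <- p[upd]
        }
        jtkP <- pmin(1, rf$n_distinct * pmin_)

        fourierPass <- f24 > f24_min & amp > amp_min & meanRpm > mean_min
        jtkPass <- jtkP < jtk_alpha & amp > amp_min & meanRpm > mean_min
        conf <- ifelse(fourierPass & jtkPass, "HC",
                ifelse(fourierPass | jtkPass, "LC", "none"))
        out[[g]] <- DataFrame(gene_id = rownames(V), group = g, f24 = f24,
            phase = phase, amplitude_fold = amp, mean_rpm = meanRpm,
            jtk_p = jtkP, jtk_lag = blag, fourier_pass = fourierPass,
            jtk_pass = jtkPass, confidence = conf)
    }
    res <- do.call(rbind, unname(out))
    rownames(res) <- NULL
    summ <- do.call(rbind, lapply(groups, function(g) {
        r <- res[res$group == g, ]
        both <- sum(r$fourier_pass & r$jtk_pass)
        either <- sum(r$fourier_pass | r$jtk_pass)
        data.frame(group = g, hc = both, lc = either - both,
                   overlap_fraction = if (either) both / either else NA_real_)
    }))
    metadata(res) <- list(cutoffs = list(f24_min = f24_min,
        amp_min = amp_min, mean_min = mean_min, jtk_alpha = jtk_alpha,
        period = period), summary = summ)
    new("CyclingResults", res)
}
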