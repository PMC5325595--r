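#' @include AllClasses.R accessors.R
NULL

#' Build 3'-end counting windows for a set of gene models
#'
#' For every isoform, a terminal window extends `window_size` spliced bp
#' upstream from the isoform 3' end, projected through the exon structure
#' to genomic coordinates (so a window spanning a splice junction becomes
#' several genomic intervals).  A transcript shorter than `window_size`
#' yields a window truncated to the transcript length.  Windows of the
#' isoforms of one gene are merged where they overlap, so a read 3'
#' position shared by two isoforms is counted once for the gene.
#'
#' @param models a [GeneModels-class].
#' @param window_size window length in transcript bp (default 300).
#' @return stranded `GRanges` of window pieces with metadata column
#'   `gene_id`; pieces of one gene are disjoint.
#' @export
buildWindows <- function(models, window_size = 300) {
    ex <- exonsByTranscript(models)
    tg <- txToGene(models)
    pieces <- list()
    for (t in names(ex)) {
        e <- ex[[t]]
        w <- GenomicRanges::width(e)
        minus <- as.character(GenomicRanges::strand(e))[1] == "-"
        ord <- if (minus) seq_along(w) else rev(seq_along(w))
        remaining <- min(window_size, sum(w))
        st <- en <- integer(0)
        for (i in ord) {
            if (remaining <= 0) break
            take <- min(remaining, w[i])
            if (minus) {           # 3' end is leftmost; walk left to right
                st <- c(st, GenomicRanges::start(e)[i])
                en <- c(en, GenomicRanges::start(e)[i] + take - 1L)
            } else {               # 3' end is rightmost; walk right to left
                st <- c(st, GenomicRanges::end(e)[i] - take + 1L)
                en <- c(en, GenomicRanges::end(e)[i])
            }
            remaining <- remaining - take
        }
        pieces[[t]] <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(e)[1], IRanges::IRanges(st, en),
            strand = if (minus) "-" else "+", gene_id = tg[[t]])
    }
    gr <- do.call(c, unname(pieces))
    ## merge overlapping windows within a gene
    byGene <- GenomicRanges::split(GenomicRanges::granges(gr), gr$gene_id)
    merged <- GenomicRanges::reduce(byGene)
    out <- unlist(merged, use.names = FALSE)
    mcols(out)$gene_id <- rep(names(merged),
                              S4Vectors::elementNROWS(merged))
    out
}

#' Count read 3' positions in gene windows
#'
#' A read is counted for a gene when its 3'-terminal position falls inside
#' one of the gene's windows on the matching strand.  A position inside
#' windows of several genes counts once per gene; the number of such
#' ambiguous reads and of reads matching no window is reported.  Counting
#' is a pure set operation: deterministic and independent of read order.
#'
#' @param reads width-1 stranded `GRanges` of read 3' positions; an
#'   optional metadata column `sample` splits the counts into columns.
#' @param windows window `GRanges` from [buildWindows()].
#' @return integer matrix genes x samples with attributes
#'   `ambiguous_reads` and `unassigned_reads` (per-sample counts).
#' @export
countInWindows <- function(reads, windows) {
    genes <- unique(windows$gene_id)
    smp <- if (!is.null(mcols(reads)$sample))
        as.character(mcols(reads)$sample) else rep("S1", length(reads))
    samples <- unique(smp)
    if (!length(samples)) samples <- "S1"
    hits <- GenomicRanges::findOverlaps(reads, windows, ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(hits)
    gh <- windows$gene_id[S4Vectors::subjectHits(hits)]
    ## one (read, gene) pair even if the read sits in two pieces of a gene
    key <- !duplicated(paste(qh, gh))
    qh <- qh[key]; gh <- gh[key]
    cnt <- table(factor(gh, levels = genes), factor(smp[qh], levels = samples))
    out <- matrix(as.integer(cnt), nrow = length(genes),
                  dimnames = list(genes, samples))
    nGenes <- tabulate(qh, nbins = length(reads))
    attr(out, "ambiguous_reads") <-
        table(factor(smp[nGenes >= 2], levels = samples))
    attr(out, "unassigned_reads") <-
        table(factor(smp[nGenes == 0], levels = samples))
    out
}

#' Reads-per-million normalization
#'
#' Scales each sample (column) so counts become reads per one million
#' counted reads; every column of the result sums to 1e6.  The denominator
#' is the window-assigned read total of that sample.
#'
#' @param counts numeric matrix genes x samples of raw window counts.
#' @return numeric matrix of RPM values.
#' @export
normalizeRPM <- function(counts) {
    tot <- colSums(counts)
    zero <- which(tot == 0)
    if (length(zero))
        stop("sample with zero counted reads: ",
             paste(colnames(counts)[zero], collapse = ", "))
    sweep(counts, 2, tot, "/") * 1e6
}

#' 3'-end window quantification
#'
#' Chains [buildWindows()], [countInWindows()] and [normalizeRPM()]:
#' the terminal-window strategy of 3'-tag quantification, which counts
#' reads only near isoform 3' ends and is therefore insensitive to gene
#' length.
#'
#' @inheritParams buildWindows
#' @inheritParams countInWindows
#' @return list with `rpm` (matrix), `counts` (matrix with ambiguity
#'   attributes) and `windows` (`GRanges`).
#' @export
quantifyThreePrime <- function(reads, models, window_size = 300) {
    windows <- buildWindows(models, window_size)
    counts <- countInWindows(reads, windows)
    list(rpm = normalizeRPM(counts), counts = counts, windows = windows)
}
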