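#' @include AllClasses.R
NULL

#' Accessors for the circadian design
#'
#' `sampleGroup()`, `replicateSet()` and `sampleZT()` extract the design
#' columns; `rpm()` the expression assay.  `groupNames()` lists the groups
#' present.
#'
#' @param x a [CircadianExperiment-class].
#' @return vectors parallel to the columns of `x` (a matrix for `rpm`).
#' @name design-accessors
NULL

#' @rdname design-accessors
#' @export
sampleGroup <- function(x) as.character(colData(x)$group)

#' @rdname design-accessors
#' @export
replicateSet <- function(x) as.integer(colData(x)$replicate_set)

#' @rdname design-accessors
#' @export
sampleZT <- function(x) as.numeric(colData(x)$zt)

#' @rdname design-accessors
#' @export
rpm <- function(x) assay(x, "rpm")

#' @rdname design-accessors
#' @export
groupNames <- function(x) unique(sampleGroup(x))

#' Check the complete two-set six-timepoint grid for a group
#'
#' Downstream statistics assume the full design; this fails fast when a
#' group's samples do not form two replicate sets of six distinct ZTs at
#' 4-h spacing.
#'
#' @param x a [CircadianExperiment-class].
#' @param group group label.
#' @return invisibly, the sorted ZT grid of the group.
#' @export
checkDesign <- function(x, group) {
    sel <- sampleGroup(x) == group
    if (!any(sel))
        stop("no samples for group '", group, "'")
    zt <- sampleZT(x)[sel]
    rs <- replicateSet(x)[sel]
    grid <- NULL
    for (s in 1:2) {
        z <- sort(zt[rs == s])
        if (length(z) != 6 || anyDuplicated(z) ||
            any(abs(diff(z) - 4) > 1e-9))
            stop("group '", group, "', replicate set ", s,
                 ": need 6 distinct ZTs at 4-h spacing, got {",
                 paste(z, collapse = ", "), "}")
        if (is.null(grid)) grid <- z
        else if (!isTRUE(all.equal(grid, z)))
            stop("group '", group,
                 "': replicate sets sampled on different ZT grids")
    }
    invisible(grid)
}

setMethod("show", "CircadianExperiment", function(object) {
    callNextMethod()
    g <- table(sampleGroup(object))
    cat("groups:", paste(sprintf("%s(%d)", names(g), g), collapse = " "),
        "\n")
})

setMethod("show", "GeneModels", function(object) {
    cat(class(object), "with", length(unique(object@txGene)), "genes /",
        length(object@exons), "transcripts\n")
})

#' Transcripts and genes of a GeneModels object
#'
#' @param x a [GeneModels-class].
#' @return `txNames()`/`geneNames()` return character vectors;
#'   `exonsByTranscript()` the underlying `GRangesList`; `txToGene()` the
#'   transcript-to-gene map.
#' @name genemodel-accessors
NULL

#' @rdname genemodel-accessors
#' @export
txNames <- function(x) names(x@exons)

#' @rdname genemodel-accessors
#' @export
geneNames <- function(x) unique(unname(x@txGene))

#' @rdname genemodel-accessors
#' @export
exonsByTranscript <- function(x) x@exons

#' @rdname genemodel-accessors
#' @export
txToGene <- function(x) x@txGene

#' Strand-aware 3' ends of every isoform
#'
#' The 3' end of a transcript is its last base in transcription order:
#' the maximum coordinate on the + strand, the minimum on the - strand.
#'
#' @param x a [GeneModels-class].
#' @return width-1 `GRanges`, one range per transcript, with metadata
#'   columns `tx_id` and `gene_id`.
#' @export
threePrimeEnds <- function(x) {
    ex <- x@exons
    gr <- unlist(range(ex), use.names = FALSE)
    plus <- as.character(GenomicRanges::strand(gr)) == "+"
    pos <- ifelse(plus, GenomicRanges::end(gr), GenomicRanges::start(gr))
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
        IRanges::IRanges(pos, width = 1), strand = GenomicRanges::strand(gr))
    mcols(out)$tx_id <- names(ex)
    mcols(out)$gene_id <- unname(x@txGene[names(ex)])
    out
}

#' Spliced length of every isoform
#'
#' @param x a [GeneModels-class].
#' @return named numeric vector of summed exon widths per transcript.
#' @export
txLengths <- function(x) {
    vapply(seq_along(x@exons),
           function(i) sum(GenomicRanges::width(x@exons[[i]])), numeric(1)) |>
        stats::setNames(names(x@exons))
}
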