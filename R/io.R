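#' @include AllClasses.R
#' @importFrom utils read.delim write.table
NULL

## Expression-table dialect: tab-separated, first column `gene_id`, one
## column per library.  Sample metadata is carried in the header as
## `sample_id|group|replicate_set|zt` (pipe-delimited) so a single file is
## self-describing; alternatively a sidecar table may supply the metadata
## and the header then holds bare sample ids.

.parseSampleHeader <- function(h) {
    parts <- strsplit(h, "|", fixed = TRUE)
    bad <- which(lengths(parts) != 4)
    if (length(bad))
        stop("malformed sample column header '", h[bad[1]],
             "': expected sample_id|group|replicate_set|zt")
    m <- do.call(rbind, parts)
    rs <- suppressWarnings(as.integer(m[, 3]))
    zt <- suppressWarnings(as.numeric(m[, 4]))
    bad <- which(is.na(rs) | is.na(zt))
    if (length(bad))
        stop("malformed sample column header '", h[bad[1]],
             "': non-numeric replicate_set or zt")
    DataFrame(sample_id = m[, 1], group = m[, 2], replicate_set = rs,
              zt = zt)
}

#' Read an expression table
#'
#' Reads a genes-by-samples TSV of reads-per-million values into a
#' [CircadianExperiment-class].  Sample metadata is taken from the
#' pipe-delimited column headers, or from `metadata` (a data.frame or path
#' to a TSV with columns `sample_id`, `group`, `replicate_set`, `zt`) when
#' the headers are bare sample ids.
#'
#' @param path TSV file.
#' @param metadata optional sidecar sample table (data.frame or path).
#' @return A [CircadianExperiment-class].
#' @seealso [writeExpressionTable()]
#' @export
readExpressionTable <- function(path, metadata = NULL) {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (colnames(tab)[1] != "gene_id")
        stop("first column must be 'gene_id', found '", colnames(tab)[1], "'")
    genes <- as.character(tab[[1]])
    dup <- genes[duplicated(genes)]
    if (length(dup))
        stop("duplicate gene_id: ", dup[1])
    vals <- tab[, -1, drop = FALSE]
    if (is.null(metadata)) {
        sd <- .parseSampleHeader(colnames(vals))
    } else {
        if (is.character(metadata))
            metadata <- read.delim(metadata, stringsAsFactors = FALSE)
        sd <- as(metadata, "DataFrame")
        i <- match(colnames(vals), sd$sample_id)
        if (anyNA(i))
            stop("sample '", colnames(vals)[which(is.na(i))[1]],
                 "' missing from metadata")
        sd <- sd[i, ]
    }
    m <- as.matrix(vals)
    if (!is.numeric(m)) {
        j <- which(!vapply(vals, is.numeric, logical(1)))[1]
        i <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
        stop("non-numeric value for gene '", genes[i], "', sample '",
             sd$sample_id[j], "'")
    }
    if (any(m < 0, na.rm = TRUE)) {
        idx <- which(m < 0, arr.ind = TRUE)[1, ]
        stop("negative value for gene '", genes[idx[1]], "', sample '",
             sd$sample_id[idx[2]], "'")
    }
    rownames(m) <- genes
    colnames(m) <- sd$sample_id
    CircadianExperiment(m, sd)
}

#' Write an expression table
#'
#' Writes the `rpm` assay as a TSV whose column headers embed the sample
#' metadata (`sample_id|group|replicate_set|zt`), the dialect
#' [readExpressionTable()] reads back.
#'
#' @param x a [CircadianExperiment-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeExpressionTable <- function(x, path) {
    hdr <- paste(colnames(x), sampleGroup(x), replicateSet(x),
                 format(sampleZT(x), trim = TRUE), sep = "|")
    m <- rpm(x)
    out <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    colnames(out) <- c("gene_id", hdr)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene models from GTF or BED12
#'
#' GTF exon records are grouped by `transcript_id` and mapped to genes via
#' `gene_id`.  BED12 blocks become exons; the gene of a transcript is taken
#' from `tx2gene` when given, otherwise the transcript name with a trailing
#' `.N` / `-RX` suffix stripped.  GTF's 1-based closed and BED's 0-based
#' half-open coordinates both end up in the 1-based closed convention of
#' `GRanges`, so both encodings of a transcript yield the identical model.
#'
#' @param path GTF (`.gtf`) or BED12 (`.bed`) file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @param tx2gene optional named character vector transcript -> gene.
#' @return A [GeneModels-class].
#' @export
readGeneModels <- function(path, format = c("auto", "gtf", "bed12"),
                           tx2gene = NULL) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
            "gtf" else "bed12"
    if (format == "gtf") {
        gr <- rtracklayer::import(path, format = "gtf")
        gr <- gr[gr$type == "exon"]
        if (!length(gr))
            stop("no exon records in ", path)
        ex <- GenomicRanges::split(GenomicRanges::granges(gr),
                                   gr$transcript_id)
        txg <- vapply(split(gr$gene_id, gr$transcript_id),
                      function(g) g[1], character(1))
    } else {
        b <- rtracklayer::import(path, format = "bed")
        ex <- rtracklayer::blocks(b)
        names(ex) <- b$name
        if (is.null(tx2gene))
            tx2gene <- stats::setNames(
                sub("([.-](RA|RB|RC|RD|[0-9]+))$", "", b$name), b$name)
        txg <- tx2gene[names(ex)]
    }
    GeneModels(ex, txg[names(ex)])
}

#' Read / write single-read 3'-position records (BED6)
#'
#' Each record is the 3'-terminal genomic position of one aligned read,
#' stored as a width-1 stranded interval.
#'
#' @param path BED6 file.
#' @return `readReadPositions()`: a width-1 stranded `GRanges`.
#' @export
readReadPositions <- function(path) {
    gr <- rtracklayer::import(path, format = "bed")
    if (any(GenomicRanges::width(gr) != 1))
        gr <- GenomicRanges::resize(gr, 1, fix = "end")
    gr
}

#' @rdname readReadPositions
#' @param reads width-1 stranded `GRanges` of read 3' positions.
#' @export
writeReadPositions <- function(reads, path) {
    rtracklayer::export(reads, path, format = "bed")
    invisible(path)
}

#' Write result tables and a JSON summary
#'
#' Writes each table in `tables` as `<name>.tsv` (deterministic column
#' order, header always present) and a `summary.json` with per-table row
#' counts plus, for cycling results, per-group counts of high- and
#' low-confidence cyclers.
#'
#' @param tables named list of data.frame-like tables.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeResults <- function(tables, out_dir) {
    if (!dir.exists(out_dir))
        dir.create(out_dir, recursive = TRUE)
    paths <- character()
    summary <- list()
    for (nm in names(tables)) {
        tab <- as.data.frame(tables[[nm]])
        p <- file.path(out_dir, paste0(nm, ".tsv"))
        write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
        s <- list(rows = nrow(tab))
        if (all(c("group", "confidence") %in% colnames(tab))) {
            s$hc_per_group <- as.list(table(
                tab$group[tab$confidence == "HC"]))
            s$lc_per_group <- as.list(table(
                tab$group[tab$confidence == "LC"]))
        }
        summary[[nm]] <- s
    }
    sp <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, sp, auto_unbox = TRUE, pretty = TRUE)
    invisible(c(paths, sp))
}
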