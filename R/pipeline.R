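#' @include AllClasses.R
NULL

#' Run the full analysis pipeline
#'
#' Chains quantification (optional), enrichment, cycling detection and
#' phase summaries, writing result tables and a JSON summary to
#' `out_dir` when given.
#'
#' @param ce a [CircadianExperiment-class]; alternatively supply `reads`
#'   and `models` plus `sampleData` to quantify first.
#' @param reads,models,sampleData optional inputs for the quantification
#'   stage: read 3'-position `GRanges` with a `sample` metadata column,
#'   a [GeneModels-class], and the per-sample design table.
#' @param outgroup outgroup label (default `"TH"`).
#' @param window_size 3'-window size in bp (default 300).
#' @param out_dir optional output directory for [writeResults()].
#' @param ... further arguments passed to [runCycling()].
#' @return list with `experiment`, `enrichment`, `cycling` and `overlap`.
#' @export
runPipeline <- function(ce = NULL, reads = NULL, models = NULL,
                        sampleData = NULL, outgroup = "TH",
                        window_size = 300, out_dir = NULL, ...) {
    if (is.null(ce)) {
        if (is.null(reads) || is.null(models) || is.null(sampleData))
            stop("supply either 'ce' or reads + models + sampleData")
        q <- quantifyThreePrime(reads, models, window_size)
        ce <- CircadianExperiment(q$rpm, sampleData)
    }
    enr <- runEnrichment(ce, outgroup = outgroup)
    cyc <- runCycling(ce, ...)
    circ <- setdiff(groupNames(ce), outgroup)
    ov <- overlapAnalysis(cyc, groups = circ, ce = ce)
    if (!is.null(out_dir))
        writeResults(list(enrichment = as.data.frame(enr),
                          cycling = as.data.frame(cyc)), out_dir)
    list(experiment = ce, enrichment = enr, cycling = cyc, overlap = ov)
}
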