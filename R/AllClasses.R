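#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
NULL

#' CircadianExperiment: an around-the-clock expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying a single `rpm`
#' assay of reads-per-million values together with the circadian sampling
#' design in `colData`: the neuron `group` each library was sorted from, the
#' independent time-course it belongs to (`replicate_set`, 1 or 2) and the
#' zeitgeber time `zt` (hours after lights-on) at which it was collected.
#'
#' A complete design has, for every group, two replicate sets of six
#' timepoints spaced 4 h apart.  Different groups may use different ZT
#' grids (e.g. ZT2,6,...,22 for some and ZT3,7,...,23 for another);
#' downstream statistics operate in absolute ZT so offset grids are handled
#' transparently.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @aliases CircadianExperiment
#' @export
setClass("CircadianExperiment", contains = "SummarizedExperiment")

.validCircadianExperiment <- function(object) {
    msg <- NULL
    cd <- colData(object)
    need <- c("group", "replicate_set", "zt")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (!("rpm" %in% names(assays(object))))
        msg <- c(msg, "assay 'rpm' is required")
    else {
        v <- assay(object, "rpm")
        if (anyNA(v) && all(is.na(v))) {
            msg <- c(msg, "assay 'rpm' is all NA")
        } else if (any(v < 0, na.rm = TRUE)) {
            msg <- c(msg, "assay 'rpm' contains negative values")
        }
    }
    if (!length(msg)) {
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, paste0("duplicate gene identifier: ",
                rownames(object)[anyDuplicated(rownames(object))]))
        if (!all(cd$replicate_set %in% c(1L, 2L)))
            msg <- c(msg, "replicate_set must be 1 or 2")
        if (any(cd$zt < 0 | cd$zt >= 24))
            msg <- c(msg, "zt must lie in [0, 24)")
    }
    if (length(msg)) msg else TRUE
}
setValidity("CircadianExperiment", .validCircadianExperiment)

#' Construct a CircadianExperiment
#'
#' @param rpm numeric matrix of reads-per-million values, genes in rows
#'   (unique rownames required), samples in columns.
#' @param sampleData `data.frame` or [S4Vectors::DataFrame] with one row per
#'   column of `rpm` and columns `group`, `replicate_set`, `zt`.  A
#'   `sample_id` column, if present, is used for column names.
#'
#' @return A [CircadianExperiment-class] object.
#' @examples
#' rpm <- matrix(runif(12, 0, 100), nrow = 2,
#'               dimnames = list(c("per", "tim"), NULL))
#' sd <- data.frame(group = "LNv", replicate_set = rep(1:2, each = 3),
#'                  zt = rep(c(2, 6, 10), 2))
#' ce <- CircadianExperiment(rpm, sd)
#' @export
CircadianExperiment <- function(rpm, sampleData) {
    rpm <- as.matrix(rpm)
    storage.mode(rpm) <- "double"
    sampleData <- as(sampleData, "DataFrame")
    sampleData$group <- as.character(sampleData$group)
    sampleData$replicate_set <- as.integer(sampleData$replicate_set)
    sampleData$zt <- as.numeric(sampleData$zt)
    if (is.null(colnames(rpm))) {
        colnames(rpm) <- if (!is.null(sampleData$sample_id))
            as.character(sampleData$sample_id)
        else
            paste(sampleData$group, sampleData$replicate_set,
                  sampleData$zt, sep = "_")
    }
    rownames(sampleData) <- colnames(rpm)
    se <- SummarizedExperiment(assays = list(rpm = rpm),
                               colData = sampleData)
    new("CircadianExperiment", se)
}

#' GeneModels: transcript structures with 3' ends
#'
#' Holds the exon structure of every isoform of every gene, as a
#' [GenomicRanges::GRangesList] with one element per transcript (exons
#' sorted in genomic order, non-overlapping within a transcript), plus the
#' transcript-to-gene map.  Coordinates are stored 1-based closed as is
#' conventional for `GRanges`; GTF input needs no shifting and BED input is
#' shifted on read.  The 3' end of an isoform is its rightmost base on the
#' + strand and leftmost on the - strand; isoforms of one gene with
#' different 3' UTR lengths keep their distinct ends, which is what makes
#' isoform-resolved terminal windows possible.
#'
#' @slot exons `GRangesList`, one element per transcript.
#' @slot txGene named character vector mapping transcript id to gene id.
#' @export
setClass("GeneModels",
    representation(exons = "GRangesList", txGene = "character"))

.validGeneModels <- function(object) {
    msg <- NULL
    ex <- object@exons
    if (length(ex) != length(object@txGene))
        msg <- c(msg, "txGene must have one entry per transcript")
    if (!identical(names(ex), names(object@txGene)))
        msg <- c(msg, "txGene names must match transcript names")
    if (any(S4Vectors::elementNROWS(ex) == 0))
        msg <- c(msg, "transcript with no exons")
    str <- unique(as.character(unlist(GenomicRanges::strand(ex),
                                      use.names = FALSE)))
    if (!all(str %in% c("+", "-")))
        msg <- c(msg, paste0("unknown strand: ",
                             paste(setdiff(str, c("+", "-")), collapse = ",")))
    if (length(msg)) msg else TRUE
}
setValidity("GeneModels", .validGeneModels)

#' Construct a GeneModels object
#'
#' @param exons `GRangesList` of exons, one element per transcript, named by
#'   transcript id.
#' @param txGene named character vector (names = transcript ids) giving the
#'   gene id of each transcript.
#' @return A [GeneModels-class] object.
#' @export
GeneModels <- function(exons, txGene) {
    exons <- GenomicRanges::reduce(exons)
    new("GeneModels", exons = exons, txGene = txGene[names(exons)])
}

#' SimulationConfig: parameters of the synthetic circadian time course
#'
#' Bundles every knob of the synthetic-data generator.  The defaults encode
#' the study design the package targets: four neuron groups (three circadian,
#' one dopaminergic outgroup), two independent replicate time courses per
#' group, six timepoints at 4-h spacing, with the DN1 grid offset by +1 h
#' relative to the others.
#'
#' @slot n_genes number of genes to simulate.
#' @slot groups character vector of group labels.
#' @slot zt_grids named list of numeric ZT grids, one per group (6 values,
#'   4 h apart).
#' @slot frac_cyclers fraction of expressed genes programmed to cycle, per
#'   group (recycled scalar allowed).
#' @slot amplitude_fold peak/trough ratio of the cosine mean of programmed
#'   cyclers (>= 1).
#' @slot phase_dist one of `"uniform"`, `"unimodal"`, `"bimodal"`: how peak
#'   phases are drawn over [0, 24).
#' @slot phase_param numeric parameters of the phase distribution: for
#'   `"unimodal"`, `c(mean, sd)` hours; for `"bimodal"`, `c(mean1, mean2, sd)`.
#' @slot baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   expression (RPM scale).
#' @slot dispersion negative-binomial overdispersion of raw counts
#'   (variance = mu + dispersion * mu^2); `0` switches sampling off and
#'   returns the deterministic mean model.
#' @slot frac_group_restricted fraction of genes expressed in only a random
#'   proper subset of groups.
#' @slot frac_low_expression fraction of genes with baseline below the
#'   10-RPM enrichment filter.
#' @slot library_size raw reads per simulated library.
#' @slot three_prime_bias exponential decay length (bp) of read 3'-position
#'   placement upstream of isoform 3' ends.
#' @slot seed integer seed (NA = leave the RNG state alone).
#' @export
setClass("SimulationConfig",
    representation(n_genes = "integer", groups = "character",
        zt_grids = "list", frac_cyclers = "numeric",
        amplitude_fold = "numeric", phase_dist = "character",
        phase_param = "numeric", baseline_meanlog = "numeric",
        baseline_sdlog = "numeric", dispersion = "numeric",
        frac_group_restricted = "numeric", frac_low_expression = "numeric",
        library_size = "numeric", three_prime_bias = "numeric",
        seed = "integer"))

.validSimulationConfig <- function(object) {
    msg <- NULL
    fr <- c(object@frac_cyclers, object@frac_group_restricted,
            object@frac_low_expression)
    if (any(fr < 0 | fr > 1))
        msg <- c(msg, "fractions must lie in [0, 1]")
    if (object@amplitude_fold < 1)
        msg <- c(msg, "amplitude_fold must be >= 1")
    if (object@library_size <= 0)
        msg <- c(msg, "library_size must be positive")
    if (!all(object@groups %in% names(object@zt_grids)))
        msg <- c(msg, "every group needs a zt grid")
    for (g in object@groups) {
        zt <- sort(object@zt_grids[[g]])
        if (length(zt) != 6)
            msg <- c(msg, paste0("group ", g, ": zt grid must have 6 points"))
        else if (any(abs(diff(zt) - 4) > 1e-9))
            msg <- c(msg, paste0("group ", g, ": zt grid must be 4 h spaced"))
    }
    if (!object@phase_dist %in% c("uniform", "unimodal", "bimodal"))
        msg <- c(msg, "phase_dist must be uniform, unimodal or bimodal")
    if (length(msg)) msg else TRUE
}
setValidity("SimulationConfig", .validSimulationConfig)

#' Default ZT sampling grids of the study design
#'
#' @return Named list of 6-point ZT grids: ZT2,6,...,22 for LNv, LNd and TH;
#'   ZT3,7,...,23 for DN1.
#' @export
defaultZtGrids <- function() {
    list(LNv = seq(2, 22, by = 4), LNd = seq(2, 22, by = 4),
         DN1 = seq(3, 23, by = 4), TH  = seq(2, 22, by = 4))
}

#' Construct a SimulationConfig
#'
#' @param n_genes number of genes (default 2000).
#' @param groups group labels (default `c("LNv","LNd","DN1","TH")`).
#' @param zt_grids named list of ZT grids; defaults to [defaultZtGrids()].
#' @param frac_cyclers per-group fraction of expressed genes that cycle
#'   (default 0.1; the circadian groups of the motivating study call a few
#'   hundred cyclers out of a few thousand expressed genes).
#' @param amplitude_fold peak/trough fold of programmed cyclers (default 4).
#' @param phase_dist,phase_param phase distribution (default uniform).
#' @param baseline_meanlog,baseline_sdlog baseline log-normal (default
#'   `log(50)`, `1`: median 50 RPM with a long right tail, typical of
#'   RPM-scale neuronal expression).
#' @param dispersion NB overdispersion (default 0.04, i.e. CV ~ 0.2 at high
#'   expression, matching the modest reproducibility of low-input
#'   libraries; 0 = noiseless means).
#' @param frac_group_restricted fraction of genes expressed in only some
#'   groups (default 0.2).
#' @param frac_low_expression fraction of genes kept below the 10-RPM
#'   filter (default 0.15).
#' @param library_size raw reads per library (default 1e6).
#' @param three_prime_bias read-placement decay length in bp (default 30).
#' @param seed integer seed or NA.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- SimulationConfig(n_genes = 100, seed = 1)
#' @export
SimulationConfig <- function(n_genes = 2000L,
        groups = c("LNv", "LNd", "DN1", "TH"),
        zt_grids = defaultZtGrids()[groups],
        frac_cyclers = 0.1, amplitude_fold = 4,
        phase_dist = "uniform", phase_param = numeric(),
        baseline_meanlog = log(50), baseline_sdlog = 1,
        dispersion = 0.04, frac_group_restricted = 0.2,
        frac_low_expression = 0.15, library_size = 1e6,
        three_prime_bias = 30, seed = NA_integer_) {
    frac_cyclers <- rep_len(frac_cyclers, length(groups))
    names(frac_cyclers) <- groups
    new("SimulationConfig", n_genes = as.integer(n_genes), groups = groups,
        zt_grids = zt_grids, frac_cyclers = frac_cyclers,
        amplitude_fold = amplitude_fold, phase_dist = phase_dist,
        phase_param = phase_param, baseline_meanlog = baseline_meanlog,
        baseline_sdlog = baseline_sdlog, dispersion = dispersion,
        frac_group_restricted = frac_group_restricted,
        frac_low_expression = frac_low_expression,
        library_size = library_size, three_prime_bias = three_prime_bias,
        seed = as.integer(seed))
}

#' Results containers
#'
#' `CyclingResults` and `EnrichmentResults` are thin
#' [S4Vectors::DataFrame] subclasses so that per-analysis metadata (cutoffs
#' used, pre-screen size, ambiguity reports) travels with the table.
#'
#' @name results-classes
#' @aliases CyclingResults-class EnrichmentResults-class
NULL

#' @rdname results-classes
#' @export
setClass("CyclingResults", contains = "DFrame")

#' @rdname results-classes
#' @export
setClass("EnrichmentResults", contains = "DFrame")
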