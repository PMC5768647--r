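#' @include AllGenerics.R
NULL

#' FirthDataSet: container for a case/control RNA-seq cohort
#'
#' `FirthDataSet` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds the raw count matrix (assay `"counts"`), per-sample metadata
#' (`colData`, which must carry a `condition` column with levels drawn from
#' the disease/control vocabulary) and per-gene annotation (`rowData`,
#' typically `symbol` and `biotype`). Normalized abundances produced by
#' [normalizeCounts()] live in the `"normcounts"` assay; per-sample scale
#' factors in `colData$sizeFactor`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [FirthDataSet()] the constructor, [simulateCohort()],
#'   [preprocessCounts()], [firthDE()]
#' @export
setClass("FirthDataSet", contains = "SummarizedExperiment")

setValidity("FirthDataSet", function(object) {
    msg <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (!is.numeric(cts))
            msg <- c(msg, "'counts' must be numeric")
        else if (any(cts < 0, na.rm = TRUE))
            msg <- c(msg, "'counts' must be non-negative")
        if (anyNA(cts)) msg <- c(msg, "'counts' must not contain NA")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids in rownames")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids in colnames")
    if (!("condition" %in% colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData must contain a 'condition' column")
    else if (anyNA(SummarizedExperiment::colData(object)$condition))
        msg <- c(msg, "'condition' must not contain NA")
    if (length(msg)) msg else TRUE
})

#' Construct a FirthDataSet
#'
#' @param counts Integer-like matrix of non-negative counts, genes x samples,
#'   with unique rownames (gene ids) and colnames (sample ids).
#' @param colData A `data.frame` or [S4Vectors::DataFrame] of per-sample
#'   metadata; must contain `condition` (e.g. `"HD"`, `"PD"`, `"C"`).
#' @param rowData Optional per-gene annotation (`symbol`, `biotype`, ...).
#' @return A [FirthDataSet-class] object.
#' @examples
#' cts <- matrix(rpois(40, 20), nrow = 10,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' fds <- FirthDataSet(cts,
#'                     colData = data.frame(condition = c("HD", "HD", "C", "C")))
#' fds
#' @export
FirthDataSet <- function(counts, colData, rowData = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' must have rownames (gene ids) and colnames (sample ids)")
    colData <- S4Vectors::DataFrame(colData)
    if (!("condition" %in% colnames(colData)))
        stop("colData must contain a 'condition' column")
    colData$condition <- factor(as.character(colData$condition))
    args <- list(assays = list(counts = counts), colData = colData)
    if (!is.null(rowData)) args$rowData <- S4Vectors::DataFrame(rowData)
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    methods::new("FirthDataSet", se)
}

#' @describeIn FirthDataSet raw count matrix accessor.
#' @param object,... see above.
#' @export
setMethod("counts", "FirthDataSet", function(object, ...)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname normCounts
#' @export
setMethod("normCounts", "FirthDataSet", function(object, ...) {
    if (!("normcounts" %in% SummarizedExperiment::assayNames(object)))
        stop("no 'normcounts' assay; run normalizeCounts() first")
    SummarizedExperiment::assay(object, "normcounts")
})

#' @rdname normCounts
#' @export
setReplaceMethod("normCounts", "FirthDataSet", function(object, ..., value) {
    SummarizedExperiment::assay(object, "normcounts") <- value
    object
})

#' @describeIn FirthDataSet per-sample median-of-ratios scale factors
#'   (set by [computeSizeFactors()]).
#' @export
setMethod("sizeFactors", "FirthDataSet", function(object) {
    sf <- SummarizedExperiment::colData(object)$sizeFactor
    if (is.null(sf)) return(NULL)
    stats::setNames(sf, colnames(object))
})

#' @describeIn FirthDataSet set size factors.
#' @param value Positive numeric vector, one per sample.
#' @export
setReplaceMethod("sizeFactors", "FirthDataSet", function(object, value) {
    if (length(value) != ncol(object))
        stop("need one size factor per sample")
    if (any(!is.finite(value)) || any(value <= 0))
        stop("size factors must be finite and > 0")
    SummarizedExperiment::colData(object)$sizeFactor <- unname(value)
    object
})

#' @rdname conditions
#' @export
setMethod("conditions", "FirthDataSet", function(object, ...)
    factor(SummarizedExperiment::colData(object)$condition))

#' @rdname simTruth
#' @export
setMethod("simTruth", "FirthDataSet", function(object, ...) {
    rd <- SummarizedExperiment::rowData(object)
    need <- c("label", "lfc_d1", "lfc_d2")
    if (!all(need %in% colnames(rd)))
        stop("no simulation truth attached; object was not simulated")
    rd[, need]
})

setMethod("show", "FirthDataSet", function(object) {
    cat("FirthDataSet with", nrow(object), "genes and",
        ncol(object), "samples\n")
    tab <- table(conditions(object))
    cat("conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
    if (!is.null(sizeFactors(object))) cat("size factors: set\n")
    if ("label" %in% colnames(SummarizedExperiment::rowData(object)))
        cat("simulated truth: attached\n")
})

#' SimParams: simulation settings for a synthetic case/case/control cohort
#'
#' Parameter object consumed by [simulateCohort()]. The defaults describe a
#' two-disease post-mortem brain cohort of the size used throughout the
#' package's validation: 29 + 29 disease samples and 49 controls, 10% of
#' genes with a shared disease effect and 5% unique to each disease at
#' |log2 fold change| = 1, negative-binomial counts with dispersion 0.1.
#'
#' @slot nDisease1,nDisease2,nControl integer sample counts per group.
#' @slot nGenes integer number of genes.
#' @slot fracSharedDE,fracD1OnlyDE,fracD2OnlyDE fractions in `[0,1]` of genes
#'   with effects shared across diseases, or unique to disease 1 / disease 2;
#'   must sum to at most 1, remainder is null.
#' @slot lfcMagnitude absolute planted log2 fold change; sign is random per
#'   gene (shared genes get one sign used in both diseases).
#' @slot dispersion NB dispersion `alpha` (variance = mu + alpha * mu^2).
#' @slot sizeFactorRange range of per-sample scale multipliers (uniform).
#' @slot baselineMeanRange range of per-gene base means (log-uniform).
#' @slot nBatches,batchLfc number of sequencing batches and the log2 shift
#'   applied to even-numbered batches (0 = no batch effect).
#' @slot seed integer RNG seed; all randomness is derived from it.
#' @seealso [simParams()], [simulateCohort()]
#' @export
setClass("SimParams", representation(
    nDisease1 = "integer", nDisease2 = "integer", nControl = "integer",
    nGenes = "integer",
    fracSharedDE = "numeric", fracD1OnlyDE = "numeric",
    fracD2OnlyDE = "numeric",
    lfcMagnitude = "numeric", dispersion = "numeric",
    sizeFactorRange = "numeric", baselineMeanRange = "numeric",
    nBatches = "integer", batchLfc = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
    msg <- character()
    ns <- c(object@nDisease1, object@nDisease2, object@nControl, object@nGenes)
    if (any(is.na(ns)) || any(ns < 1L))
        msg <- c(msg, "sample and gene counts must all be >= 1")
    fr <- c(object@fracSharedDE, object@fracD1OnlyDE, object@fracD2OnlyDE)
    if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-12)
        msg <- c(msg, "DE fractions must lie in [0,1] and sum to <= 1")
    if (object@dispersion <= 0)
        msg <- c(msg, "dispersion must be > 0")
    for (nm in c("sizeFactorRange", "baselineMeanRange")) {
        r <- methods::slot(object, nm)
        if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
            msg <- c(msg, paste0(nm, " must be a positive ascending interval"))
    }
    if (object@nBatches < 1L) msg <- c(msg, "nBatches must be >= 1")
    if (is.na(object@seed)) msg <- c(msg, "seed must be a finite integer")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimParams", function(object) {
    cat("SimParams:", object@nDisease1, "+", object@nDisease2, "disease /",
        object@nControl, "control samples,", object@nGenes, "genes\n")
    cat(sprintf("  DE fractions shared/d1/d2: %.3g/%.3g/%.3g, |log2FC| = %g\n",
                object@fracSharedDE, object@fracD1OnlyDE, object@fracD2OnlyDE,
                object@lfcMagnitude))
    cat(sprintf("  NB dispersion %g, size factors [%g, %g], base means [%g, %g]\n",
                object@dispersion, object@sizeFactorRange[1],
                object@sizeFactorRange[2], object@baselineMeanRange[1],
                object@baselineMeanRange[2]))
    cat("  batches:", object@nBatches, " batch log2 shift:", object@batchLfc,
        " seed:", object@seed, "\n")
})
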