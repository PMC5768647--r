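#' @import methods
#' @importFrom BiocGenerics counts sizeFactors "sizeFactors<-"
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay "assay<-" assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

#' Normalized count accessor
#'
#' Returns the normalized (and, after [trimOutliers()], winsorized) abundance
#' matrix stored in the `"normcounts"` assay of a [FirthDataSet].
#'
#' @param object A `FirthDataSet`.
#' @param ... Ignored.
#' @return A numeric matrix, genes x samples.
#' @export
setGeneric("normCounts", function(object, ...) standardGeneric("normCounts"))

#' @rdname normCounts
#' @param value A numeric matrix with the dimensions of `object`.
#' @export
setGeneric("normCounts<-", function(object, ..., value)
    standardGeneric("normCounts<-"))

#' Simulation ground truth accessor
#'
#' Per-gene planted truth of a simulated cohort: effect label
#' (`null`, `shared`, `d1_only`, `d2_only`) and the signed log2 effect applied
#' in each disease group.
#'
#' @param object A `FirthDataSet` produced by [simulateCohort()].
#' @param ... Ignored.
#' @return A [S4Vectors::DataFrame] with columns `label`, `lfc_d1`, `lfc_d2`.
#' @export
setGeneric("simTruth", function(object, ...) standardGeneric("simTruth"))

#' Condition accessor
#'
#' @param object A `FirthDataSet`.
#' @param ... Ignored.
#' @return Factor of per-sample conditions.
#' @export
setGeneric("conditions", function(object, ...) standardGeneric("conditions"))
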