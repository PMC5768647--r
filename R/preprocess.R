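#' @include utils.R
NULL

#' Polyadenylated gene biotypes
#'
#' The default biotype whitelist for poly-A-selected libraries: protein
#' coding genes, lincRNA, processed transcripts, sense intronic/overlapping
#' transcripts and the IG/TR receptor gene segments. Both the Ensembl
#' spelling `"sense_overlapping"` and the common variant
#' `"sense_overlaping"` are accepted.
#'
#' @return Character vector of biotype strings.
#' @export
polyABiotypes <- function() {
    c("protein_coding", "lincRNA", "processed_transcript",
      "sense_intronic", "sense_overlaping", "sense_overlapping",
      "IG_V_gene", "IG_D_gene", "IG_J_gene", "IG_C_gene",
      "TR_V_gene", "TR_D_gene", "TR_J_gene", "TR_C_gene")
}

#' Filter genes by annotation biotype
#'
#' Keeps exactly the genes whose biotype is in `allowed`, preserving the
#' original gene order. An empty `allowed` list yields an empty (zero-gene)
#' object, not an error.
#'
#' @param fds A [FirthDataSet-class]; `rowData` must carry a `biotype`
#'   column covering every gene.
#' @param allowed Character vector of retained biotypes
#'   (default [polyABiotypes()]).
#' @return The filtered [FirthDataSet-class].
#' @export
filterBiotypes <- function(fds, allowed = polyABiotypes()) {
    bt <- SummarizedExperiment::rowData(fds)$biotype
    if (is.null(bt))
        stop("rowData has no 'biotype' column")
    missing <- rownames(fds)[is.na(bt)]
    if (length(missing))
        stop("genes missing biotype annotation: ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) ", ...")
    keep <- bt %in% allowed
    message(sum(!keep), " of ", length(keep),
            " genes removed by biotype filter")
    fds[keep, ]
}

#' Filter genes with too many zero counts in either group
#'
#' Removes a gene when strictly more than half of the case samples, or
#' strictly more than half of the control samples, have zero counts. The
#' case group defaults to the pooled disease samples so all contrasts share
#' one gene universe.
#'
#' @param fds A [FirthDataSet-class].
#' @param caseConditions Conditions forming the case group
#'   (default `c("HD","PD")`).
#' @param controlConditions Conditions forming the control group
#'   (default `"C"`).
#' @return The filtered [FirthDataSet-class].
#' @export
filterLowCounts <- function(fds, caseConditions = c("HD", "PD"),
                            controlConditions = "C") {
    cond <- as.character(conditions(fds))
    caseIdx <- cond %in% caseConditions
    ctrlIdx <- cond %in% controlConditions
    if (!any(caseIdx)) stop("case group is empty")
    if (!any(ctrlIdx)) stop("control group is empty")
    cts <- counts(fds)
    zCase <- rowSums(cts[, caseIdx, drop = FALSE] == 0)
    zCtrl <- rowSums(cts[, ctrlIdx, drop = FALSE] == 0)
    drop <- (zCase > sum(caseIdx) / 2) | (zCtrl > sum(ctrlIdx) / 2)
    message(sum(drop), " of ", length(drop),
            " genes removed by zero-count filter")
    fds[!drop, ]
}

#' Median-of-ratios size factors for a count matrix
#'
#' Per-sample scale factor: the median, over reference genes, of the ratio
#' of the sample's count to the gene's geometric mean across samples.
#' Reference genes are those with strictly positive counts in every sample;
#' geometric means are computed in log space.
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @return Named positive numeric vector of per-sample factors.
#' @examples
#' m <- rbind(g1 = c(2, 8), g2 = c(2, 8))
#' colnames(m) <- c("a", "b")
#' sizeFactorsMoR(m)  # 0.5, 2
#' @export
sizeFactorsMoR <- function(counts) {
    counts <- as.matrix(counts)
    ref <- rowSums(counts > 0) == ncol(counts)
    if (!any(ref))
        stop("no gene has all-positive counts; prefilter low-count genes ",
             "before computing size factors")
    logc <- log(counts[ref, , drop = FALSE])
    logGeo <- rowMeans(logc)
    sf <- apply(logc, 2, function(col) exp(stats::median(col - logGeo)))
    stats::setNames(sf, colnames(counts))
}

#' Compute and attach size factors
#'
#' Runs [sizeFactorsMoR()] on the `"counts"` assay and stores the result in
#' `colData$sizeFactor` (retrievable with `sizeFactors()`).
#'
#' @param fds A [FirthDataSet-class].
#' @return `fds` with size factors attached.
#' @export
computeSizeFactors <- function(fds) {
    sizeFactors(fds) <- sizeFactorsMoR(counts(fds))
    fds
}

#' Normalize counts by size factors
#'
#' Divides each sample's counts by its scale factor and stores the result in
#' the `"normcounts"` assay. Size factors are computed first if absent.
#'
#' @param fds A [FirthDataSet-class].
#' @return `fds` with a `"normcounts"` assay.
#' @export
normalizeCounts <- function(fds) {
    if (is.null(sizeFactors(fds))) fds <- computeSizeFactors(fds)
    sf <- sizeFactors(fds)
    normCounts(fds) <- sweep(counts(fds), 2, sf, "/")
    fds
}

# winsorize one numeric vector at median +/- zMax * 1.4826 * MAD;
# MAD = 0 (constant-ish group) leaves values untouched.
.winsorize <- function(x, zMax) {
    med <- stats::median(x)
    s <- stats::mad(x)          # constant 1.4826 is mad()'s default
    if (s == 0) return(x)
    pmin(pmax(x, med - zMax * s), med + zMax * s)
}

#' Winsorize outlying normalized counts within condition groups
#'
#' Per gene and per condition group, values whose robust z-score
#' `|x - median| / (1.4826 * MAD)` exceeds `zMax` are replaced by the group
#' boundary `median +/- zMax * 1.4826 * MAD`. Groups with fewer than three
#' samples are skipped with a warning; groups with MAD 0 are left untouched.
#' This trimming never changes a group median and never widens a group
#' range.
#'
#' @param fds A [FirthDataSet-class] with a `"normcounts"` assay.
#' @param zMax Robust z-score threshold (> 0, default 3).
#' @return `fds` with the `"normcounts"` assay winsorized.
#' @export
trimOutliers <- function(fds, zMax = 3) {
    if (zMax <= 0) stop("'zMax' must be > 0")
    m <- normCounts(fds)
    cond <- as.character(conditions(fds))
    for (g in unique(cond)) {
        idx <- which(cond == g)
        if (length(idx) < 3) {
            warning("condition group '", g, "' has fewer than 3 samples; ",
                    "outlier trimming skipped for this group")
            next
        }
        sub <- m[, idx, drop = FALSE]
        m[, idx] <- t(apply(sub, 1, .winsorize, zMax = zMax))
    }
    normCounts(fds) <- m
    fds
}

#' Full preprocessing: filters, normalization, outlier trimming
#'
#' Applies, in order: biotype filter, zero-count filter, median-of-ratios
#' size factors, normalization, and (optionally) robust winsorization.
#'
#' @param fds A [FirthDataSet-class] with raw counts.
#' @param allowed Biotype whitelist (default [polyABiotypes()]); `NULL`
#'   skips the biotype filter.
#' @param caseConditions,controlConditions Groups for the zero-count filter.
#' @param trim Logical; winsorize outliers (default `TRUE`).
#' @param zMax Winsorization threshold.
#' @return The analysis-ready [FirthDataSet-class].
#' @export
preprocessCounts <- function(fds, allowed = polyABiotypes(),
                             caseConditions = c("HD", "PD"),
                             controlConditions = "C",
                             trim = TRUE, zMax = 3) {
    if (!is.null(allowed)) fds <- filterBiotypes(fds, allowed)
    fds <- filterLowCounts(fds, caseConditions, controlConditions)
    fds <- normalizeCounts(fds)
    if (trim) fds <- trimOutliers(fds, zMax)
    fds
}
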