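#' @include firth.R
NULL

#' Define a case/control contrast
#'
#' @param name Contrast label, e.g. `"HD_vs_C"`.
#' @param case Condition(s) forming the case group; the pooled-disease
#'   contrast uses both diseases as cases.
#' @param control Condition(s) forming the control group; must be disjoint
#'   from `case`.
#' @return A list of class `"de_contrast"`.
#' @export
makeContrast <- function(name, case, control = "C") {
    if (length(intersect(case, control)))
        stop("case and control conditions must be disjoint")
    structure(list(name = name, case = case, control = control),
              class = "de_contrast")
}

#' The three standard disease contrasts
#'
#' HD vs control, PD vs control, and the pooled neurodegeneration (ND)
#' contrast with HD and PD concatenated as a single case group. All
#' controls enter every contrast.
#'
#' @return Named list of three [makeContrast()] objects.
#' @export
standardContrasts <- function() {
    list(HD_vs_C = makeContrast("HD_vs_C", "HD"),
         PD_vs_C = makeContrast("PD_vs_C", "PD"),
         ND_vs_C = makeContrast("ND_vs_C", c("HD", "PD")))
}

# Build the covariate block of the design matrix: numeric covariates are
# standardized like counts; categoricals are dummy-coded, first level
# reference.
.covariateBlock <- function(colData, covariates) {
    if (!length(covariates)) return(NULL)
    missing <- setdiff(covariates, colnames(colData))
    if (length(missing))
        stop("covariates missing from sample metadata: ",
             paste(missing, collapse = ", "))
    blocks <- lapply(covariates, function(cv) {
        v <- colData[[cv]]
        if (is.numeric(v)) {
            m <- matrix(standardizeVector(v), ncol = 1)
            colnames(m) <- cv
            m
        } else {
            f <- factor(v)
            if (nlevels(f) < 2)
                stop("categorical covariate '", cv, "' has a single level")
            m <- stats::model.matrix(~f)[, -1, drop = FALSE]
            colnames(m) <- paste0(cv, levels(f)[-1])
            m
        }
    })
    do.call(cbind, blocks)
}

#' Per-gene Firth logistic differential expression for one contrast
#'
#' For every gene, fits Firth logistic regression of disease status (1 =
#' case) on the standardized trimmed normalized abundance plus optional
#' covariates, and tests the count term with the penalized likelihood-ratio
#' test. The count coefficient is the standardized log odds ratio (LOR):
#' positive LOR means greater abundance in cases. Benjamini-Hochberg
#' q-values are computed across all successfully tested genes of the
#' contrast; genes whose fit fails (or that are constant within the
#' contrast's samples) get `NA` p and q and are excluded from the number of
#' tests.
#'
#' @param fds A preprocessed [FirthDataSet-class] (with `"normcounts"`).
#' @param contrast A [makeContrast()] object.
#' @param covariates Character vector of `colData` columns to adjust for
#'   (default none).
#' @param alpha Significance threshold on q (default 0.01).
#' @return A [S4Vectors::DataFrame] of class `FirthResults` with columns
#'   `gene_id`, `symbol`, `lor`, `se`, `p`, `q`, `converged`, `de`
#'   (logical call at `q < alpha`); contrast and group sizes in
#'   `metadata()`.
#' @export
firthDE <- function(fds, contrast, covariates = character(), alpha = 0.01) {
    stopifnot(inherits(contrast, "de_contrast"))
    cond <- as.character(conditions(fds))
    sel <- cond %in% c(contrast$case, contrast$control)
    sub <- fds[, sel]
    y <- as.numeric(as.character(conditions(sub)) %in% contrast$case)
    if (!any(y == 1) || !any(y == 0))
        stop("contrast '", contrast$name, "': a group is empty")
    m <- normCounts(sub)
    covBlock <- .covariateBlock(SummarizedExperiment::colData(sub),
                                covariates)
    nGenes <- nrow(m)
    lor <- se <- p <- rep(NA_real_, nGenes)
    convd <- rep(FALSE, nGenes)
    for (i in seq_len(nGenes)) {
        x <- m[i, ]
        if (length(unique(x)) < 2) next
        X <- cbind(`(Intercept)` = 1, count = standardizeVector(x),
                   covBlock)
        res <- tryCatch(firthTest(y, X, termIndex = 2L),
                        error = function(e) NULL)
        if (is.null(res)) next
        lor[i] <- res$fitFull$coefficients[2]
        se[i] <- res$fitFull$se[2]
        p[i] <- res$p
        convd[i] <- res$fitFull$converged && res$fitReduced$converged
    }
    q <- bhAdjust(p)
    rd <- SummarizedExperiment::rowData(sub)
    symbol <- if ("symbol" %in% colnames(rd)) rd$symbol else rownames(sub)
    out <- S4Vectors::DataFrame(
        gene_id = rownames(sub), symbol = symbol,
        lor = lor, se = se, p = p, q = q, converged = convd,
        de = !is.na(q) & q < alpha, row.names = rownames(sub))
    S4Vectors::metadata(out) <- list(
        contrast = contrast$name, case = contrast$case,
        control = contrast$control,
        nCase = sum(y == 1), nControl = sum(y == 0),
        covariates = covariates, alpha = alpha)
    out
}

#' Significant gene ids of a DE result
#'
#' @param res A result from [firthDE()].
#' @return Character vector of gene ids called differentially expressed.
#' @export
deGenes <- function(res) res$gene_id[res$de]

#' Batch concordance diagnostic
#'
#' Fits each gene's Firth model with and without a categorical batch
#' covariate and reports the Spearman correlation of the per-gene count
#' coefficients between the two model families. A correlation near 1
#' indicates batch structure does not confound the DE coefficients.
#'
#' @param fds A preprocessed [FirthDataSet-class]; `colData` must have a
#'   `batch` column with at least two levels among the contrast's samples.
#' @param contrast A [makeContrast()] object.
#' @param covariates Additional covariates for both model families.
#' @return A list: `contrast`, `rho`, `p` (of the Spearman test), `n`
#'   (genes with coefficients in both families).
#' @export
batchConcordance <- function(fds, contrast, covariates = character()) {
    cond <- as.character(conditions(fds))
    sel <- cond %in% c(contrast$case, contrast$control)
    batch <- factor(SummarizedExperiment::colData(fds)$batch[sel])
    if (nlevels(batch) < 2)
        stop("batch concordance needs >= 2 batches among the ",
             "contrast's samples")
    y <- as.numeric(cond[sel] %in% contrast$case)
    if (all(tapply(y, batch, function(v) length(unique(v))) == 1))
        stop("batch is confounded with case/control status")
    without <- firthDE(fds, contrast, covariates = covariates)
    withB <- firthDE(fds, contrast,
                     covariates = c(covariates, "batch"))
    ok <- !is.na(without$lor) & !is.na(withB$lor)
    ct <- suppressWarnings(
        stats::cor.test(without$lor[ok], withB$lor[ok],
                        method = "spearman"))
    list(contrast = contrast$name, rho = unname(ct$estimate),
         p = ct$p.value, n = sum(ok))
}
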