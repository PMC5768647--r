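#' @include utils.R
NULL

#' Order genes for rank aggregation
#'
#' Builds the per-contrast gene ordering that enters robust rank
#' aggregation: ascending raw p-value, ties broken by descending |LOR| and
#' then ascending gene id. Genes with missing p go last (by id).
#'
#' @param res A [firthDE()] result.
#' @return Character vector of gene ids, best (most significant) first.
#' @export
rraRankList <- function(res) {
    p <- res$p
    p[is.na(p)] <- Inf
    absLor <- abs(res$lor)
    absLor[is.na(absLor)] <- -Inf
    res$gene_id[order(p, -absLor, res$gene_id)]
}

#' Normalized rank matrix across gene lists
#'
#' For `n` ordered gene lists over one shared universe of size `N`, returns
#' the matrix of normalized ranks `position / N` (position 1 = best),
#' one row per gene, one column per list.
#'
#' @param lists List of character vectors, each a complete ordering of the
#'   same gene universe.
#' @return Numeric matrix, genes x lists, values in `(0, 1]`; row order
#'   follows the first list's universe sorted by id.
#' @export
normalizedRanks <- function(lists) {
    if (!length(lists)) stop("need at least one list")
    universe <- sort(lists[[1]])
    for (i in seq_along(lists)) {
        l <- lists[[i]]
        if (anyDuplicated(l))
            stop("list ", i, " contains duplicate gene ids")
        if (!identical(sort(l), universe)) {
            diffs <- c(setdiff(l, universe), setdiff(universe, l))
            stop("gene universes differ across lists; symmetric ",
                 "difference includes: ",
                 paste(utils::head(diffs, 5), collapse = ", "))
        }
    }
    N <- length(universe)
    r <- vapply(lists, function(l) match(universe, l) / N, numeric(N))
    rownames(r) <- universe
    if (is.null(colnames(r)) && !is.null(names(lists)))
        colnames(r) <- names(lists)
    r
}

#' Robust rank aggregation rho score for one gene
#'
#' Given a gene's normalized ranks `r_1..r_n` across `n` lists, sorts them
#' and evaluates the binomial order-statistic tails
#' `beta_k = P(Bin(n, r_(k)) >= k)`; the rho score is the minimum over `k`,
#' and the corrected score applies a Bonferroni factor:
#' `min(1, n * rho)`. Order of the input ranks is irrelevant.
#'
#' @param r Numeric vector of normalized ranks in `(0, 1]`.
#' @return A list: `rho`, `corrected`, `beta` (the per-k tails).
#' @examples
#' rhoScore(c(0.1, 0.2, 0.3))$corrected  # 0.081
#' @export
rhoScore <- function(r) {
    if (any(is.na(r)) || any(r <= 0 | r > 1))
        stop("normalized ranks must lie in (0, 1]")
    n <- length(r)
    rs <- sort(r)
    beta <- stats::pbinom(seq_len(n) - 1, n, rs, lower.tail = FALSE)
    rho <- min(beta)
    list(rho = rho, corrected = min(1, n * rho), beta = beta)
}

#' Robust rank aggregation across gene lists
#'
#' Aggregates `n` complete orderings of one gene universe into a per-gene
#' score detecting genes ranked consistently better than expected under
#' independent uniform orderings. Genes are sorted ascending by corrected
#' score (ties by gene id); `significant` flags scores below `threshold`.
#'
#' @param lists List (ideally named) of character vectors, each a complete
#'   ordering of the same universe, best first.
#' @param threshold Score threshold for the significance flag
#'   (default 0.01).
#' @return A `data.frame`: `gene_id`, `score` (corrected), `rho`,
#'   `rra_rank`, one `rank_<list>` column per input list, `significant`.
#' @export
aggregateRanks <- function(lists, threshold = 0.01) {
    r <- normalizedRanks(lists)
    n <- ncol(r)
    sc <- apply(r, 1, function(v) {
        s <- rhoScore(v)
        c(s$rho, s$corrected)
    })
    res <- data.frame(gene_id = rownames(r), score = sc[2, ],
                      rho = sc[1, ], stringsAsFactors = FALSE)
    rankCols <- round(r * nrow(r))
    colnames(rankCols) <- paste0(
        "rank_", if (is.null(colnames(r))) seq_len(n) else colnames(r))
    res <- cbind(res, as.data.frame(rankCols))
    res <- res[order(res$score, res$gene_id), , drop = FALSE]
    res$rra_rank <- seq_len(nrow(res))
    res$significant <- res$score < threshold
    rownames(res) <- NULL
    res[, c("gene_id", "score", "rho", "rra_rank",
            colnames(rankCols), "significant")]
}
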