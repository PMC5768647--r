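#' @include gsea.R
NULL

#' Partition two DE gene lists into unique and common sets
#'
#' @param hd,pd Character vectors of significant gene ids from the two
#'   disease contrasts.
#' @return A named list of three disjoint sets: `HD_only` (`hd \ pd`),
#'   `PD_only` (`pd \ hd`), `common` (intersection); their union is
#'   `hd U pd`.
#' @examples
#' partitionDE(c("A", "B", "C"), c("B", "C", "D"))
#' @export
partitionDE <- function(hd, pd) {
    hd <- unique(hd)
    pd <- unique(pd)
    list(HD_only = setdiff(hd, pd),
         PD_only = setdiff(pd, hd),
         common = intersect(hd, pd))
}

#' Hypergeometric enrichment of each DE partition
#'
#' Runs [hypergeomEnrich()] for every partition against every collection;
#' BH correction is applied within each partition x collection block. The
#' universe is the set of genes that passed preprocessing (the tested
#' universe, not the genome). Empty partitions yield no rows.
#'
#' @param partitions Named list of gene-id sets (from [partitionDE()]).
#' @param universe Character vector of tested gene ids.
#' @param collections Named list of gene-set collections (each a named list
#'   of member vectors).
#' @return A `data.frame` with `partition` and `collection` columns
#'   prepended to the [hypergeomEnrich()] output.
#' @export
enrichPartitions <- function(partitions, universe, collections) {
    if (is.null(names(collections)))
        names(collections) <- paste0("collection", seq_along(collections))
    rows <- list()
    for (pn in names(partitions)) {
        if (!length(partitions[[pn]])) next
        for (cn in names(collections)) {
            res <- hypergeomEnrich(partitions[[pn]], universe,
                                   collections[[cn]])
            if (nrow(res))
                rows[[length(rows) + 1L]] <-
                    cbind(partition = pn, collection = cn, res,
                          stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(partition = character(), collection = character(),
                          set = character(), overlap = integer(),
                          querySize = integer(), setSize = integer(),
                          universeSize = integer(), p = numeric(),
                          q = numeric(), members = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Group enriched gene sets by shared DE-gene membership
#'
#' Builds a graph over gene sets with an edge whenever two sets share more
#' than `threshold` of their DE genes — by default the overlap coefficient,
#' `|A n B| / min(|A|, |B|)` over each set's DE members, so a small set
#' nested in a larger one groups with it; groups are the connected
#' components.
#'
#' @param setMembers Named list: per gene set, the character vector of its
#'   DE-gene members (e.g. split from the `members` column of
#'   [enrichPartitions()]).
#' @param threshold Sharing fraction above which two sets are linked
#'   (strict, default 0.2; must lie in `[0, 1]`).
#' @param method `"overlap"` (default, min-set denominator) or
#'   `"jaccard"`.
#' @return A `data.frame`: `set`, `group` (integer component id, numbered
#'   by first appearance); singleton groups allowed.
#' @export
groupGeneSets <- function(setMembers, threshold = 0.2,
                          method = c("overlap", "jaccard")) {
    method <- match.arg(method)
    if (threshold < 0 || threshold > 1)
        stop("'threshold' must lie in [0, 1]")
    nm <- names(setMembers)
    if (is.null(nm)) stop("'setMembers' must be named")
    n <- length(setMembers)
    edges <- matrix(character(0), ncol = 2)
    if (n > 1) {
        pairs <- utils::combn(n, 2)
        share <- apply(pairs, 2, function(ij) {
            a <- unique(setMembers[[ij[1]]])
            b <- unique(setMembers[[ij[2]]])
            ov <- length(intersect(a, b))
            den <- if (method == "overlap") min(length(a), length(b))
                   else length(union(a, b))
            if (den == 0) 0 else ov / den
        })
        link <- share > threshold
        if (any(link))
            edges <- cbind(nm[pairs[1, link]], nm[pairs[2, link]])
    }
    g <- igraph::graph_from_data_frame(
        as.data.frame(edges, stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = nm, stringsAsFactors = FALSE))
    comp <- igraph::components(g)$membership[nm]
    # renumber components in order of first appearance for determinism
    grp <- as.integer(factor(comp, levels = unique(comp)))
    data.frame(set = nm, group = grp, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Cross-contrast enrichment direction concordance
#'
#' For each gene set significant (`q < qThreshold`) in at least two
#' contrasts' GSEA results, records whether the NES signs agree; also
#' tallies, per contrast, shared and unique significant sets (the counts
#' behind a Venn of enriched sets).
#'
#' @param gseaList Named list of [gseaPreranked()] results, one per
#'   contrast.
#' @param qThreshold Significance threshold on q (default 0.05).
#' @return A list: `table` (`data.frame`: set, per-contrast significance
#'   and direction, `nSignificant`, `concordant` — `NA` for sets
#'   significant in fewer than two contrasts) and `counts` (named vector:
#'   significant sets per contrast, sets significant in >= 2 contrasts,
#'   concordant among those, and unique counts per contrast).
#' @export
directionConcordance <- function(gseaList, qThreshold = 0.05) {
    if (is.null(names(gseaList)))
        stop("'gseaList' must be named by contrast")
    sets <- sort(unique(unlist(lapply(gseaList, `[[`, "set"))))
    sig <- dir <- matrix(NA, length(sets), length(gseaList),
                         dimnames = list(sets, names(gseaList)))
    for (cn in names(gseaList)) {
        res <- gseaList[[cn]]
        i <- match(res$set, sets)
        sig[i, cn] <- !is.na(res$q) & res$q < qThreshold
        dir[i, cn] <- res$direction
    }
    nSig <- rowSums(sig, na.rm = TRUE)
    concordant <- rep(NA, length(sets))
    for (i in which(nSig >= 2)) {
        d <- dir[i, which(sig[i, ] %in% TRUE)]
        concordant[i] <- length(unique(d)) == 1L
    }
    tab <- data.frame(set = sets, stringsAsFactors = FALSE)
    for (cn in names(gseaList)) {
        tab[[paste0("sig_", cn)]] <- sig[, cn]
        tab[[paste0("dir_", cn)]] <- dir[, cn]
    }
    tab$nSignificant <- as.integer(nSig)
    tab$concordant <- concordant
    counts <- c(vapply(names(gseaList), function(cn)
                    sum(sig[, cn], na.rm = TRUE), 0),
                shared = sum(nSig >= 2),
                concordant = sum(concordant, na.rm = TRUE))
    uniq <- vapply(names(gseaList), function(cn)
        sum(sig[, cn] %in% TRUE & nSig == 1), 0)
    names(uniq) <- paste0(names(gseaList), "_unique")
    list(table = tab, counts = c(counts, uniq))
}
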