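#' @include gmt.R
NULL

#' Rank genes by standardized coefficient
#'
#' Orders the complete gene list of one contrast by descending standardized
#' LOR (the count-variable coefficient); ties are broken by ascending gene
#' id so the ranking is deterministic. Genes with missing coefficients
#' (failed fits) are dropped.
#'
#' @param res A [firthDE()] result.
#' @return Named numeric vector of scores sorted best-first; names are
#'   gene ids.
#' @export
rankGenes <- function(res) {
    if (anyDuplicated(res$gene_id)) stop("duplicate gene ids in results")
    ok <- !is.na(res$lor)
    ids <- res$gene_id[ok]
    sc <- res$lor[ok]
    o <- order(-sc, ids)
    stats::setNames(sc[o], ids[o])
}

# ES from hit positions: between hits the running sum falls linearly, so
# its extrema occur just after (R) or just before (B) a hit.
.esFromIdx <- function(absW, idx, N) {
    m <- length(idx)
    nMiss <- N - m
    w <- absW[idx]
    nr <- sum(w)
    cw <- if (nr > 0) cumsum(w) / nr else seq_len(m) / m
    missBefore <- idx - seq_len(m)
    R <- cw - missBefore / nMiss
    B <- c(0, cw[-m]) - missBefore / nMiss
    maxv <- max(R, 0)
    minv <- min(B, 0)
    if (maxv >= -minv) maxv else minv
}

#' Weighted GSEA enrichment score for one set
#'
#' Running-sum statistic over a ranked gene list: at each member ("hit") the
#' sum rises by `|score|^p` normalized by the total hit weight, at each
#' non-member it falls by `1/(N - Nh)`; the enrichment score is the maximum
#' deviation from zero, signed.
#'
#' @param ranked Named score vector from [rankGenes()] (order is the
#'   ranking).
#' @param set Character vector of member gene ids.
#' @param weightP Score weight exponent (default 1; 0 gives the unweighted
#'   Kolmogorov-Smirnov-like statistic).
#' @return ES in `[-1, 1]`.
#' @examples
#' r <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
#' gseaES(r, "g1")  #  1
#' gseaES(r, "g4")  # -1
#' @export
gseaES <- function(ranked, set, weightP = 1) {
    N <- length(ranked)
    idx <- which(names(ranked) %in% set)
    if (!length(idx))
        stop("gene set is disjoint from the ranked universe")
    if (length(idx) == N)
        stop("gene set covers the whole ranked universe")
    .esFromIdx(abs(ranked)^weightP, idx, N)
}

#' Preranked GSEA over a collection with a gene-sampling null
#'
#' Computes the enrichment score of every set against the complete ranked
#' list, then a permutation null per set by drawing random same-size gene
#' sets from the universe. `NES = ES / mean(|null ES| of matching sign)`;
#' the nominal p is the fraction of same-sign null scores at least as
#' extreme (with a +1 continuity correction so p is in `(0, 1]`); q is
#' Benjamini-Hochberg across the collection.
#'
#' @param ranked Named score vector from [rankGenes()].
#' @param collection Named list of gene sets (e.g. from [readGmt()] or
#'   [simulateGeneSets()]).
#' @param nPerm Number of null draws per set (>= 100, default 1000).
#' @param seed Integer seed; same seed gives identical results.
#' @param minSize Sets with fewer members in the universe are skipped
#'   (default 5).
#' @param weightP Score weight exponent.
#' @param qThreshold Significance threshold recorded in the output
#'   (default 0.05).
#' @return A `data.frame`: `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `direction` (sign of NES), `significant` (`q < qThreshold`).
#' @export
gseaPreranked <- function(ranked, collection, nPerm = 1000L, seed = 1L,
                          minSize = 5L, weightP = 1, qThreshold = 0.05) {
    if (!length(collection)) stop("empty gene-set collection")
    if (nPerm < 100L) stop("'nPerm' must be >= 100")
    N <- length(ranked)
    absW <- abs(ranked)^weightP
    sizes <- vapply(collection, function(s)
        sum(names(ranked) %in% s), 0L)
    keep <- sizes >= minSize & sizes < N
    if (any(!keep))
        message(sum(!keep), " gene set(s) skipped (fewer than ", minSize,
                " members in the universe, or covering it)")
    collection <- collection[keep]
    sizes <- sizes[keep]
    if (!length(collection)) stop("no gene set passes the size floor")
    es <- vapply(names(collection), function(nm)
        gseaES(ranked, collection[[nm]], weightP), numeric(1))

    # one null ensemble per distinct set size, shared across same-size sets
    nullBySize <- new.env(parent = emptyenv())
    withSeed(subSeed(seed, "gsea_perm"), {
        for (m in sort(unique(sizes))) {
            null <- vapply(seq_len(nPerm), function(b)
                .esFromIdx(absW, sort(sample.int(N, m)), N), numeric(1))
            assign(as.character(m), null, envir = nullBySize)
        }
    })
    nes <- p <- rep(NA_real_, length(es))
    for (i in seq_along(es)) {
        null <- get(as.character(sizes[i]), envir = nullBySize)
        same <- if (es[i] >= 0) null[null >= 0] else -null[null < 0]
        obs <- abs(es[i])
        if (length(same)) {
            nes[i] <- sign(es[i]) * obs / mean(same)
            p[i] <- (sum(same >= obs) + 1) / (length(same) + 1)
        } else {
            nes[i] <- sign(es[i]) * Inf
            p[i] <- 1 / (nPerm + 1)
        }
    }
    q <- bhAdjust(p)
    data.frame(set = names(collection), size = as.integer(sizes),
               es = es, nes = nes, p = p, q = q,
               direction = as.integer(sign(nes)),
               significant = q < qThreshold,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability `P(X >= overlap)` of the overlap
#' between a query gene list and each set of a collection, within a stated
#' universe; sets are intersected with the universe first. q is
#' Benjamini-Hochberg across the collection.
#'
#' @param query Character vector of gene ids, a subset of `universe`.
#' @param universe Character vector: the tested gene universe.
#' @param collection Named list of gene sets.
#' @return A `data.frame`: `set`, `overlap`, `querySize`, `setSize`,
#'   `universeSize`, `p`, `q`, plus `members` (comma-joined overlapping
#'   genes, for downstream set grouping).
#' @examples
#' u <- paste0("g", 1:10)
#' hypergeomEnrich(u[1:5], u, list(s = u[1:5]))$p  # 1/choose(10,5)
#' @export
hypergeomEnrich <- function(query, universe, collection) {
    query <- unique(query)
    universe <- unique(universe)
    if (!all(query %in% universe))
        stop("query contains genes outside the universe")
    U <- length(universe)
    rows <- lapply(names(collection), function(nm) {
        s <- intersect(collection[[nm]], universe)
        ov <- intersect(query, s)
        k <- length(ov)
        p <- stats::phyper(k - 1, length(s), U - length(s),
                           length(query), lower.tail = FALSE)
        data.frame(set = nm, overlap = k, querySize = length(query),
                   setSize = length(s), universeSize = U, p = p,
                   members = paste(sort(ov), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- bhAdjust(out$p)
    out[, c("set", "overlap", "querySize", "setSize", "universeSize",
            "p", "q", "members")]
}
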