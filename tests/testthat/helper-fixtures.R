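# Shared fixtures, built in code at test time.

# tiny FirthDataSet with explicit counts and conditions
makeTinyFds <- function(counts, condition, biotype = NULL, batch = NULL) {
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("g", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    cd <- data.frame(condition = condition)
    if (!is.null(batch)) cd$batch <- batch
    rd <- NULL
    if (!is.null(biotype)) rd <- data.frame(biotype = biotype)
    FirthDataSet(counts, colData = cd, rowData = rd)
}

# random 2x2-structured logistic dataset from a table of cell counts
tableToYX <- function(n11, n12, n21, n22) {
    list(y = rep(c(1, 1, 0, 0), c(n11, n12, n21, n22)),
         x = rep(c(1, 0, 1, 0), c(n11, n12, n21, n22)))
}

# add-1/2 cell-corrected log odds ratio: the exact Firth estimate for a
# saturated 2x2 logistic model (the independent oracle)
addHalfLOR <- function(n11, n12, n21, n22)
    log((n11 + 0.5) * (n22 + 0.5) / ((n12 + 0.5) * (n21 + 0.5)))

# brute-force GSEA running-sum extremes: explicit per-prefix hit/miss
# sums, independent of the package's position-based evaluation
bruteExtremes <- function(ranked, set, weightP = 1) {
    hit <- names(ranked) %in% set
    nr <- sum(abs(ranked[hit])^weightP)
    nMiss <- sum(!hit)
    devs <- vapply(seq_along(ranked), function(i) {
        pHit <- sum(abs(ranked[seq_len(i)][hit[seq_len(i)]])^weightP) / nr
        pMiss <- sum(!hit[seq_len(i)]) / nMiss
        pHit - pMiss
    }, numeric(1))
    c(max = max(devs, 0), min = min(devs, 0))
}

# signed maximum deviation with the same deterministic tie rule as the
# package (exact tie between the positive and negative extreme -> positive)
bruteES <- function(ranked, set, weightP = 1) {
    ex <- bruteExtremes(ranked, set, weightP)
    if (ex["max"] >= -ex["min"]) unname(ex["max"]) else unname(ex["min"])
}

# brute-force RRA score: evaluate every binomial tail directly via sums of
# dbinom terms (independent of pbinom's survival path)
bruteRho <- function(r) {
    n <- length(r)
    rs <- sort(r)
    beta <- vapply(seq_len(n), function(k)
        sum(vapply(k:n, function(j) choose(n, j) * rs[k]^j *
                       (1 - rs[k])^(n - j), numeric(1))), numeric(1))
    list(rho = min(beta), corrected = min(1, n * min(beta)))
}
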