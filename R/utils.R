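#' @include AllClasses.R
NULL

# Deterministic sub-seed derivation: one user-facing seed fans out to
# independent per-component streams. Kept below 2^31 - 1 for set.seed().
subSeed <- function(seed, component) {
    s <- (as.numeric(seed) %% 2147483647) + 1
    for (tok in utf8ToInt(as.character(component)))
        s <- (s * 48271 + tok) %% 2147483647
    as.integer(s)
}

withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Benjamini-Hochberg adjustment with missing-value propagation
#'
#' Step-up FDR adjustment. `NA` p-values (e.g. genes whose model fit failed)
#' propagate as `NA` and do not enter the number of tests, so q-values of
#' successfully tested genes are not deflated by failed fits.
#'
#' @param p Numeric vector of p-values in `[0,1]`; `NA` allowed.
#' @return Adjusted q-values, same length and names as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p)) stop("'p' must be numeric")
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p-values must lie in [0,1]")
    q <- rep(NA_real_, length(p))
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    names(q) <- names(p)
    q
}

# TSV conventions shared by the pipeline: plain tab-separated, header row,
# no quoting, no row names.
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      comment.char = "", check.names = FALSE,
                      stringsAsFactors = FALSE)
}
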