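#' @include utils.R
NULL

#' Read a GMT gene-set file
#'
#' Parses the MSigDB GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then one field per member. Trailing tabs / empty
#' member fields are ignored. Lines with fewer than three fields are a
#' parse error naming the line; duplicate set names are an error; duplicate
#' members within a set are deduplicated with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character member vectors, with per-set
#'   descriptions in `attr(, "description")`.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 0L) < 3L |
                 vapply(fields, function(f)
                     sum(nzchar(f[-(1:2)])), 0L) < 1L)
    if (length(bad))
        stop("GMT parse error: line ", bad[1],
             " has no members (need name, description, >=1 member)")
    nm <- vapply(fields, `[`, "", 1L)
    if (anyDuplicated(nm))
        stop("duplicate gene-set names in GMT: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    desc <- vapply(fields, `[`, "", 2L)
    sets <- lapply(fields, function(f) {
        mem <- f[-(1:2)]
        mem <- mem[nzchar(mem)]
        if (anyDuplicated(mem)) {
            warning("duplicate members deduplicated in set '", f[1], "'")
            mem <- unique(mem)
        }
        mem
    })
    names(sets) <- nm
    attr(sets, "description") <- stats::setNames(desc, nm)
    sets
}

#' Write a gene-set collection as GMT
#'
#' @param collection Named list of character member vectors; optional
#'   per-set descriptions in `attr(collection, "description")` (default
#'   `"na"`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGmt <- function(collection, path) {
    if (is.null(names(collection)) || any(!nzchar(names(collection))))
        stop("all gene sets must be named")
    if (anyDuplicated(names(collection)))
        stop("duplicate gene-set names")
    if (any(vapply(collection, length, 0L) == 0L))
        stop("gene sets must be non-empty")
    desc <- attr(collection, "description")
    if (is.null(desc))
        desc <- stats::setNames(rep("na", length(collection)),
                                names(collection))
    lines <- vapply(names(collection), function(nm)
        paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}
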