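#' @include utils.R
NULL

#' Standardize a vector to mean 0, sample SD 1
#'
#' Centering and scaling used before the logistic fit so the count
#' coefficient is a standardized log odds ratio (log-odds change per 1 SD
#' of normalized abundance), comparable across genes.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return `(x - mean(x)) / sd(x)` (sample SD, denominator n - 1).
#' @examples
#' standardizeVector(c(1, 2, 3))  # -1 0 1
#' @export
standardizeVector <- function(x) {
    if (length(unique(x)) < 2)
        stop("cannot standardize a constant vector")
    (x - mean(x)) / stats::sd(x)
}

# penalized log-likelihood l*(beta) = l(beta) + 0.5 log det X'WX
.firthLogLik <- function(y, X, beta) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    W <- mu * (1 - mu)
    info <- crossprod(X, X * W)
    sum(y * log(mu) + (1 - y) * log(1 - mu)) +
        0.5 * determinant(info, logarithm = TRUE)$modulus[1]
}

#' Firth penalized logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' `l(beta) + 0.5 log det I(beta)` by Newton-Raphson on the Firth-modified
#' score `X'(y - mu + h (1/2 - mu))`, with step-halving whenever a step
#' would decrease the penalized likelihood. Estimates are finite even under
#' complete separation, where ordinary logistic ML diverges.
#'
#' @param y Binary response vector (0/1 or logical), both classes present.
#' @param X Design matrix including the intercept column; full column rank.
#' @param tol Convergence tolerance on the sup-norm of the modified score
#'   (default 1e-6).
#' @param maxIter Maximum Newton iterations (default 50); if reached,
#'   `converged` is `FALSE`.
#' @return A list of class `"firth_fit"`: `coefficients`, `se`,
#'   `logLik` (penalized, at the optimum), `iter`, `converged`.
#' @examples
#' # complete separation: x perfectly splits y, yet the estimate is finite
#' y <- rep(c(1, 0), each = 4)
#' X <- cbind(1, rep(c(1, 0), each = 4))
#' firthFit(y, X)$coefficients[2]  # log(81)
#' @export
firthFit <- function(y, X, tol = 1e-6, maxIter = 50L) {
    y <- as.numeric(y)
    X <- as.matrix(X)
    if (anyNA(y) || anyNA(X)) stop("NA in response or design")
    if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
    if (length(unique(y)) < 2) stop("'y' must contain both classes")
    if (nrow(X) != length(y)) stop("dimension mismatch between y and X")
    if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")

    p <- ncol(X)
    beta <- numeric(p)
    beta[1] <- stats::qlogis(mean(y))   # intercept start at observed odds
    ll <- .firthLogLik(y, X, beta)
    converged <- FALSE
    iter <- 0L
    info <- NULL
    for (iter in seq_len(maxIter)) {
        eta <- drop(X %*% beta)
        mu <- stats::plogis(eta)
        mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
        W <- mu * (1 - mu)
        info <- crossprod(X, X * W)
        infoInv <- solve(info)
        h <- rowSums((X %*% infoInv) * X) * W   # hat-matrix diagonal
        score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
        delta <- drop(infoInv %*% score)
        if (max(abs(score)) < tol) {
            # polish with damped half-steps: drives the score far below
            # the declared tolerance and cannot 2-cycle the way full
            # Newton steps can near quasi-separated optima
            for (extra in seq_len(30L)) {
                beta <- beta + 0.5 * delta
                eta <- drop(X %*% beta)
                mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
                W <- mu * (1 - mu)
                info <- crossprod(X, X * W)
                infoInv <- solve(info)
                h <- rowSums((X %*% infoInv) * X) * W
                score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
                delta <- drop(infoInv %*% score)
                if (max(abs(score)) < tol * 1e-6) break
            }
            ll <- .firthLogLik(y, X, beta)
            converged <- TRUE
            break
        }
        # line search along the Newton direction: take the first halved
        # step that strictly improves the penalized likelihood; if the
        # surface is locally flat (e.g. Newton 2-cycles around the
        # optimum under quasi-separation), fall back to the best tried
        # step instead of accepting a non-improving full step
        step <- 1
        best <- NULL
        llBest <- -Inf
        for (half in seq_len(20L)) {
            cand <- beta + step * delta
            llNew <- .firthLogLik(y, X, cand)
            if (is.finite(llNew) && llNew > llBest) {
                best <- cand
                llBest <- llNew
            }
            if (is.finite(llNew) && llNew > ll + 1e-13) break
            step <- step / 2
        }
        beta <- best
        ll <- llBest
    }
    se <- sqrt(diag(solve(info)))
    names(beta) <- names(se) <- colnames(X)
    structure(list(coefficients = beta, se = se, logLik = ll,
                   iter = iter, converged = converged),
              class = "firth_fit")
}

#' @export
print.firth_fit <- function(x, ...) {
    cat("Firth logistic fit (penalized logLik ",
        format(x$logLik, digits = 6), ", ",
        x$iter, " iterations", if (!x$converged) ", NOT converged", ")\n",
        sep = "")
    print(cbind(coef = x$coefficients, se = x$se))
    invisible(x)
}

# profile fit: maximize the FULL model's penalized likelihood over the
# nuisance coefficients with beta[fixedIndex] held at 0. The penalty stays
# 0.5 log det I(beta) of the full design, as required for the penalized
# likelihood-ratio test.
.firthFitFixed <- function(y, X, fixedIndex, tol = 1e-6, maxIter = 50L) {
    p <- ncol(X)
    free <- setdiff(seq_len(p), fixedIndex)
    beta <- numeric(p)
    beta[1] <- if (1 %in% free) stats::qlogis(mean(y)) else 0
    ll <- .firthLogLik(y, X, beta)
    converged <- FALSE
    for (iter in seq_len(maxIter)) {
        eta <- drop(X %*% beta)
        mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
        W <- mu * (1 - mu)
        info <- crossprod(X, X * W)
        infoInv <- solve(info)
        h <- rowSums((X %*% infoInv) * X) * W
        score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))[free]
        delta <- numeric(p)
        delta[free] <- drop(solve(info[free, free, drop = FALSE], score))
        if (max(abs(score)) < tol) {
            for (extra in seq_len(30L)) {
                beta <- beta + 0.5 * delta
                eta <- drop(X %*% beta)
                mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
                W <- mu * (1 - mu)
                info <- crossprod(X, X * W)
                infoInv <- solve(info)
                h <- rowSums((X %*% infoInv) * X) * W
                score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))[free]
                delta <- numeric(p)
                delta[free] <- drop(
                    solve(info[free, free, drop = FALSE], score))
                if (max(abs(score)) < tol * 1e-6) break
            }
            ll <- .firthLogLik(y, X, beta)
            converged <- TRUE
            break
        }
        step <- 1
        best <- NULL
        llBest <- -Inf
        for (half in seq_len(20L)) {
            cand <- beta + step * delta
            llNew <- .firthLogLik(y, X, cand)
            if (is.finite(llNew) && llNew > llBest) {
                best <- cand
                llBest <- llNew
            }
            if (is.finite(llNew) && llNew > ll + 1e-13) break
            step <- step / 2
        }
        beta <- best
        ll <- llBest
    }
    list(coefficients = beta, logLik = ll, iter = iter,
         converged = converged)
}

#' Penalized likelihood-ratio test for one model term
#'
#' Tests a single design column by comparing the full Firth fit with the
#' profile fit in which the tested coefficient is fixed at zero while the
#' nuisance coefficients are re-maximized — both under the full model's
#' Jeffreys penalty. The statistic `2 (l*_full - l*_profile)` is referred
#' to chi-square with 1 df.
#'
#' @param y Binary response.
#' @param X Full design matrix (with intercept).
#' @param termIndex Column of `X` to test (default 2, the covariate after
#'   the intercept).
#' @param ... Passed to [firthFit()].
#' @return A list: `p` (in `(0,1]`, `NA` when either fit fails to
#'   converge), `stat`, `fitFull`, `fitReduced`.
#' @export
firthTest <- function(y, X, termIndex = 2L, ...) {
    X <- as.matrix(X)
    if (termIndex < 1L || termIndex > ncol(X))
        stop("'termIndex' out of range")
    fitFull <- firthFit(y, X, ...)
    fitRed <- .firthFitFixed(y, X, termIndex, ...)
    if (!fitFull$converged || !fitRed$converged)
        return(list(p = NA_real_, stat = NA_real_,
                    fitFull = fitFull, fitReduced = fitRed))
    stat <- max(0, 2 * (fitFull$logLik - fitRed$logLik))
    list(p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         stat = stat, fitFull = fitFull, fitReduced = fitRed)
}
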