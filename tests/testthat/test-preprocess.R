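test_that("biotype filter keeps exactly the allowed biotypes, in order", {
    m <- matrix(1:12, nrow = 3,
                dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
    fds <- makeTinyFds(m, c("HD", "HD", "C", "C"),
                       biotype = c("protein_coding", "miRNA", "lincRNA"))
    out <- suppressMessages(filterBiotypes(fds))
    expect_identical(rownames(out), c("a", "c"))

    allPC <- makeTinyFds(m, c("HD", "HD", "C", "C"),
                         biotype = rep("protein_coding", 3))
    expect_identical(rownames(suppressMessages(filterBiotypes(allPC))),
                     rownames(allPC))
    # empty whitelist: empty result, not an error
    expect_equal(nrow(suppressMessages(
        filterBiotypes(fds, allowed = character()))), 0)
    # idempotent
    twice <- suppressMessages(filterBiotypes(out))
    expect_identical(rownames(twice), rownames(out))
    # missing annotation is an error naming offenders
    bad <- makeTinyFds(m, c("HD", "HD", "C", "C"),
                       biotype = c("protein_coding", NA, "lincRNA"))
    expect_error(suppressMessages(filterBiotypes(bad)), "b")
})

test_that("both spellings of the sense-overlapping biotype are accepted", {
    expect_true(all(c("sense_overlaping", "sense_overlapping") %in%
                    polyABiotypes()))
})

test_that("zero-count filter uses a strict more-than-half rule per group", {
    cond <- rep(c("HD", "C"), each = 4)
    m <- rbind(
        dropCase = c(0, 0, 0, 5, 3, 3, 3, 3),  # 3/4 case zeros -> drop
        boundary = c(0, 0, 4, 4, 0, 0, 4, 4),  # exactly half both -> keep
        keepAll  = c(2, 2, 2, 2, 2, 2, 2, 2),
        dropCtrl = c(5, 5, 5, 5, 0, 0, 0, 2))  # 3/4 control zeros -> drop
    colnames(m) <- paste0("s", 1:8)
    fds <- makeTinyFds(m, cond)
    out <- suppressMessages(
        filterLowCounts(fds, caseConditions = "HD"))
    expect_identical(rownames(out), c("boundary", "keepAll"))
    expect_error(filterLowCounts(fds, caseConditions = "PD"), "empty")
})

test_that("median-of-ratios size factors match hand-derived values", {
    m <- rbind(g1 = c(2, 8), g2 = c(2, 8))
    colnames(m) <- c("a", "b")
    expect_equal(unname(sizeFactorsMoR(m)), c(0.5, 2))

    ident <- rbind(g1 = c(5, 5), g2 = c(9, 9))
    colnames(ident) <- c("a", "b")
    expect_equal(unname(sizeFactorsMoR(ident)), c(1, 1))

    # gene with a zero is excluded from the reference set
    withZero <- rbind(g1 = c(0, 4), g2 = c(3, 3))
    colnames(withZero) <- c("a", "b")
    expect_equal(unname(sizeFactorsMoR(withZero)), c(1, 1))

    allZero <- rbind(g1 = c(0, 4), g2 = c(3, 0))
    colnames(allZero) <- c("a", "b")
    expect_error(sizeFactorsMoR(allZero), "prefilter")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
    skip_if_not_installed("DESeq2")
    fds <- simulateCohort(simParams(nGenes = 500, seed = 31))
    keep <- rowSums(counts(fds) > 0) == ncol(fds)
    m <- counts(fds)[keep, ]
    expect_equal(unname(sizeFactorsMoR(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-12)
})

test_that("normalization divides by factors and preserves within-sample ranks", {
    m <- matrix(c(8, 2, 4, 6), nrow = 2,
                dimnames = list(c("g1", "g2"), c("a", "b")))
    fds <- makeTinyFds(m, c("HD", "C"))
    sizeFactors(fds) <- c(2, 1)
    fds <- normalizeCounts(fds)
    expect_equal(normCounts(fds)[, "a"], c(g1 = 4, g2 = 1))
    expect_equal(normCounts(fds)[, "b"], c(g1 = 4, g2 = 6))

    sim <- normalizeCounts(computeSizeFactors(
        suppressMessages(filterLowCounts(
            simulateCohort(simParams(nGenes = 200, seed = 7))))))
    for (j in c(1, 50)) {
        expect_identical(order(normCounts(sim)[, j]),
                         order(counts(sim)[, j]))
    }
    # median over reference genes of normalized/geomean equals 1 per sample
    nm <- normCounts(sim)
    ref <- rowSums(counts(sim) > 0) == ncol(sim)
    geo <- exp(rowMeans(log(counts(sim)[ref, ])))
    ratios <- nm[ref, ] / geo
    expect_equal(unname(apply(ratios, 2, median)),
                 rep(1, ncol(sim)), tolerance = 1e-12)
})

test_that("winsorization clamps only extreme values and keeps group medians", {
    m <- rbind(g1 = c(10, 11, 12, 1000, 7, 8, 9, 10))
    colnames(m) <- paste0("s", 1:8)
    fds <- makeTinyFds(m, rep(c("HD", "C"), each = 4))
    sizeFactors(fds) <- rep(1, 8)
    fds <- normalizeCounts(fds)
    out <- trimOutliers(fds, zMax = 3)
    hd <- normCounts(out)[1, 1:4]
    # group (10,11,12,1000): median 11.5, MAD = 1.4826 * 1.5
    bound <- 11.5 + 3 * stats::mad(c(10, 11, 12, 1000))
    expect_equal(unname(hd), c(10, 11, 12, bound))
    expect_equal(median(hd), median(c(10, 11, 12, 1000)))
    expect_lte(diff(range(hd)), diff(range(c(10, 11, 12, 1000))))
    # untouched group unchanged
    expect_equal(unname(normCounts(out)[1, 5:8]), c(7, 8, 9, 10))

    # no value beyond the threshold: identity
    calm <- makeTinyFds(rbind(g1 = c(10, 11, 12, 13, 7, 8, 9, 10)),
                        rep(c("HD", "C"), each = 4))
    sizeFactors(calm) <- rep(1, 8)
    calm <- normalizeCounts(calm)
    expect_equal(normCounts(trimOutliers(calm)), normCounts(calm))

    # constant group (MAD = 0): untouched
    flat <- makeTinyFds(rbind(g1 = c(5, 5, 5, 5, 1, 2, 3, 90)),
                        rep(c("HD", "C"), each = 4))
    sizeFactors(flat) <- rep(1, 8)
    flat <- normalizeCounts(flat)
    expect_equal(unname(normCounts(trimOutliers(flat))[1, 1:4]),
                 rep(5, 4))

    # groups smaller than 3 samples are skipped with a warning
    tiny <- makeTinyFds(rbind(g1 = c(1, 100, 2, 3, 4, 5)),
                        c("HD", "HD", "C", "C", "C", "C"))
    sizeFactors(tiny) <- rep(1, 6)
    tiny <- normalizeCounts(tiny)
    expect_warning(trimOutliers(tiny), "fewer than 3")
})

test_that("full preprocessing applies filters in order and returns trimmed matrix", {
    fds <- simulateCohort(simParams(nGenes = 300, seed = 13))
    out <- suppressMessages(preprocessCounts(fds))
    expect_true("normcounts" %in%
                SummarizedExperiment::assayNames(out))
    expect_true(all(normCounts(out) >= 0))
    expect_lte(nrow(out), nrow(fds))
    expect_false(is.null(sizeFactors(out)))
})
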