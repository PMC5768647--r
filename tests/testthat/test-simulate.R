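test_that("simulation is deterministic and honours planted fractions", {
    p <- simParams(nGenes = 300, seed = 11)
    a <- simulateCohort(p)
    b <- simulateCohort(p)
    expect_identical(counts(a), counts(b))
    expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                     as.data.frame(SummarizedExperiment::colData(b)))

    tr <- simTruth(a)
    expect_equal(sum(tr$label == "shared"), round(0.10 * 300))
    expect_equal(sum(tr$label == "d1_only"), round(0.05 * 300))
    expect_equal(sum(tr$label == "d2_only"), round(0.05 * 300))
    # null genes carry no effect in either disease
    expect_true(all(tr$lfc_d1[tr$label == "null"] == 0))
    expect_true(all(tr$lfc_d2[tr$label == "null"] == 0))
    # shared genes carry the same signed effect in both diseases
    sh <- tr$label == "shared"
    expect_identical(tr$lfc_d1[sh], tr$lfc_d2[sh])
    expect_true(all(abs(tr$lfc_d1[sh]) == 1))

    expect_equal(as.vector(table(conditions(a))[c("HD", "PD", "C")]),
                 c(29, 29, 49))
})

test_that("zero DE fractions give an all-null cohort", {
    fds <- simulateCohort(simParams(nGenes = 50, fracSharedDE = 0,
                                    fracD1OnlyDE = 0, fracD2OnlyDE = 0,
                                    seed = 3))
    expect_true(all(simTruth(fds)$label == "null"))
})

test_that("invalid simulation parameters are rejected", {
    expect_error(simParams(fracSharedDE = 0.7, fracD1OnlyDE = 0.4),
                 "sum")
    expect_error(simParams(nGenes = 0), ">= 1")
    expect_error(simParams(dispersion = -1), "dispersion")
    expect_error(simParams(sizeFactorRange = c(2, 1)), "interval")
})

test_that("size factors drive column sums as planted", {
    # two-sample design with scale factors 0.5 and 2: over many genes the
    # expected column-sum ratio is 4
    # plant the factors exactly through degenerate ranges: one cohort
    # scaled by 0.5 throughout, one by 2; same seed, same base means
    pa <- simParams(nDisease1 = 1, nDisease2 = 1, nControl = 1,
                    nGenes = 4000, fracSharedDE = 0, fracD1OnlyDE = 0,
                    fracD2OnlyDE = 0, sizeFactorRange = c(0.5, 0.5),
                    seed = 5)
    pb <- simParams(nDisease1 = 1, nDisease2 = 1, nControl = 1,
                    nGenes = 4000, fracSharedDE = 0, fracD1OnlyDE = 0,
                    fracD2OnlyDE = 0, sizeFactorRange = c(2, 2),
                    seed = 5)
    sa <- sum(counts(simulateCohort(pa)))
    sb <- sum(counts(simulateCohort(pb)))
    expect_equal(sb / sa, 4, tolerance = 0.05)
})

test_that("null-gene counts match the NB mean/variance parameterization", {
    alpha <- 0.2
    p <- simParams(nDisease1 = 250, nDisease2 = 250, nControl = 250,
                   nGenes = 60, fracSharedDE = 0, fracD1OnlyDE = 0,
                   fracD2OnlyDE = 0, dispersion = alpha,
                   sizeFactorRange = c(1, 1),
                   baselineMeanRange = c(100, 100), seed = 17)
    cts <- counts(simulateCohort(p))
    m <- rowMeans(cts)
    v <- apply(cts, 1, var)
    expect_equal(mean(m), 100, tolerance = 0.03)
    # variance = mu + alpha mu^2 = 100 + 0.2 * 10^4 = 2100
    expect_equal(mean(v), 100 + alpha * 100^2, tolerance = 0.1)
})

test_that("simulated gene sets honour purity and round-trip through GMT", {
    fds <- simulateCohort(simParams(nGenes = 400, seed = 23))
    gs <- simulateGeneSets(fds, nSets = 12, nEnriched = 3, seed = 23,
                           purity = 1)
    tr <- simTruth(fds)
    for (i in which(gs$truth$enriched)) {
        lab <- gs$truth$label[i]
        members <- gs$collection[[i]]
        memLab <- tr[members, "label"]
        expect_true(all(memLab == lab))
        effCol <- if (lab == "d2_only") "lfc_d2" else "lfc_d1"
        expect_true(all(sign(tr[members, effCol]) ==
                        gs$truth$direction[i]))
    }
    # background sets are not label-pure
    bg <- gs$collection[!gs$truth$enriched]
    expect_true(any(vapply(bg, function(s)
        length(unique(tr[s, "label"])) > 1, logical(1))))

    # GMT round trip with a fixed seed reproduces membership exactly
    path <- tempfile(fileext = ".gmt")
    writeGmt(gs$collection, path)
    back <- readGmt(path)
    expect_identical(unname(lapply(back, identity)),
                     unname(gs$collection))
    gs2 <- simulateGeneSets(fds, nSets = 12, nEnriched = 3, seed = 23,
                            purity = 1)
    expect_identical(gs$collection, gs2$collection)
})

test_that("cohort TSVs round-trip through writeCohort/readCohort", {
    fds <- simulateCohort(simParams(nGenes = 40, seed = 9))
    d <- tempfile()
    writeCohort(fds, d)
    back <- readCohort(file.path(d, "counts.tsv"),
                       file.path(d, "samples.tsv"),
                       file.path(d, "annotation.tsv"))
    expect_identical(counts(back), counts(fds))
    expect_identical(as.character(conditions(back)),
                     as.character(conditions(fds)))
    expect_identical(SummarizedExperiment::rowData(back)$biotype,
                     SummarizedExperiment::rowData(fds)$biotype)
})
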