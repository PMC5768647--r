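test_that("gene ranking is by descending LOR with id tie-break", {
    res <- S4Vectors::DataFrame(gene_id = c("a", "b", "c"),
                                lor = c(2, -1, 0.5))
    expect_identical(names(rankGenes(res)), c("a", "c", "b"))
    tied <- S4Vectors::DataFrame(gene_id = c("b", "a"), lor = c(1, 1))
    expect_identical(names(rankGenes(tied)), c("a", "b"))
    # sign reversal reverses the order exactly (distinct scores)
    res2 <- S4Vectors::DataFrame(gene_id = letters[1:5],
                                 lor = c(3, -2, 1, 0.5, -0.1))
    expect_identical(names(rankGenes(
        S4Vectors::DataFrame(gene_id = res2$gene_id, lor = -res2$lor))),
        rev(names(rankGenes(res2))))
    dup <- S4Vectors::DataFrame(gene_id = c("a", "a"), lor = c(1, 2))
    expect_error(rankGenes(dup), "duplicate")
})

test_that("enrichment score matches hand-derived extremes and bounds", {
    r <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
    expect_equal(gseaES(r, "g1"), 1)
    expect_equal(gseaES(r, "g4"), -1)
    sym <- c(g1 = 2, g2 = 1, g3 = -1, g4 = -2)
    expect_equal(gseaES(sym, c("g2", "g3")),
                 bruteES(sym, c("g2", "g3")), tolerance = 1e-12)
    expect_error(gseaES(r, c("g1", "g2", "g3", "g4")), "whole")
    expect_error(gseaES(r, "zz"), "disjoint")
})

test_that("enrichment score equals the brute-force running sum on random universes", {
    set.seed(7)
    for (i in 1:40) {
        N <- sample(8:50, 1)
        r <- sort(rnorm(N), decreasing = TRUE)
        names(r) <- paste0("g", seq_len(N))
        m <- sample(1:(N - 1), 1)
        set <- sample(names(r), m)
        for (wp in c(0, 1)) {
            expect_equal(gseaES(r, set, weightP = wp),
                         bruteES(r, set, weightP = wp),
                         tolerance = 1e-12)
        }
    }
})

test_that("reversing a symmetric ranking negates the enrichment score", {
    set.seed(11)
    for (i in 1:20) {
        N <- 20
        half <- sort(runif(N / 2, 0.5, 3), decreasing = TRUE)
        scores <- c(half, -rev(half))   # antisymmetric score profile
        names(scores) <- paste0("g", seq_len(N))
        rev_scores <- stats::setNames(rev(-scores), rev(names(scores)))
        set <- sample(names(scores), 5)
        ex <- bruteExtremes(scores, set)
        if (abs(ex["max"] + ex["min"]) < 1e-9) {
            # exact positive/negative tie: both orientations report the
            # positive extreme by the deterministic tie rule
            expect_equal(gseaES(rev_scores, set), gseaES(scores, set),
                         tolerance = 1e-12)
        } else {
            expect_equal(gseaES(rev_scores, set), -gseaES(scores, set),
                         tolerance = 1e-12)
        }
    }
})

test_that("enrichment score agrees with the fgsea reference statistic", {
    skip_if_not_installed("fgsea")
    set.seed(3)
    N <- 40
    r <- sort(rnorm(N), decreasing = TRUE)
    names(r) <- paste0("g", seq_len(N))
    for (i in 1:10) {
        set <- sample(names(r), sample(3:15, 1))
        ref <- fgsea::calcGseaStat(r, selectedStats = which(names(r) %in% set),
                                   gseaParam = 1)
        expect_equal(gseaES(r, set), ref, tolerance = 1e-10)
    }
})

test_that("preranked GSEA recovers planted sets, is seeded, and calibrated", {
    fds <- simulateCohort(simParams(nGenes = 400, nDisease1 = 15,
                                    nDisease2 = 15, nControl = 20,
                                    seed = 77))
    fds <- suppressMessages(preprocessCounts(fds, allowed = NULL))
    gs <- simulateGeneSets(fds, nSets = 15, nEnriched = 3, seed = 77,
                           purity = 1)
    res <- firthDE(fds, makeContrast("ND_vs_C", c("HD", "PD")))
    ranked <- rankGenes(res)
    out <- gseaPreranked(ranked, gs$collection, nPerm = 1000, seed = 5)
    out2 <- gseaPreranked(ranked, gs$collection, nPerm = 1000, seed = 5)
    expect_identical(out, out2)
    expect_true(all(abs(out$es) <= 1))
    expect_true(all(out$p > 0 & out$p <= 1))

    sharedSets <- gs$truth$set[gs$truth$enriched &
                               gs$truth$label == "shared"]
    hit <- out[out$set %in% sharedSets, ]
    expect_true(all(hit$q < 0.05))
    expect_identical(hit$direction,
                     gs$truth$direction[match(hit$set, gs$truth$set)])
})

test_that("null rankings give roughly uniform nominal GSEA p-values", {
    set.seed(21)
    N <- 300
    scores <- sort(rnorm(N), decreasing = TRUE)
    names(scores) <- paste0("g", seq_len(N))
    coll <- lapply(1:40, function(i) sample(names(scores), 20))
    names(coll) <- paste0("S", 1:40)
    out <- gseaPreranked(scores, coll, nPerm = 200, seed = 9)
    # background sets under a null ranking: p roughly uniform
    expect_gt(suppressWarnings(ks.test(out$p, "punif"))$p.value, 0.01)
    expect_error(gseaPreranked(scores, list(), nPerm = 200), "empty")
    expect_error(gseaPreranked(scores, coll, nPerm = 10), ">= 100")
})

test_that("hypergeometric enrichment reproduces exact worked values", {
    u <- paste0("g", 1:10)
    res <- hypergeomEnrich(u[1:5], u, list(s = u[1:5]))
    expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)

    res2 <- hypergeomEnrich(u, u, list(s = u))
    expect_equal(res2$p, 1)

    u4 <- paste0("g", 1:4)
    res3 <- hypergeomEnrich(u4[1:2], u4, list(s = c("g2", "g3")))
    expect_equal(res3$p, 5 / 6, tolerance = 1e-12)
    expect_error(hypergeomEnrich(c("g1", "zz"), u4, list(s = u4[1:2])),
                 "outside")
})

test_that("GMT parsing validates structure and round-trips", {
    path <- tempfile(fileext = ".gmt")
    coll <- list(A = c("g1", "g2", "g3"), B = c("g2", "g4"))
    writeGmt(coll, path)
    expect_identical(unname(lapply(readGmt(path), identity)),
                     unname(coll))

    # trailing tabs do not create empty members
    writeLines("C\tdesc\tg1\tg2\t\t", path)
    expect_identical(readGmt(path)$C, c("g1", "g2"))

    # two fields only: parse error naming the line
    writeLines(c("A\tdesc\tg1", "B\tdesc"), path)
    expect_error(readGmt(path), "line 2")

    # duplicate set names are an error, duplicate members a warning
    writeLines(c("A\td\tg1", "A\td\tg2"), path)
    expect_error(readGmt(path), "duplicate")
    writeLines("A\td\tg1\tg1\tg2", path)
    expect_warning(out <- readGmt(path), "deduplicated")
    expect_identical(out$A, c("g1", "g2"))
})

test_that("GMT reader agrees with the fgsea reference parser", {
    skip_if_not_installed("fgsea")
    path <- tempfile(fileext = ".gmt")
    coll <- list(S1 = c("a", "b", "c"), S2 = c("b", "d", "e", "f"))
    writeGmt(coll, path)
    ref <- fgsea::gmtPathways(path)
    expect_identical(unname(lapply(readGmt(path), identity)),
                     unname(ref))
})
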