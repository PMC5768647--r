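#' @include utils.R
NULL

#' Create simulation parameters
#'
#' Constructor for [SimParams-class]. Defaults emulate a two-disease
#' post-mortem cohort (29/29/49 samples) with 10% shared, 5% + 5%
#' disease-unique differentially expressed genes at |log2FC| = 1.
#'
#' @param nDisease1,nDisease2,nControl Group sample sizes.
#' @param nGenes Number of genes.
#' @param fracSharedDE,fracD1OnlyDE,fracD2OnlyDE Fractions of genes with
#'   shared / disease-1-unique / disease-2-unique effects (sum <= 1).
#' @param lfcMagnitude Absolute planted log2 fold change.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param sizeFactorRange Uniform range of per-sample scale multipliers.
#' @param baselineMeanRange Log-uniform range of per-gene base means.
#' @param nBatches Number of sequencing batches (samples assigned cyclically).
#' @param batchLfc Log2 shift applied to even-numbered batches.
#' @param seed Integer seed driving all randomness.
#' @return A validated [SimParams-class] object.
#' @examples
#' simParams(nGenes = 500, seed = 7)
#' @export
simParams <- function(nDisease1 = 29L, nDisease2 = 29L, nControl = 49L,
                      nGenes = 2000L,
                      fracSharedDE = 0.10, fracD1OnlyDE = 0.05,
                      fracD2OnlyDE = 0.05,
                      lfcMagnitude = 1, dispersion = 0.1,
                      sizeFactorRange = c(0.5, 2),
                      baselineMeanRange = c(10, 1000),
                      nBatches = 1L, batchLfc = 0, seed = 1L) {
    methods::new("SimParams",
        nDisease1 = as.integer(nDisease1), nDisease2 = as.integer(nDisease2),
        nControl = as.integer(nControl), nGenes = as.integer(nGenes),
        fracSharedDE = fracSharedDE, fracD1OnlyDE = fracD1OnlyDE,
        fracD2OnlyDE = fracD2OnlyDE,
        lfcMagnitude = lfcMagnitude, dispersion = dispersion,
        sizeFactorRange = as.numeric(sizeFactorRange),
        baselineMeanRange = as.numeric(baselineMeanRange),
        nBatches = as.integer(nBatches), batchLfc = batchLfc,
        seed = as.integer(seed))
}

# Table-1-like covariate profiles (mean, sd) per condition. The covariates
# carry no effect on counts: they exist so the DE design-matrix path is
# exercised while planted truth stays clean.
.covProfiles <- list(
    HD = c(age = 60.5, age_sd = 11.4, pmi = 16.4, pmi_sd = 7.8,
           rin = 7.1, rin_sd = 1.2),
    PD = c(age = 77.5, age_sd = 8.9, pmi = 11.1, pmi_sd = 9.7,
           rin = 7.0, rin_sd = 0.7),
    C  = c(age = 68.6, age_sd = 15.8, pmi = 14.6, pmi_sd = 9.5,
           rin = 7.8, rin_sd = 0.7))

#' Simulate a case/case/control RNA-seq cohort with planted truth
#'
#' Draws negative-binomial counts with per-sample scale factors and planted
#' log2 effects: `mu[g,j] = baseMean[g] * sizeFactor[j] * 2^effect(g, cond_j)`
#' (times a batch shift when `nBatches > 1` and `batchLfc != 0`), variance
#' `mu + dispersion * mu^2`. Disease 1 samples are labelled `"HD"`, disease 2
#' `"PD"`, controls `"C"`. Per-gene truth labels (`null`, `shared`,
#' `d1_only`, `d2_only`) and signed per-disease log2 effects are recorded in
#' `rowData` and retrievable via [simTruth()]. Identical parameters and seed
#' reproduce the output bit for bit.
#'
#' @param params A [SimParams-class] object from [simParams()].
#' @return A [FirthDataSet-class] with assay `"counts"`, colData columns
#'   `condition`, `batch`, `age_at_death`, `PMI`, `RIN`, and truth columns in
#'   `rowData` (`symbol`, `biotype`, `label`, `lfc_d1`, `lfc_d2`).
#' @examples
#' fds <- simulateCohort(simParams(nGenes = 100, seed = 1))
#' table(simTruth(fds)$label)
#' @export
simulateCohort <- function(params) {
    stopifnot(methods::is(params, "SimParams"))
    methods::validObject(params)
    nG <- params@nGenes
    nS <- params@nDisease1 + params@nDisease2 + params@nControl
    geneIds <- sprintf("GENE%05d", seq_len(nG))
    sampleIds <- sprintf("S%03d", seq_len(nS))
    condition <- factor(rep(c("HD", "PD", "C"),
                            c(params@nDisease1, params@nDisease2,
                              params@nControl)),
                        levels = c("HD", "PD", "C"))

    # planted effect assignment
    nShared <- round(params@fracSharedDE * nG)
    nD1 <- round(params@fracD1OnlyDE * nG)
    nD2 <- round(params@fracD2OnlyDE * nG)
    label <- rep("null", nG)
    lfc1 <- lfc2 <- numeric(nG)
    withSeed(subSeed(params@seed, "assignment"), {
        idx <- sample.int(nG, nShared + nD1 + nD2)
        iShared <- idx[seq_len(nShared)]
        iD1 <- idx[nShared + seq_len(nD1)]
        iD2 <- idx[nShared + nD1 + seq_len(nD2)]
        label[iShared] <- "shared"
        label[iD1] <- "d1_only"
        label[iD2] <- "d2_only"
        sgn <- sample(c(-1, 1), nG, replace = TRUE)
        lfc1[iShared] <- sgn[iShared] * params@lfcMagnitude
        lfc2[iShared] <- sgn[iShared] * params@lfcMagnitude
        lfc1[iD1] <- sgn[iD1] * params@lfcMagnitude
        lfc2[iD2] <- sgn[iD2] * params@lfcMagnitude
        biotype <- sample(c("protein_coding", "lincRNA"), nG,
                          replace = TRUE, prob = c(0.85, 0.15))
    })

    # covariates: Gaussian per condition group, no effect on counts
    withSeed(subSeed(params@seed, "covariates"), {
        prof <- .covProfiles[as.character(condition)]
        age <- vapply(prof, function(p)
            stats::rnorm(1, p["age"], p["age_sd"]), numeric(1))
        pmi <- vapply(prof, function(p)
            pmax(1, stats::rnorm(1, p["pmi"], p["pmi_sd"])), numeric(1))
        rin <- vapply(prof, function(p)
            pmin(10, pmax(1, stats::rnorm(1, p["rin"], p["rin_sd"]))),
            numeric(1))
    })

    batch <- factor(paste0("B", (seq_len(nS) - 1L) %% params@nBatches + 1L))

    withSeed(subSeed(params@seed, "counts"), {
        baseMean <- exp(stats::runif(nG, log(params@baselineMeanRange[1]),
                                     log(params@baselineMeanRange[2])))
        sf <- stats::runif(nS, params@sizeFactorRange[1],
                           params@sizeFactorRange[2])
        eff <- matrix(0, nG, nS)
        eff[, condition == "HD"] <- lfc1
        eff[, condition == "PD"] <- lfc2
        batchShift <- ifelse(as.integer(batch) %% 2L == 0L,
                             params@batchLfc, 0)
        mu <- baseMean * 2^eff *
            rep(sf * 2^batchShift, each = nG)
        cts <- matrix(stats::rnbinom(nG * nS, mu = mu,
                                     size = 1 / params@dispersion),
                      nG, nS)
    })
    dimnames(cts) <- list(geneIds, sampleIds)
    storage.mode(cts) <- "integer"

    colData <- S4Vectors::DataFrame(
        condition = condition, batch = batch,
        age_at_death = round(unname(age), 1), PMI = round(unname(pmi), 1),
        RIN = round(unname(rin), 1), row.names = sampleIds)
    rowData <- S4Vectors::DataFrame(
        symbol = sub("GENE", "SYM", geneIds), biotype = biotype,
        label = label, lfc_d1 = lfc1, lfc_d2 = lfc2, row.names = geneIds)
    fds <- FirthDataSet(cts, colData = colData, rowData = rowData)
    S4Vectors::metadata(fds)$simParams <- params
    fds
}

#' Simulate gene-set collections with planted enrichment
#'
#' Builds `nSets` gene sets over the simulated gene universe. The first
#' `nEnriched` sets are enriched: each targets one truth label (cycling
#' through `shared`, `d1_only`, `d2_only`, restricted to labels actually
#' present) and one effect direction, and draws a fraction `purity` of its
#' members from genes carrying that label and sign; the remainder, and all
#' background sets, are sampled uniformly from the universe.
#'
#' @param fds A simulated [FirthDataSet-class] (truth attached).
#' @param nSets Total number of sets.
#' @param sizeRange Integer range of set sizes.
#' @param nEnriched Number of planted enriched sets (`<= nSets`).
#' @param seed Integer seed.
#' @param purity Fraction of an enriched set drawn from its target
#'   label/sign pool (default 0.9; 1 = drawn only from the pool).
#' @return A list with `collection` (named list of gene-id vectors, GMT-ready)
#'   and `truth` (data.frame: set, enriched flag, target label, direction).
#' @examples
#' fds <- simulateCohort(simParams(nGenes = 300, seed = 2))
#' gs <- simulateGeneSets(fds, nSets = 10, nEnriched = 3, seed = 2)
#' gs$truth[gs$truth$enriched, ]
#' @export
simulateGeneSets <- function(fds, nSets, sizeRange = c(15L, 60L),
                             nEnriched = 0L, seed = 1L, purity = 0.9) {
    truth <- simTruth(fds)
    universe <- rownames(fds)
    if (max(sizeRange) > length(universe))
        stop("set size range exceeds the gene universe")
    if (nEnriched > nSets) stop("nEnriched must be <= nSets")
    if (purity < 0 || purity > 1) stop("purity must lie in [0,1]")
    labels <- intersect(c("shared", "d1_only", "d2_only"),
                        unique(truth$label))
    if (nEnriched > 0 && !length(labels))
        stop("cannot plant enriched sets: no genes carry a DE label")
    collection <- vector("list", nSets)
    names(collection) <- sprintf("SET%03d", seq_len(nSets))
    setTruth <- data.frame(set = names(collection), enriched = FALSE,
                           label = NA_character_, direction = NA_integer_)
    withSeed(subSeed(seed, "genesets"), {
        sizes <- sample(seq(sizeRange[1], sizeRange[2]), nSets,
                        replace = TRUE)
        for (i in seq_len(nSets)) {
            if (i <= nEnriched) {
                lab <- labels[(i - 1L) %% length(labels) + 1L]
                dir <- sample(c(-1L, 1L), 1L)
                effCol <- if (lab == "d2_only") "lfc_d2" else "lfc_d1"
                pool <- universe[truth$label == lab &
                                 sign(truth[[effCol]]) == dir]
                if (!length(pool)) {     # no gene with that sign: flip
                    dir <- -dir
                    pool <- universe[truth$label == lab &
                                     sign(truth[[effCol]]) == dir]
                }
                if (!length(pool))
                    stop("cannot plant an enriched set for label '", lab,
                         "': no genes carry it")
                # the pool share is `purity` of the target size; if the
                # pool is smaller, the set shrinks rather than dilutes
                nPool <- min(length(pool), round(purity * sizes[i]))
                nBg <- round((1 - purity) * sizes[i])
                members <- sample(pool, nPool)
                rest <- sample(setdiff(universe, members), nBg)
                collection[[i]] <- sample(c(members, rest))
                setTruth$enriched[i] <- TRUE
                setTruth$label[i] <- lab
                setTruth$direction[i] <- dir
            } else {
                collection[[i]] <- sample(universe, sizes[i])
            }
        }
    })
    list(collection = collection, truth = setTruth)
}

#' Write simulated cohort tables to disk
#'
#' Emits the plain-text interchange files of the pipeline: counts TSV (first
#' column `gene_id`, then one column per sample), sample metadata TSV,
#' gene annotation TSV and truth TSV.
#'
#' @param fds A [FirthDataSet-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
writeCohort <- function(fds, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(fds))
    rd <- as.data.frame(SummarizedExperiment::rowData(fds))
    paths <- c(counts = file.path(dir, "counts.tsv"),
               samples = file.path(dir, "samples.tsv"),
               annotation = file.path(dir, "annotation.tsv"))
    writeTsv(data.frame(gene_id = rownames(fds), counts(fds),
                        check.names = FALSE), paths["counts"])
    writeTsv(cbind(sample_id = colnames(fds),
                   cd[setdiff(colnames(cd), "sizeFactor")]),
             paths["samples"])
    annotCols <- intersect(c("symbol", "biotype"), colnames(rd))
    writeTsv(cbind(gene_id = rownames(fds), rd[annotCols]),
             paths["annotation"])
    if (all(c("label", "lfc_d1", "lfc_d2") %in% colnames(rd))) {
        paths["truth"] <- file.path(dir, "truth.tsv")
        writeTsv(cbind(gene_id = rownames(fds),
                       rd[c("label", "lfc_d1", "lfc_d2")]),
                 paths["truth"])
    }
    invisible(paths)
}

#' Read a cohort from interchange TSV files
#'
#' Inverse of [writeCohort()]: assembles a [FirthDataSet-class] from a counts
#' TSV, a sample metadata TSV and a gene annotation TSV.
#'
#' @param countsPath,samplesPath,annotationPath File paths.
#' @return A [FirthDataSet-class].
#' @export
readCohort <- function(countsPath, samplesPath, annotationPath = NULL) {
    cts <- readTsv(countsPath)
    m <- as.matrix(cts[, -1, drop = FALSE])
    rownames(m) <- cts[[1]]
    samples <- readTsv(samplesPath)
    rownames(samples) <- samples$sample_id
    samples <- samples[colnames(m), setdiff(colnames(samples), "sample_id"),
                       drop = FALSE]
    rowData <- NULL
    if (!is.null(annotationPath)) {
        ann <- readTsv(annotationPath)
        rownames(ann) <- ann$gene_id
        if (!all(rownames(m) %in% rownames(ann)))
            stop("annotation does not cover all genes in the count matrix")
        rowData <- ann[rownames(m),
                       setdiff(colnames(ann), "gene_id"), drop = FALSE]
    }
    FirthDataSet(m, colData = samples, rowData = rowData)
}
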