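#' @include compare.R
NULL

#' Assemble a pipeline configuration
#'
#' Flat configuration consumed by [runPipeline()]. Two modes: `"simulate"`
#' builds a synthetic cohort (and gene-set collection) from `sim` /
#' `sets_*` settings; `"ingest"` starts from user-supplied counts, sample
#' metadata, annotation TSVs and a GMT file.
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param counts,samples,annotation,gmt File paths (ingest mode; `gmt` also
#'   honoured in simulate mode to override the simulated collection).
#' @param sim A [SimParams-class] (simulate mode); its seed is overridden
#'   by `seed`.
#' @param setsN,setsEnriched,setsSizeRange,setsPurity Simulated gene-set
#'   collection settings (simulate mode).
#' @param covariates Character vector of model covariates.
#' @param deAlpha,gseaQ,rraThreshold Significance thresholds for the DE
#'   call, GSEA q and RRA score.
#' @param nPerm GSEA permutation count.
#' @param trim,zMax Outlier winsorization switch and threshold.
#' @param biotypeFilter Apply the poly-A biotype whitelist (default TRUE).
#' @param seed Integer master seed fanned out to every stage.
#' @return A list of class `"pipeline_config"`.
#' @export
pipelineConfig <- function(mode = c("simulate", "ingest"),
                           counts = NULL, samples = NULL,
                           annotation = NULL, gmt = NULL,
                           sim = simParams(),
                           setsN = 30L, setsEnriched = 6L,
                           setsSizeRange = c(15L, 60L), setsPurity = 0.9,
                           covariates = character(),
                           deAlpha = 0.01, gseaQ = 0.05,
                           rraThreshold = 0.01, nPerm = 1000L,
                           trim = TRUE, zMax = 3, biotypeFilter = TRUE,
                           seed = 1L) {
    mode <- match.arg(mode)
    for (thr in list(deAlpha, gseaQ, rraThreshold))
        if (thr <= 0 || thr >= 1) stop("thresholds must lie in (0, 1)")
    cfg <- list(mode = mode, counts = counts, samples = samples,
                annotation = annotation, gmt = gmt, sim = sim,
                setsN = as.integer(setsN),
                setsEnriched = as.integer(setsEnriched),
                setsSizeRange = as.integer(setsSizeRange),
                setsPurity = setsPurity,
                covariates = covariates, deAlpha = deAlpha,
                gseaQ = gseaQ, rraThreshold = rraThreshold,
                nPerm = as.integer(nPerm), trim = trim, zMax = zMax,
                biotypeFilter = biotypeFilter, seed = as.integer(seed))
    class(cfg) <- "pipeline_config"
    cfg
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys mirror [pipelineConfig()] arguments in snake_case (`mode`,
#' `counts`, `samples`, `annotation`, `gmt`, `covariates`, `de_alpha`,
#' `gsea_q`, `rra_threshold`, `n_perm`, `trim`, `z_max`, `biotype_filter`,
#' `seed`, `sets_n`, `sets_enriched`, `sets_size_min`, `sets_size_max`,
#' `sets_purity`, and `sim_*` for the [simParams()] fields, e.g.
#' `sim_n_genes`, `sim_frac_shared_de`).
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"` list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    g <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
    simArgs <- list(
        nDisease1 = g("sim_n_disease1", 29L),
        nDisease2 = g("sim_n_disease2", 29L),
        nControl = g("sim_n_control", 49L),
        nGenes = g("sim_n_genes", 2000L),
        fracSharedDE = g("sim_frac_shared_de", 0.10),
        fracD1OnlyDE = g("sim_frac_d1_only_de", 0.05),
        fracD2OnlyDE = g("sim_frac_d2_only_de", 0.05),
        lfcMagnitude = g("sim_lfc_magnitude", 1),
        dispersion = g("sim_dispersion", 0.1),
        sizeFactorRange = c(g("sim_size_factor_min", 0.5),
                            g("sim_size_factor_max", 2)),
        baselineMeanRange = c(g("sim_baseline_mean_min", 10),
                              g("sim_baseline_mean_max", 1000)),
        nBatches = g("sim_n_batches", 1L),
        batchLfc = g("sim_batch_lfc", 0),
        seed = g("seed", 1L))
    covs <- g("covariates", character())
    if (length(covs) == 1 && nzchar(covs))
        covs <- trimws(strsplit(covs, ",")[[1]])
    pipelineConfig(
        mode = g("mode", "simulate"),
        counts = y$counts, samples = y$samples,
        annotation = y$annotation, gmt = y$gmt,
        sim = do.call(simParams, simArgs),
        setsN = g("sets_n", 30L), setsEnriched = g("sets_enriched", 6L),
        setsSizeRange = c(g("sets_size_min", 15L), g("sets_size_max", 60L)),
        setsPurity = g("sets_purity", 0.9),
        covariates = covs,
        deAlpha = g("de_alpha", 0.01), gseaQ = g("gsea_q", 0.05),
        rraThreshold = g("rra_threshold", 0.01),
        nPerm = g("n_perm", 1000L), trim = g("trim", TRUE),
        zMax = g("z_max", 3), biotypeFilter = g("biotype_filter", TRUE),
        seed = g("seed", 1L))
}

.contrastNames <- c("HD_vs_C", "PD_vs_C", "ND_vs_C")

.stageSimulate <- function(config, outdir) {
    dataDir <- file.path(outdir, "data")
    if (config$mode == "simulate") {
        sim <- config$sim
        sim@seed <- subSeed(config$seed, "cohort")
        fds <- simulateCohort(sim)
        writeCohort(fds, dataDir)
        gs <- simulateGeneSets(fds, nSets = config$setsN,
                               sizeRange = config$setsSizeRange,
                               nEnriched = config$setsEnriched,
                               seed = subSeed(config$seed, "sets"),
                               purity = config$setsPurity)
        writeGmt(gs$collection, file.path(dataDir, "genesets.gmt"))
        writeTsv(gs$truth, file.path(dataDir, "geneset_truth.tsv"))
    } else {
        for (key in c("counts", "samples", "annotation", "gmt")) {
            p <- config[[key]]
            if (is.null(p) || !file.exists(p))
                stop("ingest mode: missing input file for '", key, "'",
                     if (!is.null(p)) paste0(": ", p))
        }
        fds <- readCohort(config$counts, config$samples, config$annotation)
        writeCohort(fds, dataDir)
        file.copy(config$gmt, file.path(dataDir, "genesets.gmt"),
                  overwrite = TRUE)
    }
    invisible(dataDir)
}

.stagePreprocess <- function(config, outdir) {
    dataDir <- file.path(outdir, "data")
    fds <- readCohort(file.path(dataDir, "counts.tsv"),
                      file.path(dataDir, "samples.tsv"),
                      file.path(dataDir, "annotation.tsv"))
    fds <- preprocessCounts(
        fds,
        allowed = if (config$biotypeFilter) polyABiotypes() else NULL,
        trim = config$trim, zMax = config$zMax)
    writeTsv(data.frame(sample_id = colnames(fds),
                        size_factor = unname(sizeFactors(fds))),
             file.path(outdir, "size_factors.tsv"))
    writeTsv(data.frame(gene_id = rownames(fds), normCounts(fds),
                        check.names = FALSE),
             file.path(outdir, "normalized.tsv"))
    invisible(outdir)
}

# rebuild an analysis-ready FirthDataSet from the preprocessed stage files
.loadNormalized <- function(config, outdir) {
    dataDir <- file.path(outdir, "data")
    nrm <- readTsv(file.path(outdir, "normalized.tsv"))
    m <- as.matrix(nrm[, -1, drop = FALSE])
    rownames(m) <- nrm[[1]]
    samples <- readTsv(file.path(dataDir, "samples.tsv"))
    rownames(samples) <- samples$sample_id
    samples <- samples[colnames(m), , drop = FALSE]
    ann <- readTsv(file.path(dataDir, "annotation.tsv"))
    rownames(ann) <- ann$gene_id
    fds <- FirthDataSet(m, colData = samples[, -1, drop = FALSE],
                        rowData = ann[rownames(m), -1, drop = FALSE])
    normCounts(fds) <- m
    fds
}

.stageDE <- function(config, outdir) {
    fds <- .loadNormalized(config, outdir)
    for (ct in standardContrasts()) {
        res <- firthDE(fds, ct, covariates = config$covariates,
                       alpha = config$deAlpha)
        writeTsv(as.data.frame(res),
                 file.path(outdir, paste0("de_", ct$name, ".tsv")))
    }
    invisible(outdir)
}

.readDeTable <- function(outdir, name)
    readTsv(file.path(outdir, paste0("de_", name, ".tsv")))

.stageGSEA <- function(config, outdir) {
    collection <- readGmt(file.path(outdir, "data", "genesets.gmt"))
    for (nm in .contrastNames) {
        de <- .readDeTable(outdir, nm)
        ranked <- rankGenes(de)
        res <- gseaPreranked(ranked, collection, nPerm = config$nPerm,
                             seed = subSeed(config$seed,
                                            paste0("gsea_", nm)),
                             qThreshold = config$gseaQ)
        writeTsv(res, file.path(outdir, paste0("gsea_", nm, ".tsv")))
    }
    invisible(outdir)
}

.stageRRA <- function(config, outdir) {
    lists <- lapply(.contrastNames, function(nm)
        rraRankList(.readDeTable(outdir, nm)))
    names(lists) <- sub("_vs_C", "", .contrastNames)
    res <- aggregateRanks(lists, threshold = config$rraThreshold)
    writeTsv(res, file.path(outdir, "rra.tsv"))
    invisible(outdir)
}

.stageCompare <- function(config, outdir) {
    deTabs <- lapply(.contrastNames, .readDeTable, outdir = outdir)
    names(deTabs) <- .contrastNames
    hd <- deTabs$HD_vs_C$gene_id[deTabs$HD_vs_C$de]
    pd <- deTabs$PD_vs_C$gene_id[deTabs$PD_vs_C$de]
    parts <- partitionDE(hd, pd)
    writeTsv(data.frame(
        gene_id = unlist(parts, use.names = FALSE),
        partition = rep(names(parts), lengths(parts))),
        file.path(outdir, "partition_membership.tsv"))
    universe <- deTabs$HD_vs_C$gene_id
    collection <- readGmt(file.path(outdir, "data", "genesets.gmt"))
    enr <- enrichPartitions(parts, universe, list(sets = collection))
    writeTsv(enr, file.path(outdir, "partition_enrichment.tsv"))
    sigEnr <- enr[!is.na(enr$q) & enr$q < config$gseaQ & enr$overlap > 0, ]
    if (nrow(sigEnr)) {
        members <- strsplit(sigEnr$members, ",", fixed = TRUE)
        names(members) <- paste(sigEnr$partition, sigEnr$set, sep = ":")
        grp <- groupGeneSets(members)
    } else {
        grp <- data.frame(set = character(), group = integer())
    }
    writeTsv(grp, file.path(outdir, "set_groups.tsv"))
    gseaList <- lapply(.contrastNames, function(nm)
        readTsv(file.path(outdir, paste0("gsea_", nm, ".tsv"))))
    names(gseaList) <- .contrastNames
    conc <- directionConcordance(gseaList, qThreshold = config$gseaQ)
    writeTsv(conc$table, file.path(outdir, "concordance.tsv"))
    writeTsv(data.frame(quantity = names(conc$counts),
                        count = unname(conc$counts)),
             file.path(outdir, "concordance_counts.tsv"))
    invisible(outdir)
}

#' Run the analysis pipeline
#'
#' Orchestrates simulate/ingest, preprocessing, the three Firth DE
#' contrasts, preranked GSEA, robust rank aggregation and the
#' disease-comparison stage. Every stage reads and writes plain TSV/GMT
#' files under `outdir`, so stages can be re-run individually and chaining
#' them equals a single `"all"` run bit for bit given the same seed.
#'
#' @param config A `"pipeline_config"` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run, in pipeline order, a
#'   subset of `c("simulate", "preprocess", "de", "gsea", "rra",
#'   "compare")`, or `"all"`.
#' @return Invisibly, `outdir`. Side effects: the result tables
#'   (`data/*.tsv`, `data/genesets.gmt`, `normalized.tsv`,
#'   `size_factors.tsv`, `de_*.tsv`, `gsea_*.tsv`, `rra.tsv`,
#'   `partition_*.tsv`, `set_groups.tsv`, `concordance*.tsv`) and a
#'   `manifest.json` recording seed, thresholds and package version.
#' @export
runPipeline <- function(config, outdir, stages = "all") {
    stopifnot(inherits(config, "pipeline_config"))
    allStages <- c("simulate", "preprocess", "de", "gsea", "rra", "compare")
    if (identical(stages, "all")) stages <- allStages
    unknown <- setdiff(stages, allStages)
    if (length(unknown))
        stop("unknown stage(s): ", paste(unknown, collapse = ", "))
    stages <- allStages[allStages %in% stages]
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    runners <- list(simulate = .stageSimulate,
                    preprocess = .stagePreprocess, de = .stageDE,
                    gsea = .stageGSEA, rra = .stageRRA,
                    compare = .stageCompare)
    for (st in stages) {
        message("[firthseq] stage: ", st)
        tryCatch(runners[[st]](config, outdir),
                 error = function(e)
                     stop("pipeline stage '", st, "' failed: ",
                          conditionMessage(e), call. = FALSE))
    }
    manifest <- list(
        package = "firthseq",
        version = as.character(utils::packageVersion("firthseq")),
        mode = config$mode, seed = config$seed, stages = stages,
        thresholds = list(de_alpha = config$deAlpha, gsea_q = config$gseaQ,
                          rra = config$rraThreshold),
        n_perm = config$nPerm, covariates = config$covariates)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(outdir)
}
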