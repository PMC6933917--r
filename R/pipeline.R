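# End-to-end orchestration: preprocess -> differential expression ->
# network -> strain association -> enrichment -> cross-species comparison,
# from a single config (R list or YAML file), with a run manifest and
# TSV outputs per stage.

#' Pipeline configuration
#'
#' @param tpm,counts,meta,orthologs,humanModules,humanLFC input file paths
#'   (TSV/GMT); may be `NULL` when the corresponding objects are passed to
#'   [runPipeline()] directly.
#' @param enrichGMT optional gene-set GMT path for module enrichment.
#' @param minTPM,maxFracBelow low-expression filter parameters.
#' @param power soft power (integer) or `"auto"`.
#' @param minModuleSize minimum module size.
#' @param mergeHeight eigengene dissimilarity threshold for module merging.
#' @param alpha significance threshold used by every stage.
#' @param nPerm permutations for the overlap null.
#' @param control control strain label.
#' @param seed global seed; every stochastic stage derives its own
#'   substream from it.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(tpm = NULL, counts = NULL, meta = NULL,
                           orthologs = NULL, humanModules = NULL,
                           humanLFC = NULL, enrichGMT = NULL,
                           minTPM = 10, maxFracBelow = 0.9, power = 8,
                           minModuleSize = 30L, mergeHeight = 0.25,
                           alpha = 0.05, nPerm = 10000L, control = "B6",
                           seed = 1L) {
    stopifnot(minTPM >= 0, maxFracBelow >= 0, maxFracBelow <= 1,
              identical(power, "auto") || (is.numeric(power) && power >= 1),
              minModuleSize >= 1, mergeHeight >= 0, mergeHeight <= 1,
              alpha > 0, alpha < 1, nPerm >= 1)
    cfg <- list(tpm = tpm, counts = counts, meta = meta,
                orthologs = orthologs, humanModules = humanModules,
                humanLFC = humanLFC, enrichGMT = enrichGMT, minTPM = minTPM,
                maxFracBelow = maxFracBelow, power = power,
                minModuleSize = as.integer(minModuleSize),
                mergeHeight = mergeHeight, alpha = alpha,
                nPerm = as.integer(nPerm), control = control,
                seed = .checkSeed(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys are the arguments of [pipelineConfig()].
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing (filter, log transform, batch correction, PCA),
#' per-strain differential expression, co-expression module detection,
#' eigengene strain association, optional module enrichment, and the
#' cross-species comparison (module overlap with permutation null;
#' perturbation-effect concordance). Any stage failure aborts with the
#' stage name. All stage outputs, a resolved-config echo and a run manifest
#' are written to `outDir`.
#'
#' @param config a `PipelineConfig` or path to a YAML config.
#' @param outDir output directory.
#' @param inputs optional named list of in-memory inputs overriding the
#'   config paths: `tpm`, `counts` ([ExpressionExperiment-class]), `meta`
#'   (data frame), `orthologs` (data frame), `humanModules`
#'   ([GeneSetCatalog-class]), `humanLFC` (data frame), `enrichGMT`
#'   ([GeneSetCatalog-class]).
#' @return Invisibly, a list with `corrected`, `pca`, `de`, `modules`,
#'   `drivers`, `enrichment`, `overlap`, `concordance`, `config`.
#' @export
runPipeline <- function(config, outDir, inputs = list()) {
    if (is.character(config)) config <- readPipelineConfig(config)
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    stage <- function(name, expr) {
        .log("stage %s", name)
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    meta <- stage("inputs", inputs$meta %||%
        readSampleMetadata(config$meta, control = config$control))
    tpm <- stage("inputs", inputs$tpm %||%
        readExpression(config$tpm, scale = "tpm", meta = meta,
                       control = config$control))
    counts <- stage("inputs", inputs$counts %||%
        readExpression(config$counts, scale = "counts", meta = meta,
                       control = config$control))
    orthologs <- stage("inputs", inputs$orthologs %||%
        readOrthologMap(config$orthologs))
    humanModules <- stage("inputs", inputs$humanModules %||%
        readGMT(config$humanModules))
    humanLFC <- stage("inputs", inputs$humanLFC %||%
        readLFCTable(config$humanLFC))
    enrichCatalog <- inputs$enrichGMT %||%
        (if (!is.null(config$enrichGMT)) readGMT(config$enrichGMT) else NULL)

    corrected <- stage("preprocess", preprocess(tpm, minTPM = config$minTPM,
        maxFracBelow = config$maxFracBelow))
    pca <- stage("pca", runPCA(corrected))
    counts <- stage("diffexpr", counts[rownames(corrected), ])
    de <- stage("diffexpr", diffExprAllStrains(counts, alpha = config$alpha))
    modules <- stage("network", detectModules(corrected,
        power = config$power, minSize = config$minModuleSize,
        mergeHeight = config$mergeHeight))
    drivers <- stage("associate", associateStrains(modules, corrected,
        alpha = config$alpha, control = config$control))
    enrichment <- if (!is.null(enrichCatalog))
        stage("enrich", {
            uni <- rownames(corrected)
            do.call(rbind, lapply(moduleNames(modules), function(mod) {
                e <- ora(moduleGenes(modules, mod)[[1L]], enrichCatalog, uni,
                         alpha = config$alpha)
                cbind(module = mod, e)
            }))
        }) else NULL
    overlap <- stage("compare", overlapAnalysis(modules, humanModules,
        orthologs, nPerm = config$nPerm,
        seed = .stageSeed(config$seed, "overlap"), alpha = config$alpha))
    fit <- stage("compare", fitPerturbationModel(corrected))
    concordance <- stage("compare", concordanceAnalysis(fit, humanLFC,
        humanModules, orthologs, alpha = config$alpha))

    stage("report", {
        .writeTSV(data.frame(sample = rownames(pca$scores),
                             pca$scores[, seq_len(min(5L, ncol(pca$scores)))],
                             check.names = FALSE),
                  file.path(outDir, "pca_scores.tsv"))
        .writeTSV(data.frame(component = seq_along(pca$varExplained),
                             varExplained = pca$varExplained),
                  file.path(outDir, "pca_variance.tsv"))
        for (s in names(de))
            .writeTSV(de[[s]], file.path(outDir, paste0("de_", s, ".tsv")))
        .writeTSV(data.frame(gene = names(moduleLabels(modules)),
                             module = moduleLabels(modules)),
                  file.path(outDir, "module_assignment.tsv"))
        .writeTSV(data.frame(module = rownames(eigengenes(modules)),
                             eigengenes(modules), check.names = FALSE),
                  file.path(outDir, "module_eigengenes.tsv"))
        if (nrow(modules@fitTable))
            .writeTSV(modules@fitTable, file.path(outDir, "soft_threshold.tsv"))
        .writeTSV(drivers, file.path(outDir, "module_drivers.tsv"))
        if (!is.null(enrichment))
            .writeTSV(enrichment, file.path(outDir, "module_enrichment.tsv"))
        .writeTSV(overlap, file.path(outDir, "overlap_jaccard.tsv"))
        .writeTSV(concordance, file.path(outDir, "concordance.tsv"))
        cfgEcho <- config
        class(cfgEcho) <- NULL
        cfgEcho <- cfgEcho[!vapply(cfgEcho, is.null, logical(1))]
        yaml::write_yaml(cfgEcho, file.path(outDir, "config_resolved.yaml"))
        manifest <- c(
            paste0("crossmod version: ",
                   as.character(utils::packageVersion("crossmod"))),
            paste0("R version: ", R.version.string),
            paste0("seed: ", config$seed),
            paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
            paste0("genes analyzed: ", nrow(corrected)),
            paste0("samples: ", ncol(corrected)),
            paste0("modules: ", length(moduleNames(modules))))
        writeLines(manifest, file.path(outDir, "manifest.txt"))
    })
    invisible(list(corrected = corrected, pca = pca, de = de,
                   modules = modules, drivers = drivers,
                   enrichment = enrichment, overlap = overlap,
                   concordance = concordance, config = config))
}

#' One-command demonstration run on synthetic data
#'
#' Simulates a study with the default design, writes the generated inputs,
#' and runs the full pipeline on them. The permutation count defaults to
#' 1000 for a quick run; every other threshold keeps its reference default.
#'
#' @param dir output directory (inputs under `dir/inputs`, results under
#'   `dir/results`).
#' @param seed global seed.
#' @param nPerm permutations for the overlap null.
#' @param config optional `SimConfig` overriding the default design.
#' @return Invisibly, a list with `sim` (the generated study) and `result`
#'   (the [runPipeline()] output).
#' @export
runDemo <- function(dir, seed = 1L, nPerm = 1000L, config = simConfig()) {
    sim <- simulateStudy(config, seed = seed)
    inputDir <- file.path(dir, "inputs")
    writeSimulation(sim, inputDir)
    cfg <- pipelineConfig(nPerm = nPerm, seed = seed,
                          control = config$control)
    result <- runPipeline(cfg, file.path(dir, "results"), inputs = list(
        tpm = sim$tpm, counts = sim$counts, meta = sim$design,
        orthologs = sim$human$orthologs, humanModules = sim$human$catalog,
        humanLFC = sim$human$lfc))
    invisible(list(sim = sim, result = result))
}
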