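# Synthetic-data generator emulating the study design: six mutant strains
# plus B6 controls across three experimental batches, planted co-expression
# modules with strain-specific eigengene shifts, negative-binomial counts,
# an ortholog map, a human module catalog with planted overlaps, and human
# log2FC values with planted directional concordance. Everything is
# deterministic under a fixed seed (one R RNG stream per generator call),
# and the planted truth is returned for downstream recovery checks.

#' Simulation configuration
#'
#' Defaults mirror the emulated study: strains `APOE4`, `Apoe`, `Clu`,
#' `Bin1`, `Cd2ap` (6 replicates each) plus `APP_PS1` (5) and `B6` controls
#' (13), laid out over three batches (all late-onset models with 6 controls;
#' 1 `APP_PS1` with 7 controls; 4 `APP_PS1`), for 48 samples; five planted
#' modules of 50 genes with within-module correlation 0.7; each module
#' driven by one mutant strain with an eigengene shift of 1 log2 unit.
#'
#' @param layout data frame with columns `strain`, `batch`, `n` describing
#'   the per-batch replicate counts; default is the emulated study layout.
#' @param control control strain label.
#' @param nGenes total number of mouse genes.
#' @param nModules number of planted modules.
#' @param moduleSize genes per planted module (recycled to `nModules`).
#' @param withinCor target within-module correlation on the log scale.
#' @param noiseSD per-gene Gaussian noise SD (log2 units).
#' @param batchSD SD of per-gene batch offsets (log2 units; first batch is
#'   the reference with zero offset).
#' @param baselineRange range of per-gene baseline log2 expression.
#' @param loadingRange range of module loading magnitudes; `c(1, 1)` (with
#'   `negLoadingFrac = 0`) gives the exact noise-free constructions used in
#'   the documentation examples.
#' @param negLoadingFrac fraction of module genes with negative loadings
#'   (anti-correlated members; gives planted per-gene effects a real spread
#'   within each module, as in expression data).
#' @param delta eigengene shift (log2 units) planted for each module's
#'   driver strain; a single value or one per module.
#' @param driverStrains driver strain per module; defaults to the first
#'   `nModules` mutant strains in layout order.
#' @param dispersion negative-binomial dispersion for counts (0 = Poisson).
#' @param libSizeRange library-size range for count generation.
#' @param orthologFrac fraction of mouse genes with a human ortholog.
#' @param oneToManyFrac fraction of mapped genes that get a second human
#'   partner (forces the mapping policy to matter).
#' @param contamination fraction of each human module replaced/augmented by
#'   random human genes (controls the planted Jaccard).
#' @param rTarget target Pearson correlation between human log2FC and the
#'   driver strain's planted effects for each matched human module; a single
#'   value or one per module. Must lie in \[-1, 1\].
#' @param lfcNoiseSD SD of human log2FC noise for unmatched genes.
#' @param regions region labels for the human LFC table.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(layout = NULL, control = "B6", nGenes = 1500L,
                      nModules = 5L, moduleSize = 50L, withinCor = 0.7,
                      noiseSD = 0.3, batchSD = 0.5,
                      baselineRange = c(4, 10), loadingRange = c(0.5, 1.5),
                      negLoadingFrac = 0.5,
                      delta = 1.0, driverStrains = NULL, dispersion = 0.05,
                      libSizeRange = c(2e6, 4e6), orthologFrac = 0.9,
                      oneToManyFrac = 0.05, contamination = 0.2,
                      rTarget = 0.5, lfcNoiseSD = 0.5, regions = "brain") {
    if (is.null(layout))
        layout <- data.frame(
            strain = c("APOE4", "Apoe", "Clu", "Bin1", "Cd2ap", "B6",
                       "APP_PS1", "B6", "APP_PS1"),
            batch = c(rep("batch1", 6L), "batch2", "batch2", "batch3"),
            n = c(6L, 6L, 6L, 6L, 6L, 6L, 1L, 7L, 4L),
            stringsAsFactors = FALSE)
    stopifnot(all(c("strain", "batch", "n") %in% colnames(layout)),
              all(layout$n >= 0L))
    reps <- tapply(layout$n, layout$strain, sum)
    if (!control %in% names(reps) || reps[[control]] < 1L)
        stop("control strain has zero replicates in the layout")
    if (any(reps[names(reps) != control] < 2L) || reps[[control]] < 2L)
        stop("every strain needs >= 2 replicates")
    moduleSize <- rep_len(as.integer(moduleSize), nModules)
    if (any(moduleSize < 1L)) stop("module sizes must be >= 1")
    if (sum(moduleSize) > nGenes) stop("module sizes exceed the gene count")
    if (any(rTarget < -1 | rTarget > 1)) stop("rTarget must lie in [-1, 1]")
    mutants <- setdiff(unique(layout$strain), control)
    if (is.null(driverStrains))
        driverStrains <- rep_len(mutants, nModules)
    cfg <- list(layout = layout, control = control, nGenes = as.integer(nGenes),
                nModules = as.integer(nModules), moduleSize = moduleSize,
                withinCor = withinCor, noiseSD = noiseSD, batchSD = batchSD,
                baselineRange = baselineRange, loadingRange = loadingRange,
                negLoadingFrac = negLoadingFrac,
                delta = rep_len(delta, nModules),
                driverStrains = driverStrains, dispersion = dispersion,
                libSizeRange = libSizeRange, orthologFrac = orthologFrac,
                oneToManyFrac = oneToManyFrac, contamination = contamination,
                rTarget = rep_len(rTarget, nModules), lfcNoiseSD = lfcNoiseSD,
                regions = regions)
    class(cfg) <- "SimConfig"
    cfg
}

#' Generate the sample design
#'
#' Expands the configured layout into one metadata row per sample,
#' deterministically under the seed (sample identifiers and ordering are a
#' pure function of the layout).
#'
#' @param config a `SimConfig` from [simConfig()].
#' @param seed integer seed.
#' @return Data frame with columns `sample`, `strain`, `batch`.
#' @export
simDesign <- function(config = simConfig(), seed = 1L) {
    set.seed(.stageSeed(.checkSeed(seed), "design"))
    rows <- config$layout[rep(seq_len(nrow(config$layout)), config$layout$n), ]
    meta <- data.frame(strain = rows$strain, batch = rows$batch,
                       stringsAsFactors = FALSE)
    idx <- stats::ave(seq_len(nrow(meta)), meta$strain, FUN = seq_along)
    meta$sample <- sprintf("%s_%02d", meta$strain, idx)
    rownames(meta) <- NULL
    .validateMetadata(meta[, c("sample", "strain", "batch")],
                      control = config$control)
}

#' Generate mouse expression data with planted structure
#'
#' Latent log2 expression per gene and sample is
#' `baseline + loading * (module signal + strain shift) + batch offset +
#' N(0, noiseSD)`; module signals are standard-normal per sample, the shift
#' `delta` is added to the module signal for the module's driver strain.
#' TPM is `2^latent - 1`, clipped at zero, with columns rescaled to a
#' constant column sum of 1e6; counts are negative-binomial with mean
#' proportional to TPM times a per-sample library size.
#'
#' @param design metadata from [simDesign()].
#' @param config a `SimConfig`.
#' @param seed integer seed.
#' @return A list with `tpm` and `counts` ([ExpressionExperiment-class]) and
#'   `truth`: module `membership` (named by gene, `"grey"` = background),
#'   `loadings`, `signal` (realized per-sample module signals, shift
#'   included), `delta` (modules x strains), `beta` (genes x mutant strains,
#'   planted log2 effects), `batchOffsets`, `driverStrains`, `config`,
#'   `seed`.
#' @export
simMouseExpression <- function(design, config = simConfig(), seed = 1L) {
    seed <- .checkSeed(seed)
    set.seed(.stageSeed(seed, "expression"))
    nG <- config$nGenes
    nS <- nrow(design)
    genes <- sprintf("Gene%04d", seq_len(nG))
    strains <- design$strain
    batches <- factor(design$batch)
    mutants <- setdiff(unique(strains), config$control)
    modNames <- sprintf("M%02d", seq_len(config$nModules))
    membership <- rep("grey", nG)
    pos <- 0L
    for (i in seq_len(config$nModules)) {
        membership[pos + seq_len(config$moduleSize[i])] <- modNames[i]
        pos <- pos + config$moduleSize[i]
    }
    names(membership) <- genes
    # per-module per-sample signal with the driver-strain shift
    deltaMat <- matrix(0, config$nModules, length(mutants),
                       dimnames = list(modNames, mutants))
    for (i in seq_len(config$nModules))
        deltaMat[i, config$driverStrains[i]] <-
            deltaMat[i, config$driverStrains[i]] + config$delta[i]
    signal <- matrix(stats::rnorm(config$nModules * nS), config$nModules, nS,
                     dimnames = list(modNames, design$sample))
    for (s in mutants)
        signal[, strains == s] <- signal[, strains == s] + deltaMat[, s]
    baseline <- stats::runif(nG, config$baselineRange[1L],
                             config$baselineRange[2L])
    # loading scaled so that within-module correlation hits withinCor given
    # noiseSD; per-gene magnitude jitter from loadingRange
    lScale <- if (config$withinCor >= 1 || config$noiseSD == 0) 1 else
        config$noiseSD * sqrt(config$withinCor / (1 - config$withinCor))
    signs <- ifelse(stats::runif(nG) < config$negLoadingFrac, -1, 1)
    loadings <- signs * stats::runif(nG, config$loadingRange[1L],
                                     config$loadingRange[2L]) * lScale
    loadings[membership == "grey"] <- 0
    batchOffsets <- matrix(0, nG, nlevels(batches),
                           dimnames = list(genes, levels(batches)))
    if (nlevels(batches) > 1L)
        batchOffsets[, -1L] <- stats::rnorm(nG * (nlevels(batches) - 1L),
                                            sd = config$batchSD)
    inMod <- membership != "grey"
    sigGene <- matrix(0, nG, nS)
    sigGene[inMod, ] <- signal[membership[inMod], , drop = FALSE]
    latent <- matrix(baseline, nG, nS) + loadings * sigGene +
        batchOffsets[, as.integer(batches), drop = FALSE] +
        matrix(stats::rnorm(nG * nS, sd = config$noiseSD), nG, nS)
    dimnames(latent) <- list(genes, design$sample)
    tpm <- pmax(2^latent - 1, 0)
    tpm <- sweep(tpm, 2L, colSums(tpm), `/`) * 1e6
    lib <- stats::runif(nS, config$libSizeRange[1L], config$libSizeRange[2L])
    mu <- sweep(tpm, 2L, lib / 1e6, `*`)
    counts <- matrix(
        if (config$dispersion > 0)
            stats::rnbinom(nG * nS, mu = mu, size = 1 / config$dispersion)
        else stats::rpois(nG * nS, lambda = mu),
        nG, nS, dimnames = dimnames(tpm))
    beta <- matrix(0, nG, length(mutants), dimnames = list(genes, mutants))
    for (s in mutants)
        beta[inMod, s] <- loadings[inMod] * deltaMat[membership[inMod], s]
    truth <- list(membership = membership, loadings = loadings,
                  signal = signal, delta = deltaMat, beta = beta,
                  batchOffsets = batchOffsets,
                  driverStrains = stats::setNames(config$driverStrains,
                                                  modNames),
                  config = config, seed = seed)
    list(tpm = ExpressionExperiment(tpm, meta = design, scale = "tpm",
                                    control = config$control),
         counts = ExpressionExperiment(counts, meta = design,
                                       scale = "counts",
                                       control = config$control),
         truth = truth)
}

#' Generate the human reference with planted overlap and concordance
#'
#' Builds (i) an ortholog map covering `orthologFrac` of the mouse genes
#' one-to-one plus a fraction `oneToManyFrac` of one-to-many rows, (ii) a
#' human module catalog in which human module `HMi` consists of the
#' orthologs of mouse module i plus a `contamination` fraction of random
#' human genes, and (iii) a human log2FC table in which genes of module
#' `HMi` equal the driver strain's planted effect plus noise scaled so the
#' correlation is approximately `rTarget[i]`; all other genes carry
#' independent noise.
#'
#' @param truth the `truth` element of [simMouseExpression()].
#' @param config a `SimConfig` (defaults to the one recorded in `truth`).
#' @param seed integer seed.
#' @return A list with `catalog` ([GeneSetCatalog-class], grouped A-E),
#'   `lfc` (data frame `gene` + one column per region), `orthologs` (data
#'   frame), `humanModuleOf` (mouse module -> human module), `rTarget`
#'   (named per human module).
#' @export
simHumanReference <- function(truth, config = truth$config, seed = 1L) {
    set.seed(.stageSeed(.checkSeed(seed), "human"))
    genes <- names(truth$membership)
    nG <- length(genes)
    mapped <- sort(sample(genes, round(config$orthologFrac * nG)))
    human1 <- paste0("H_", toupper(mapped))
    orth <- data.frame(mouse = mapped, human = human1,
                       stringsAsFactors = FALSE)
    nMulti <- round(config$oneToManyFrac * length(mapped))
    if (nMulti > 0L) {
        extraIdx <- sample(length(mapped), nMulti)
        orth <- rbind(orth, data.frame(mouse = mapped[extraIdx],
                                       human = paste0(human1[extraIdx], "B"),
                                       stringsAsFactors = FALSE))
    }
    humanPool <- c(unique(orth$human),
                   sprintf("HX%04d", seq_len(round(0.2 * nG))))
    modNames <- rownames(truth$delta)
    sets <- list()
    rT <- stats::setNames(rep(0, length(modNames)),
                          paste0("HM", seq_along(modNames)))
    humanModuleOf <- stats::setNames(paste0("HM", seq_along(modNames)),
                                     modNames)
    for (i in seq_along(modNames)) {
        mGenes <- names(truth$membership)[truth$membership == modNames[i]]
        core <- unique(orth$human[orth$mouse %in% mGenes])
        nContam <- round(config$contamination * length(core))
        contam <- sample(setdiff(humanPool, core), nContam)
        sets[[humanModuleOf[[modNames[i]]]]] <- c(core, contam)
        rT[humanModuleOf[[modNames[i]]]] <- config$rTarget[i]
    }
    groups <- stats::setNames(LETTERS[(seq_along(sets) - 1L) %% 5L + 1L],
                              names(sets))
    catalog <- GeneSetCatalog(sets, groups = groups)
    # one-to-one mouse partner per human gene (first map row wins) for the
    # planted log2FC signal
    firstMouse <- orth$mouse[match(humanPool, orth$human)]
    lfcVals <- matrix(stats::rnorm(length(humanPool) * length(config$regions),
                                   sd = config$lfcNoiseSD),
                      length(humanPool), length(config$regions),
                      dimnames = list(humanPool, config$regions))
    for (i in seq_along(modNames)) {
        hmod <- humanModuleOf[[modNames[i]]]
        r <- rT[[hmod]]
        if (r == 0) next
        hGenes <- intersect(sets[[hmod]], humanPool)
        mg <- firstMouse[match(hGenes, humanPool)]
        ok <- !is.na(mg)
        hGenes <- hGenes[ok]; mg <- mg[ok]
        b <- truth$beta[mg, truth$driverStrains[[modNames[i]]]]
        sdB <- stats::sd(b)
        if (sdB == 0) next
        noiseSD <- sdB * sqrt(1 / r^2 - 1)
        for (rg in config$regions)
            lfcVals[hGenes, rg] <- sign(r) * b +
                stats::rnorm(length(b), sd = noiseSD)
    }
    lfc <- data.frame(gene = humanPool, lfcVals, check.names = FALSE,
                      stringsAsFactors = FALSE, row.names = NULL)
    colnames(lfc) <- c("gene", config$regions)
    list(catalog = catalog, lfc = lfc, orthologs = orth,
         humanModuleOf = humanModuleOf, rTarget = rT)
}

#' Run the whole generator
#'
#' @param config a `SimConfig`.
#' @param seed integer seed driving all three stages (each stage uses its
#'   own deterministic substream).
#' @return A list with `design`, `tpm`, `counts`, `truth`, `human` (the
#'   [simHumanReference()] output).
#' @export
simulateStudy <- function(config = simConfig(), seed = 1L) {
    design <- simDesign(config, seed = seed)
    expr <- simMouseExpression(design, config, seed = seed)
    human <- simHumanReference(expr$truth, config, seed = seed)
    list(design = design, tpm = expr$tpm, counts = expr$counts,
         truth = expr$truth, human = human)
}

#' Write all generated inputs to a directory
#'
#' Emits `tpm.tsv`, `counts.tsv`, `meta.tsv`, `orthologs.tsv`,
#' `human_modules.gmt`, `human_lfc.tsv` and the planted truth
#' (`truth_membership.tsv`, `truth_beta.tsv`).
#'
#' @param sim output of [simulateStudy()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeExpression(sim$tpm, file.path(dir, "tpm.tsv"))
    writeExpression(sim$counts, file.path(dir, "counts.tsv"))
    writeSampleMetadata(sim$design, file.path(dir, "meta.tsv"))
    writeOrthologMap(sim$human$orthologs, file.path(dir, "orthologs.tsv"))
    writeGMT(sim$human$catalog, file.path(dir, "human_modules.gmt"))
    writeLFCTable(sim$human$lfc, file.path(dir, "human_lfc.tsv"))
    .writeTSV(data.frame(gene = names(sim$truth$membership),
                         module = sim$truth$membership),
              file.path(dir, "truth_membership.tsv"))
    .writeTSV(data.frame(gene = rownames(sim$truth$beta), sim$truth$beta,
                         check.names = FALSE),
              file.path(dir, "truth_beta.tsv"))
    invisible(dir)
}

#' Simulate a module eigengene matrix with planted strain shifts
#'
#' Eigengene-level generator for calibrating the strain-association stage:
#' each module eigengene is a mean shift (`delta` for its driver strain's
#' samples, 0 elsewhere) plus Gaussian residual noise, so `delta` is
#' expressed relative to the residual scale.
#'
#' @param meta metadata data frame (`sample`, `strain`, `batch`).
#' @param nModules number of module eigengenes.
#' @param delta shift for each module's driver strain (recycled).
#' @param driverStrains driver strain per module (recycled; default cycles
#'   through the non-control strains).
#' @param sigma residual SD.
#' @param control control strain label.
#' @param seed integer seed.
#' @return A list with `eigengenes` (modules x samples matrix) and
#'   `driverStrains` (named by module).
#' @export
simEigengenes <- function(meta, nModules = 5L, delta = 1, driverStrains = NULL,
                          sigma = 0.3, control = "B6", seed = 1L) {
    set.seed(.checkSeed(seed))
    strains <- as.character(meta$strain)
    mutants <- setdiff(unique(strains), control)
    if (is.null(driverStrains)) driverStrains <- mutants
    driverStrains <- rep_len(driverStrains, nModules)
    delta <- rep_len(delta, nModules)
    modNames <- sprintf("ME%02d", seq_len(nModules))
    em <- matrix(stats::rnorm(nModules * nrow(meta), sd = sigma),
                 nModules, nrow(meta),
                 dimnames = list(modNames, meta$sample))
    for (i in seq_len(nModules))
        em[i, strains == driverStrains[i]] <-
            em[i, strains == driverStrains[i]] + delta[i]
    list(eigengenes = em,
         driverStrains = stats::setNames(driverStrains, modNames))
}

#' Simulate log-scale expression with planted per-gene strain effects
#'
#' Direct generator for calibrating the perturbation regression: per gene, a
#' baseline plus a planted per-gene effect for each non-control strain plus
#' independent Gaussian noise.
#'
#' @param meta metadata data frame (`sample`, `strain`, `batch`).
#' @param beta genes x strains matrix of planted log2 effects (column names
#'   are the non-control strains).
#' @param sigma residual SD (log2 units).
#' @param baseline per-gene baseline (recycled).
#' @param control control strain label.
#' @param seed integer seed.
#' @return An [ExpressionExperiment-class] on the `log2tpm` scale.
#' @export
simPerturbedLogExpression <- function(meta, beta, sigma = 0.3, baseline = 6,
                                      control = "B6", seed = 1L) {
    set.seed(.checkSeed(seed))
    nG <- nrow(beta)
    genes <- rownames(beta) %||% sprintf("Gene%05d", seq_len(nG))
    strains <- as.character(meta$strain)
    m <- matrix(rep_len(baseline, nG), nG, nrow(meta)) +
        matrix(stats::rnorm(nG * nrow(meta), sd = sigma), nG, nrow(meta))
    for (s in colnames(beta))
        m[, strains == s] <- m[, strains == s] + beta[, s]
    dimnames(m) <- list(genes, meta$sample)
    ExpressionExperiment(m, meta = meta, scale = "log2tpm", control = control)
}

#' Simulate a count matrix with per-gene fold changes
#'
#' Lightweight negative-binomial count generator used for differential-
#' expression calibration: per gene a base mean, a per-sample size factor,
#' and an optional log2 fold change applied to one strain.
#'
#' @param meta metadata data frame (`sample`, `strain`, `batch`).
#' @param nGenes number of genes.
#' @param mu base mean count (scalar or per gene).
#' @param dispersion NB dispersion (0 = Poisson).
#' @param lfc per-gene log2 fold change applied to `strain` samples
#'   (scalar or per gene; default 0).
#' @param strain strain receiving the fold change; default the first
#'   non-control strain.
#' @param control control strain label.
#' @param libFactor per-sample library scaling factors (default all 1).
#' @param seed integer seed.
#' @return An [ExpressionExperiment-class] on the `counts` scale.
#' @export
simCountMatrix <- function(meta, nGenes = 1000L, mu = 100, dispersion = 0.05,
                           lfc = 0, strain = NULL, control = "B6",
                           libFactor = NULL, seed = 1L) {
    set.seed(.checkSeed(seed))
    genes <- sprintf("Gene%05d", seq_len(nGenes))
    mu <- rep_len(mu, nGenes)
    lfc <- rep_len(lfc, nGenes)
    strains <- as.character(meta$strain)
    if (is.null(strain)) strain <- setdiff(unique(strains), control)[1L]
    libFactor <- libFactor %||% rep(1, nrow(meta))
    muMat <- outer(mu, libFactor)
    muMat[, strains == strain] <- muMat[, strains == strain] * 2^lfc
    cnt <- matrix(
        if (dispersion > 0)
            stats::rnbinom(length(muMat), mu = muMat, size = 1 / dispersion)
        else stats::rpois(length(muMat), lambda = muMat),
        nGenes, nrow(meta), dimnames = list(genes, meta$sample))
    ExpressionExperiment(cnt, meta = meta, scale = "counts", control = control)
}
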