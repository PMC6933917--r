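# The cross-species core: ortholog mapping policies, Jaccard overlap of
# mouse modules with human modules under the map, a permutation null for the
# overlap, the per-gene multi-strain perturbation regression, and the
# directional concordance of perturbation effects with human log2FC.

#' Map mouse genes to human orthologs
#'
#' `all_pairs` retains every mapped (mouse, human) pair and is used for set
#' overlap; `one_to_one` keeps only genes with a unique partner in both
#' directions (computed over the whole map) and is used for correlation, to
#' avoid duplicated observations. Unmapped genes are counted and logged.
#'
#' @param genes character vector of mouse genes.
#' @param map ortholog map data frame with columns `mouse`, `human`.
#' @param policy `"all_pairs"` or `"one_to_one"`.
#' @return Data frame with columns `mouse`, `human`, one row per retained
#'   pair.
#' @export
mapOrthologs <- function(genes, map, policy = c("all_pairs", "one_to_one")) {
    policy <- match.arg(policy)
    genes <- unique(as.character(genes))
    sub <- map[map$mouse %in% genes, c("mouse", "human"), drop = FALSE]
    if (policy == "one_to_one") {
        mTab <- table(map$mouse)
        hTab <- table(map$human)
        ok <- mTab[sub$mouse] == 1L & hTab[sub$human] == 1L
        sub <- sub[ok, , drop = FALSE]
    }
    nUnmapped <- length(genes) - length(unique(sub$mouse))
    if (nUnmapped)
        .log("mapOrthologs(%s): %d of %d genes unmapped", policy, nUnmapped,
             length(genes))
    if (!nrow(sub)) stop("no genes could be mapped to orthologs")
    rownames(sub) <- NULL
    sub
}

#' Jaccard index of two gene sets
#'
#' `|a n b| / |a u b|`; 0 when the union is empty (convention for two empty
#' sets).
#'
#' @param a,b character vectors (treated as sets).
#' @return The Jaccard index in \[0, 1\].
#' @export
jaccardIndex <- function(a, b) {
    a <- unique(a); b <- unique(b)
    u <- length(a) + length(b) - sum(a %in% b)
    if (u == 0L) return(0)
    sum(a %in% b) / u
}

#' Permutation test for mouse-human module overlap
#'
#' The observed Jaccard index is computed between the human-mapped mouse
#' module (all-pairs policy) and the human module. The null draws
#' `|mouse module|` genes without replacement from the mouse universe (the
#' union of all mouse module genes), maps and scores each draw identically,
#' and the empirical cumulative p-value uses the add-one estimator
#' `(1 + #\{J_null >= J_obs\}) / (nPerm + 1)`, which is never zero.
#'
#' @param mouseModule character vector of mouse genes, a subset of
#'   `mouseUniverse`.
#' @param humanModule character vector of human genes.
#' @param mouseUniverse character vector: the union of all mouse module
#'   genes.
#' @param map ortholog map data frame (`mouse`, `human`).
#' @param nPerm number of null draws.
#' @param seed RNG seed for the draws.
#' @return A list with `jaccard`, `intersectSize`, `p`, `nPerm`.
#' @export
permutationOverlapTest <- function(mouseModule, humanModule, mouseUniverse,
                                   map, nPerm = 10000L, seed = 1L) {
    mouseModule <- unique(as.character(mouseModule))
    mouseUniverse <- unique(as.character(mouseUniverse))
    if (!all(mouseModule %in% mouseUniverse))
        stop("mouse module must be a subset of the mouse universe")
    if (length(mouseModule) > length(mouseUniverse))
        stop("module larger than universe")
    humanModule <- unique(as.character(humanModule))
    # integer-indexed mapping for fast repeated scoring
    humanAll <- unique(c(map$human, humanModule))
    mapIdx <- split(match(map$human, humanAll), map$mouse)
    hSet <- logical(length(humanAll))
    hSet[match(humanModule, humanAll)] <- TRUE
    nH <- sum(hSet)
    scoreJ <- function(mouseGenes) {
        h <- unique(unlist(mapIdx[mouseGenes], use.names = FALSE))
        if (is.null(h) || !length(h)) return(0)
        inter <- sum(hSet[h])
        inter / (length(h) + nH - inter)
    }
    jObs <- scoreJ(mouseModule)
    set.seed(.checkSeed(seed))
    nGE <- 0L
    sz <- length(mouseModule)
    for (i in seq_len(nPerm)) {
        jNull <- scoreJ(sample(mouseUniverse, sz))
        if (jNull >= jObs) nGE <- nGE + 1L
    }
    mapped <- unique(unlist(mapIdx[mouseModule], use.names = FALSE))
    list(jaccard = jObs,
         intersectSize = if (length(mapped)) sum(hSet[mapped]) else 0L,
         p = (1 + nGE) / (nPerm + 1), nPerm = nPerm)
}

#' Overlap of every mouse module with every human module
#'
#' Runs [permutationOverlapTest()] for all (mouse module, human module)
#' pairs, with BH adjustment across pairs. The mouse universe is the union
#' of all non-grey module genes.
#'
#' @param modules a [ModuleSet-class] or named list of mouse gene sets.
#' @param catalog human module [GeneSetCatalog-class].
#' @param map ortholog map data frame.
#' @param nPerm permutations per pair.
#' @param seed RNG seed; each pair uses a deterministic sub-seed.
#' @param alpha significance threshold recorded in the output.
#' @return Data frame: `mouseModule`, `humanModule`, `humanGroup`, `jaccard`,
#'   `intersectSize`, `p`, `padj`, `significant`.
#' @export
overlapAnalysis <- function(modules, catalog, map, nPerm = 10000L, seed = 1L,
                            alpha = 0.05) {
    sets <- if (is(modules, "ModuleSet")) moduleGenes(modules) else modules
    if (!length(sets)) stop("no mouse modules to test")
    universe <- unique(unlist(sets, use.names = FALSE))
    grp <- setGroups(catalog)
    rows <- list()
    pairSeed <- .checkSeed(seed)
    for (mm in names(sets)) {
        for (hm in names(catalog)) {
            pairSeed <- (pairSeed + 7919L) %% .Machine$integer.max
            r <- permutationOverlapTest(sets[[mm]], geneSets(catalog)[[hm]],
                                        universe, map, nPerm = nPerm,
                                        seed = pairSeed)
            rows[[length(rows) + 1L]] <- data.frame(
                mouseModule = mm, humanModule = hm,
                humanGroup = if (hm %in% names(grp)) grp[[hm]] else NA_character_,
                jaccard = r$jaccard, intersectSize = r$intersectSize,
                p = r$p, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$padj <- adjustBH(out$p)
    out$significant <- out$padj < alpha
    .log("overlap analysis: %d of %d pairs significant at BH < %g",
         sum(out$significant), nrow(out), alpha)
    out
}

#' Per-gene perturbation-effect regression
#'
#' Fits, per gene, ordinary least squares of log expression on an intercept
#' plus one indicator per non-control strain (control is the reference
#' level): with the one-hot design each coefficient is the strain mean minus
#' the control mean. Batch indicators can be added by flag; the reference
#' model omits them, matching the plain multi-strain regression.
#'
#' @param x an [ExpressionExperiment-class] on the `log2tpm` scale; all
#'   strains need >= 2 samples.
#' @param withBatch add batch indicator columns to the design.
#' @return A list of class `PerturbationFit`: `beta` (genes x strains matrix
#'   of log2-scale effects vs control), `intercept`, `sigma` (residual SD per
#'   gene), `n`, `strains`, `control`.
#' @export
fitPerturbationModel <- function(x, withBatch = FALSE) {
    if (scaleTag(x) != "log2tpm")
        stop("fitPerturbationModel expects the log2tpm scale")
    m <- exprValues(x)
    control <- controlLevel(x)
    strain <- factor(as.character(sampleStrains(x)))
    if (!control %in% levels(strain)) stop("control strain not present")
    strain <- stats::relevel(strain, ref = control)
    if (any(table(strain) < 2L))
        stop("every strain needs >= 2 samples: ",
             paste(names(which(table(strain) < 2L)), collapse = ", "))
    design <- stats::model.matrix(~strain)
    if (withBatch) {
        bt <- droplevels(factor(sampleBatches(x)))
        if (nlevels(bt) > 1L)
            design <- cbind(design, stats::model.matrix(~bt)[, -1L, drop = FALSE])
    }
    qrd <- qr(design)
    if (qrd$rank < ncol(design))
        stop("rank-deficient design; collinear columns: ",
             paste(colnames(design)[qrd$pivot[-seq_len(qrd$rank)]],
                   collapse = ", "))
    coefs <- qr.coef(qrd, t(m))
    resid <- t(m) - design %*% coefs
    df <- nrow(design) - ncol(design)
    sigma <- sqrt(colSums(resid^2) / df)
    strains <- setdiff(levels(strain), control)
    beta <- t(coefs[paste0("strain", strains), , drop = FALSE])
    colnames(beta) <- strains
    structure(list(beta = beta, intercept = coefs["(Intercept)", ],
                   sigma = sigma, n = nrow(design), strains = strains,
                   control = control),
              class = "PerturbationFit")
}

#' @export
print.PerturbationFit <- function(x, ...) {
    cat("PerturbationFit:", nrow(x$beta), "genes,",
        length(x$strains), "strains vs", x$control,
        "(", x$n, "samples )\n")
    invisible(x)
}

#' Concordance of one strain's perturbation effects with one human module
#'
#' Over the genes of a human module that carry both a one-to-one mouse
#' ortholog with a fitted perturbation effect and a human log2FC value, the
#' Pearson correlation (with its test) between log2FC and the strain's beta.
#' Fewer than 3 usable genes, or zero variance in either variable, yields an
#' untestable result rather than an error.
#'
#' @param fit a `PerturbationFit` from [fitPerturbationModel()].
#' @param lfc named numeric vector of human log2FC(AD/control) values.
#' @param humanModule character vector of human genes.
#' @param map ortholog map data frame.
#' @param strain strain whose effects to correlate.
#' @param policy ortholog policy; the default `one_to_one` avoids
#'   pseudo-replication from one-to-many pairs.
#' @return A one-row data frame: `strain`, `r`, `statistic`, `p`, `n`,
#'   `status` (`"ok"` or `"untestable"`).
#' @export
moduleConcordance <- function(fit, lfc, humanModule, map, strain,
                              policy = "one_to_one") {
    if (!strain %in% fit$strains) stop("no fitted effects for strain ", strain)
    pairs <- tryCatch(mapOrthologs(rownames(fit$beta), map, policy = policy),
                      error = function(e) NULL)
    empty <- data.frame(strain = strain, r = NA_real_, statistic = NA_real_,
                        p = NA_real_, n = 0L, status = "untestable",
                        stringsAsFactors = FALSE)
    if (is.null(pairs)) return(empty)
    pairs <- pairs[pairs$human %in% humanModule & pairs$human %in% names(lfc), ,
                   drop = FALSE]
    if (nrow(pairs) < 3L) return(transform(empty, n = nrow(pairs)))
    b <- fit$beta[pairs$mouse, strain]
    f <- lfc[pairs$human]
    if (stats::sd(b) == 0 || stats::sd(f) == 0)
        return(transform(empty, n = nrow(pairs)))
    ct <- pearsonCorTest(f, b)
    data.frame(strain = strain, r = ct$estimate, statistic = ct$statistic,
               p = ct$p, n = ct$n, status = "ok", stringsAsFactors = FALSE)
}

#' Concordance of every strain with every human module and region
#'
#' Runs [moduleConcordance()] for each (strain, human module, region)
#' combination, BH-adjusting across all testable results. Results with
#' adjusted p above `alpha` are marked non-significant.
#'
#' @param fit a `PerturbationFit`.
#' @param lfcTable data frame from [readLFCTable()] (`gene` plus one numeric
#'   column per region).
#' @param catalog human module [GeneSetCatalog-class].
#' @param map ortholog map data frame.
#' @param alpha significance threshold.
#' @param policy ortholog policy passed to [moduleConcordance()].
#' @return Data frame: `strain`, `humanModule`, `humanGroup`, `region`, `r`,
#'   `statistic`, `p`, `n`, `status`, `padj`, `significant`.
#' @export
concordanceAnalysis <- function(fit, lfcTable, catalog, map, alpha = 0.05,
                                policy = "one_to_one") {
    regions <- setdiff(colnames(lfcTable), "gene")
    grp <- setGroups(catalog)
    rows <- list()
    for (rg in regions) {
        lfc <- stats::setNames(lfcTable[[rg]], lfcTable$gene)
        for (hm in names(catalog)) {
            for (s in fit$strains) {
                r <- moduleConcordance(fit, lfc, geneSets(catalog)[[hm]],
                                       map, s, policy = policy)
                r$humanModule <- hm
                r$humanGroup <- if (hm %in% names(grp)) grp[[hm]] else
                    NA_character_
                r$region <- rg
                rows[[length(rows) + 1L]] <- r
            }
        }
    }
    out <- do.call(rbind, rows)
    out$padj <- NA_real_
    testable <- out$status == "ok"
    out$padj[testable] <- adjustBH(out$p[testable])
    out$significant <- !is.na(out$padj) & out$padj < alpha
    .log("concordance analysis: %d of %d tests significant at BH < %g",
         sum(out$significant), sum(testable), alpha)
    out[, c("strain", "humanModule", "humanGroup", "region", "r", "statistic",
            "p", "n", "status", "padj", "significant")]
}
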