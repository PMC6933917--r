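# Per-strain differential expression versus control on raw counts: median-of-
# ratios normalization, method-of-moments negative-binomial dispersion, and a
# Wald test on the strain coefficient of a log-linear model with optional
# batch covariates. This is a deliberately simplified relative of the usual
# shrinkage-based NB pipelines: no dispersion shrinkage across genes, no
# fold-change shrinkage, no independent filtering.

#' Median-of-ratios size factors
#'
#' Per sample, the median over all-positive genes of the ratio of the count
#' to that gene's geometric mean across samples; factors are rescaled to
#' geometric mean 1.
#'
#' @param counts an [ExpressionExperiment-class] on the `counts` scale or a
#'   counts matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimateSizeFactors <- function(counts) {
    m <- if (is(counts, "ExpressionExperiment")) exprValues(counts) else
        as.matrix(counts)
    logGeo <- rowMeans(log(m))
    ref <- is.finite(logGeo)
    if (!any(ref))
        stop("no gene has all-positive counts; filter low-count genes first")
    sf <- apply(m, 2L, function(cnt)
        exp(stats::median(log(cnt[ref]) - logGeo[ref])))
    sf / exp(mean(log(sf)))
}

# Method-of-moments NB dispersion per gene, pooled over design cells with
# >= 2 samples. Var(K/s) ~ q * mean(1/s) + alpha * q^2 within a cell.
.momDispersion <- function(m, sf, cell) {
    z <- sweep(m, 2L, sf, `/`)
    invSf <- 1 / sf
    cells <- split(seq_len(ncol(m)), cell)
    cells <- cells[lengths(cells) >= 2L]
    est <- vapply(seq_len(nrow(m)), function(g) {
        num <- 0; den <- 0
        for (j in cells) {
            mu <- mean(z[g, j])
            if (mu <= 0) next
            v <- stats::var(z[g, j])
            w <- length(j) - 1L
            num <- num + w * (v - mu * mean(invSf[j])) / mu^2
            den <- den + w
        }
        if (den == 0) NA_real_ else num / den
    }, numeric(1))
    pmax(est, 1e-8)
}

#' Negative-binomial Wald test for one strain versus control
#'
#' Fits, per gene, a negative-binomial log-linear model with intercept,
#' strain indicator, batch indicators (when more than one batch is present
#' among the selected samples) and log size factors as offset; dispersion is
#' estimated by method of moments on normalized counts (floored at 1e-8) and
#' held fixed during the fit. The Wald statistic on the strain coefficient
#' is referenced to a t distribution with the residual degrees of freedom (a
#' small-sample correction for the plug-in dispersion); BH adjustment is
#' applied across testable genes. Genes
#' with all-zero counts in the selected samples are reported as untestable.
#' Non-converging gene fits fall back to a Poisson fit and are flagged.
#'
#' @param counts an [ExpressionExperiment-class] on the `counts` scale with
#'   strain/batch annotation.
#' @param strain strain level to test against the control level.
#' @param withBatch include batch indicators (default on).
#' @param allStrains fit the joint model on all samples rather than the
#'   default pairwise subset (tested strain plus all controls).
#' @param dispersions optional named per-gene dispersion overrides.
#' @return Data frame with one row per gene: `gene`, `baseMean`, `log2FC`,
#'   `se`, `stat`, `p`, `padj`, `status` (`"ok"`, `"poisson-fallback"`,
#'   `"untestable"`).
#' @export
nbWaldTest <- function(counts, strain, withBatch = TRUE, allStrains = FALSE,
                       dispersions = NULL) {
    if (scaleTag(counts) != "counts") stop("nbWaldTest expects the counts scale")
    control <- controlLevel(counts)
    st <- as.character(sampleStrains(counts))
    if (!strain %in% st) stop("strain '", strain, "' not present")
    if (!control %in% st) stop("control strain '", control, "' not present")
    keep <- if (allStrains) rep(TRUE, length(st)) else st %in% c(strain, control)
    m <- exprValues(counts)[, keep, drop = FALSE]
    st <- factor(st[keep], levels = c(control, setdiff(unique(st[keep]), control)))
    bt <- droplevels(factor(sampleBatches(counts)[keep]))
    sf <- estimateSizeFactors(m)
    useBatch <- withBatch && nlevels(bt) > 1L
    design <- if (useBatch) stats::model.matrix(~ st + bt) else
        stats::model.matrix(~st)
    coefName <- paste0("st", strain)
    cell <- interaction(st, bt, drop = TRUE)
    disp <- if (is.null(dispersions)) .momDispersion(m, sf, cell) else
        pmax(dispersions[rownames(m)], 1e-8)
    disp[is.na(disp)] <- 0.1
    off <- log(sf)
    res <- matrix(NA_real_, nrow(m), 4L,
                  dimnames = list(rownames(m), c("log2FC", "se", "stat", "p")))
    status <- rep("ok", nrow(m))
    for (g in seq_len(nrow(m))) {
        y <- m[g, ]
        if (all(y == 0)) {
            status[g] <- "untestable"
            next
        }
        fam <- MASS::negative.binomial(theta = 1 / disp[g])
        fit <- tryCatch(
            suppressWarnings(stats::glm.fit(design, y, family = fam,
                                            offset = off)),
            error = function(e) NULL)
        if (is.null(fit) || !fit$converged) {
            fit <- suppressWarnings(stats::glm.fit(design, y,
                family = stats::poisson(), offset = off))
            status[g] <- "poisson-fallback"
        }
        cf <- fit$coefficients
        # Wald covariance at dispersion 1 (the NB variance is in the weights)
        xw <- sqrt(fit$weights) * design
        covm <- tryCatch(chol2inv(chol(crossprod(xw))), error = function(e) NULL)
        if (is.null(covm)) {
            status[g] <- "untestable"
            next
        }
        i <- match(coefName, colnames(design))
        beta <- cf[i]
        se <- sqrt(covm[i, i])
        res[g, ] <- c(beta / log(2), se / log(2), beta / se,
                      2 * stats::pt(abs(beta / se), df = ncol(m) - ncol(design),
                                    lower.tail = FALSE))
    }
    testable <- status != "untestable"
    padj <- rep(NA_real_, nrow(m))
    padj[testable] <- adjustBH(res[testable, "p"])
    .log("nbWaldTest %s vs %s: %d genes (%d untestable, %d Poisson fallback)",
         strain, control, nrow(m), sum(status == "untestable"),
         sum(status == "poisson-fallback"))
    data.frame(gene = rownames(m),
               baseMean = rowMeans(sweep(m, 2L, sf, `/`)),
               log2FC = res[, "log2FC"], se = res[, "se"],
               stat = res[, "stat"], p = res[, "p"], padj = padj,
               status = status, row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential expression for every non-control strain
#'
#' @inheritParams nbWaldTest
#' @param alpha adjusted-p significance threshold used for the summary log.
#' @return Named list of per-strain data frames from [nbWaldTest()].
#' @export
diffExprAllStrains <- function(counts, withBatch = TRUE, alpha = 0.05) {
    strains <- setdiff(unique(as.character(sampleStrains(counts))),
                       controlLevel(counts))
    out <- lapply(strains, function(s) {
        de <- nbWaldTest(counts, s, withBatch = withBatch)
        nUp <- sum(de$padj < alpha & de$log2FC > 0, na.rm = TRUE)
        nDn <- sum(de$padj < alpha & de$log2FC < 0, na.rm = TRUE)
        .log("strain %s: %d up / %d down at adjusted p < %g", s, nUp, nDn, alpha)
        de
    })
    names(out) <- strains
    out
}
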