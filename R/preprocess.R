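# Path from quantified expression to analysis-ready matrix: low-expression
# filter, log2(TPM + 1), empirical-Bayes batch correction, and PCA.

#' Remove genes with low expression across most samples
#'
#' A gene is removed iff the fraction of samples with TPM below `minTPM` is
#' strictly greater than `maxFracBelow` (default: TPM < 10 in more than 90%
#' of samples). Boundary genes at exactly the threshold fraction are kept.
#'
#' @param x an [ExpressionExperiment-class] on the `tpm` scale.
#' @param minTPM expression threshold in TPM units.
#' @param maxFracBelow maximum tolerated fraction of samples below `minTPM`.
#' @return The filtered `ExpressionExperiment`; sample set unchanged.
#' @export
filterLowExpression <- function(x, minTPM = 10, maxFracBelow = 0.9) {
    if (scaleTag(x) != "tpm") stop("filterLowExpression expects the tpm scale")
    m <- exprValues(x)
    fracBelow <- rowMeans(m < minTPM)
    keep <- fracBelow <= maxFracBelow
    if (!any(keep)) stop("all genes removed by the low-expression filter")
    .log("low-expression filter removed %d of %d genes", sum(!keep), nrow(m))
    x[keep, ]
}

#' Log-transform TPM to log2(TPM + 1)
#'
#' @param x an [ExpressionExperiment-class] on the `tpm` scale.
#' @return The transformed object on the `log2tpm` scale.
#' @export
logTransform <- function(x) {
    if (scaleTag(x) != "tpm") stop("logTransform expects the tpm scale")
    m <- exprValues(x)
    if (any(m < 0)) stop("negative TPM values")
    .replaceValues(x, log2(m + 1), scale = "log2tpm")
}

#' Principal component analysis of samples
#'
#' PCA with genes as variables and samples as observations, gene-centered
#' (optionally unit-scaled). Component orientation is made deterministic by
#' flipping each component so its largest-magnitude gene loading is positive.
#'
#' @param x an [ExpressionExperiment-class] (any scale) or numeric matrix
#'   (genes x samples).
#' @param center center genes (default on).
#' @param scale. scale genes to unit variance (default off).
#' @return A list with `scores` (samples x components), `varExplained`
#'   (fraction of variance per component, non-increasing), `loadings`
#'   (genes x components).
#' @export
runPCA <- function(x, center = TRUE, scale. = FALSE) {
    m <- if (is(x, "ExpressionExperiment")) exprValues(x) else as.matrix(x)
    if (ncol(m) < 2L) stop("PCA needs at least 2 samples")
    if (all(apply(m, 1L, stats::sd) == 0)) stop("constant expression matrix")
    if (scale.) {
        keep <- apply(m, 1L, stats::sd) > 0
        m <- m[keep, , drop = FALSE]
    }
    pc <- stats::prcomp(t(m), center = center, scale. = scale.)
    flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
    flip[flip == 0] <- 1
    scores <- sweep(pc$x, 2L, flip, `*`)
    loadings <- sweep(pc$rotation, 2L, flip, `*`)
    v <- pc$sdev^2
    list(scores = scores, varExplained = v / sum(v), loadings = loadings)
}

#' Batch-effect correction with per-gene location/scale adjustment
#'
#' Removes known batch effects from a log-scale expression matrix by the
#' location-and-scale model: per gene, batch means and variances are
#' estimated on data standardized against a batch-weighted grand mean --
#' with strain indicators retained in the standardization design so
#' biological signal is not absorbed -- and then subtracted/divided out.
#' With `eb = TRUE` the per-gene batch parameters are shrunk across genes by
#' parametric empirical Bayes (normal prior on locations, inverse-gamma on
#' scales, method-of-moments hyperparameters, iterated to convergence).
#' A single batch returns the input unchanged.
#'
#' @param x an [ExpressionExperiment-class] on the `log2tpm` scale with
#'   strain and batch annotation.
#' @param eb use empirical-Bayes shrinkage of batch parameters (default on).
#' @param covariates include strain indicators in the standardization design
#'   (default on). Turn off to reproduce a covariate-free adjustment.
#' @return The corrected `ExpressionExperiment`.
#' @export
correctBatch <- function(x, eb = TRUE, covariates = TRUE) {
    if (scaleTag(x) != "log2tpm") stop("correctBatch expects the log2tpm scale")
    batch <- droplevels(factor(sampleBatches(x)))
    if (nlevels(batch) < 2L) {
        .log("single batch: no correction applied")
        return(x)
    }
    nb <- tabulate(batch)
    if (any(nb < 2L))
        stop("every batch needs >= 2 samples: ",
             paste(levels(batch)[nb < 2L], collapse = ", "))
    dat <- exprValues(x)
    strain <- droplevels(factor(sampleStrains(x)))
    batchmat <- stats::model.matrix(~ -1 + batch)
    design <- batchmat
    if (covariates && nlevels(strain) > 1L) {
        covmat <- stats::model.matrix(~strain)[, -1L, drop = FALSE]
        design <- cbind(batchmat, covmat)
        if (qr(design)$rank < ncol(design))
            stop("batch and strain are confounded; cannot include covariates")
    }
    nBatch <- nlevels(batch)
    N <- ncol(dat)
    # per-gene OLS fit of batch + covariate effects
    Bhat <- solve(crossprod(design), crossprod(design, t(dat)))
    grand <- crossprod(nb / N, Bhat[seq_len(nBatch), , drop = FALSE])
    varPooled <- rowSums((dat - t(design %*% Bhat))^2) / N
    if (any(varPooled == 0))
        stop("zero residual variance for ",
             sum(varPooled == 0), " genes; filter constant genes first")
    standMean <- matrix(grand, nrow(dat), N)
    if (ncol(design) > nBatch) {
        tmp <- design
        tmp[, seq_len(nBatch)] <- 0
        standMean <- standMean + t(tmp %*% Bhat)
    }
    sdat <- (dat - standMean) / sqrt(varPooled)
    gammaHat <- t(sapply(seq_len(nrow(dat)), function(i) {
        tapply(sdat[i, ], batch, mean)
    }))
    deltaHat <- t(sapply(seq_len(nrow(dat)), function(i) {
        tapply(sdat[i, ], batch, stats::var)
    }))
    if (eb) {
        gammaStar <- gammaHat
        deltaStar <- deltaHat
        for (b in seq_len(nBatch)) {
            sol <- .ebBatchSolve(sdat[, batch == levels(batch)[b], drop = FALSE],
                                 gammaHat[, b], deltaHat[, b])
            gammaStar[, b] <- sol$gamma
            deltaStar[, b] <- sol$delta
        }
    } else {
        gammaStar <- gammaHat
        deltaStar <- deltaHat
        if (any(deltaStar == 0))
            stop("zero within-batch variance without empirical Bayes shrinkage")
    }
    out <- sdat
    for (b in seq_len(nBatch)) {
        j <- batch == levels(batch)[b]
        out[, j] <- (sdat[, j] - gammaStar[, b]) / sqrt(deltaStar[, b])
    }
    out <- out * sqrt(varPooled) + standMean
    .log("batch correction across %d batches (eb=%s)", nBatch, eb)
    .replaceValues(x, out)
}

# Parametric empirical-Bayes solve for one batch: normal prior on the batch
# locations, inverse-gamma on the batch scales, method-of-moments
# hyperparameters, iterated conditional posterior means.
.ebBatchSolve <- function(sdatBatch, gammaHat, deltaHat, conv = 1e-6,
                          maxit = 500L) {
    n <- ncol(sdatBatch)
    gammaBar <- mean(gammaHat)
    tau2 <- stats::var(gammaHat)
    m <- mean(deltaHat)
    s2 <- stats::var(deltaHat)
    aprior <- (2 * s2 + m^2) / s2
    bprior <- (m * s2 + m^3) / s2
    gOld <- gammaHat
    dOld <- deltaHat
    change <- 1
    it <- 0L
    while (change > conv && it < maxit) {
        gNew <- (n * tau2 * gammaHat + dOld * gammaBar) / (n * tau2 + dOld)
        ss <- rowSums((sdatBatch - gNew)^2)
        dNew <- (0.5 * ss + bprior) / (n / 2 + aprior - 1)
        change <- max(abs(gNew - gOld) / abs(gOld + 1e-12),
                      abs(dNew - dOld) / abs(dOld + 1e-12))
        gOld <- gNew
        dOld <- dNew
        it <- it + 1L
    }
    list(gamma = gOld, delta = dOld)
}

#' Run the full preprocessing stage
#'
#' Convenience wrapper: low-expression filter on TPM, log2(TPM + 1), batch
#' correction.
#'
#' @inheritParams filterLowExpression
#' @inheritParams correctBatch
#' @return The corrected log-scale [ExpressionExperiment-class].
#' @export
preprocess <- function(x, minTPM = 10, maxFracBelow = 0.9, eb = TRUE,
                       covariates = TRUE) {
    correctBatch(logTransform(filterLowExpression(x, minTPM, maxFracBelow)),
                 eb = eb, covariates = covariates)
}
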