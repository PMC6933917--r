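# Weighted co-expression module discovery: soft-threshold selection by
# scale-free fit, unsigned adjacency, topological overlap, average-linkage
# clustering with a static branch cut, module eigengenes, and merging of
# modules with correlated eigengenes.

# Module label sequence (the conventional WGCNA color ordering), assigned by
# module size rank; "grey" is reserved for unassigned genes.
.MODULE_COLORS <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
    "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
    "lightsteelblue1", "lightcyan1", "ivory", "floralwhite", "darkorange2",
    "brown4", "bisque4", "darkslateblue", "plum2", "thistle2", "thistle1",
    "salmon4", "palevioletred3", "navajowhite2", "maroon", "lavenderblush3",
    "honeydew1", "darkseagreen4", "coral1", "antiquewhite4", "coral2",
    "mediumorchid", "skyblue2", "coral3", "skyblue1", "plum", "orangered3")

.moduleColorName <- function(i) {
    if (i <= length(.MODULE_COLORS)) .MODULE_COLORS[i] else paste0("module", i)
}

#' Co-expression network
#'
#' Gene x gene soft-thresholded adjacency: symmetric, values in \[0, 1\],
#' unit diagonal, with the soft power recorded.
#'
#' @name CoexpressionNetwork-class
#' @aliases CoexpressionNetwork
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
         representation(adjacency = "matrix", power = "numeric"))

setValidity("CoexpressionNetwork", function(object) {
    a <- object@adjacency
    msgs <- character()
    if (nrow(a) != ncol(a)) msgs <- c(msgs, "adjacency must be square")
    else {
        if (max(abs(a - t(a))) > 1e-12) msgs <- c(msgs, "adjacency must be symmetric")
        if (any(a < 0) || any(a > 1)) msgs <- c(msgs, "adjacency values must lie in [0, 1]")
        if (any(abs(diag(a) - 1) > 1e-12)) msgs <- c(msgs, "adjacency diagonal must be 1")
    }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn CoexpressionNetwork-class adjacency matrix.
#' @param x a `CoexpressionNetwork`.
#' @export
adjacency <- function(x) x@adjacency

#' @describeIn CoexpressionNetwork-class per-gene connectivity
#'   `k_i = sum_{j != i} a_ij`.
#' @export
connectivity <- function(x) rowSums(x@adjacency) - 1

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork:", nrow(object@adjacency), "genes, soft power",
        object@power, "\n")
    k <- connectivity(object)
    cat("  connectivity: mean", signif(mean(k), 4), " max", signif(max(k), 4), "\n")
})

#' Soft-threshold selection by scale-free topology fit
#'
#' For each candidate power, builds the unsigned adjacency, computes
#' connectivities, bins them into `nBins` equal-occupancy bins, and regresses
#' log10 frequency density on log10 mean connectivity. The fit index is the
#' signed R^2 (negated when the slope is positive). Returns the smallest
#' power reaching `r2Target`, or -- with a warning -- the power maximizing
#' the signed R^2 when none does.
#'
#' @param x an [ExpressionExperiment-class] on a log scale, or a numeric
#'   genes x samples matrix with >= 30 genes.
#' @param powers candidate soft powers.
#' @param r2Target signed-R^2 threshold for scale-free fit.
#' @param nBins number of equal-occupancy connectivity bins.
#' @return A list with `power` (the selection) and `fitTable` (one row per
#'   candidate power: `power`, `signedR2`, `slope`, `meanK`, `maxK`).
#' @export
pickSoftThreshold <- function(x, powers = 1:20, r2Target = 0.85, nBins = 10L) {
    m <- if (is(x, "ExpressionExperiment")) exprValues(x) else as.matrix(x)
    if (nrow(m) < 30L) stop("soft-threshold selection needs >= 30 genes")
    cc <- abs(.corGenes(m))
    fit <- do.call(rbind, lapply(powers, function(p) {
        a <- cc^p
        k <- rowSums(a) - 1
        sf <- .scaleFreeFit(k, nBins)
        data.frame(power = p, signedR2 = sf$signedR2, slope = sf$slope,
                   meanK = mean(k), maxK = max(k))
    }))
    ok <- which(fit$signedR2 >= r2Target)
    if (length(ok)) {
        power <- fit$power[ok[1L]]
    } else {
        power <- fit$power[which.max(fit$signedR2)]
        warning("no candidate power reaches signed R^2 >= ", r2Target,
                "; using the best fit (power ", power, ")")
    }
    list(power = power, fitTable = fit)
}

.corGenes <- function(m) {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0))
        stop("zero-variance genes must be filtered before network construction: ",
             paste(head(rownames(m)[sds == 0], 5L), collapse = ", "))
    stats::cor(t(m))
}

# Scale-free fit: equal-occupancy connectivity bins; within each bin the
# frequency density p(k) = (fraction of genes) / (bin width) is regressed on
# the mean connectivity, both on log10 scale.
.scaleFreeFit <- function(k, nBins = 10L) {
    if (stats::sd(k) == 0) stop("all connectivities identical")
    breaks <- unique(stats::quantile(k, probs = seq(0, 1, length.out = nBins + 1)))
    if (length(breaks) < 3L) stop("connectivity distribution too discrete to bin")
    bins <- cut(k, breaks, include.lowest = TRUE)
    dk <- tapply(k, bins, mean)
    frac <- tabulate(bins, nbins = nlevels(bins)) / length(k)
    width <- diff(breaks)
    dens <- frac / width
    keep <- !is.na(dk) & dens > 0 & dk > 0
    fit <- stats::lm(log10(dens[keep]) ~ log10(dk[keep]))
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[[2L]]
    list(signedR2 = if (slope > 0) -r2 else r2, slope = slope)
}

#' Unsigned soft-thresholded adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^power` (or `((1 + cor)/2)^power` for a signed
#' network), with unit diagonal. Zero-variance genes are an error.
#'
#' @param x an [ExpressionExperiment-class] on a log scale or a genes x
#'   samples matrix with >= 3 samples.
#' @param power soft-thresholding power.
#' @param signed build a signed network (off by default; the unsigned
#'   network is the reference analysis).
#' @return A [CoexpressionNetwork-class].
#' @export
computeAdjacency <- function(x, power = 8, signed = FALSE) {
    m <- if (is(x, "ExpressionExperiment")) exprValues(x) else as.matrix(x)
    if (ncol(m) < 3L) stop("adjacency needs >= 3 samples")
    cc <- .corGenes(m)
    a <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
    a[a > 1] <- 1
    diag(a) <- 1
    new("CoexpressionNetwork", adjacency = a, power = power)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with unit diagonal, where `k` is the connectivity. Values lie in \[0, 1\]
#' for an adjacency in \[0, 1\].
#'
#' @param net a [CoexpressionNetwork-class].
#' @return The symmetric TOM matrix with gene dimnames.
#' @export
computeTOM <- function(net) {
    a <- adjacency(net)
    k <- rowSums(a) - 1
    num <- a %*% a - a           # sum over all u minus the u = i,j terms, + a_ij
    den <- outer(k, k, pmin) + 1 - a
    tom <- num / den
    diag(tom) <- 1
    tom <- (tom + t(tom)) / 2    # symmetrize against rounding
    tom
}

#' TOM dissimilarity
#' @param tom a topological overlap matrix.
#' @return `1 - tom`.
#' @export
tomDissimilarity <- function(tom) 1 - tom

#' Average-linkage clustering with a static branch cut
#'
#' Builds the average-linkage tree over the TOM dissimilarity and cuts it at
#' `cutHeight` (default `cutHeightFrac` times the maximum merge height).
#' Branches with at least `minSize` genes become modules, labeled by the
#' conventional color sequence in decreasing size order; all remaining genes
#' get the reserved label `"grey"`.
#'
#' When the network adjacency is supplied, candidate branches must also pass
#' a separability qualification: the mean adjacency within the branch has to
#' exceed `minDensityContrast` times the mean adjacency between the branch
#' and the rest of the network. This guards the static cut against
#' aggregates of mutually unconnected high-connectivity genes, whose
#' topological overlap is structured by connectivity alone (the expected
#' neighbour sum scales with the product of connectivities): such aggregates
#' are promiscuous, with a within/outside contrast near ten in null
#' simulations, while genuinely co-expressed modules concentrate their
#' adjacency inside and exceed a contrast of one hundred.
#'
#' @param diss symmetric dissimilarity matrix with gene dimnames.
#' @param minSize minimum module size (genes).
#' @param cutHeightFrac fraction of the maximum merge height at which to cut.
#' @param cutHeight absolute cut height; overrides `cutHeightFrac`.
#' @param adjacency optional adjacency matrix for the separability
#'   qualification.
#' @param minDensityContrast minimum ratio of within-branch to
#'   branch-to-outside mean adjacency for a branch to qualify; 0 disables
#'   the check.
#' @return A list with `dendrogram` (an `hclust`) and `labels` (named
#'   character vector gene -> module label).
#' @export
clusterAndCut <- function(diss, minSize = 30L, cutHeightFrac = 0.995,
                          cutHeight = NULL, adjacency = NULL,
                          minDensityContrast = 50) {
    tree <- stats::hclust(stats::as.dist(diss), method = "average")
    h <- cutHeight %||% (cutHeightFrac * max(tree$height))
    cl <- stats::cutree(tree, h = h)
    sizes <- table(cl)
    big <- names(sizes)[sizes >= minSize]
    if (length(big) && !is.null(adjacency) && minDensityContrast > 0) {
        offDiag <- adjacency
        diag(offDiag) <- NA
        dense <- vapply(big, function(b) {
            g <- names(cl)[cl == as.integer(b)]
            out <- setdiff(colnames(offDiag), g)
            if (!length(out)) return(TRUE)
            within <- mean(offDiag[g, g], na.rm = TRUE)
            between <- mean(offDiag[g, out])
            between == 0 || within / between >= minDensityContrast
        }, logical(1))
        if (any(!dense))
            .log("dropped %d branches with within/outside adjacency contrast below %g",
                 sum(!dense), minDensityContrast)
        big <- big[dense]
    }
    labels <- rep("grey", length(cl))
    names(labels) <- names(cl)
    if (!length(big)) {
        warning("no branch qualifies as a module; all genes grey")
    } else {
        # rank branches by size, ties broken by first-gene position for
        # deterministic labeling
        firstIdx <- vapply(big, function(b) min(which(cl == as.integer(b))),
                           integer(1))
        ord <- big[order(-as.integer(sizes[big]), firstIdx)]
        for (i in seq_along(ord))
            labels[cl == as.integer(ord[i])] <- .moduleColorName(i)
    }
    list(dendrogram = tree, labels = labels)
}

#' Module eigengenes
#'
#' Per module, member genes are standardized over samples and the first
#' principal component of the resulting matrix gives the eigengene, scaled
#' to unit variance and sign-oriented so its mean correlation with member
#' expression is non-negative. The fraction of member variance explained is
#' reported alongside.
#'
#' @param x an [ExpressionExperiment-class] on a log scale or a genes x
#'   samples matrix.
#' @param labels named character vector gene -> module label (`"grey"` is
#'   skipped). Every non-grey module needs >= 1 gene of positive variance.
#' @return A list with `eigengenes` (modules x samples matrix) and
#'   `varExplained` (named numeric).
#' @export
computeEigengenes <- function(x, labels) {
    m <- if (is(x, "ExpressionExperiment")) exprValues(x) else as.matrix(x)
    mods <- names(sort(table(labels[labels != "grey"]), decreasing = TRUE))
    if (!length(mods)) stop("no non-grey modules")
    em <- matrix(NA_real_, length(mods), ncol(m),
                 dimnames = list(mods, colnames(m)))
    ve <- setNames(numeric(length(mods)), mods)
    for (mod in mods) {
        genes <- names(labels)[labels == mod]
        sub <- m[genes, , drop = FALSE]
        sds <- apply(sub, 1L, stats::sd)
        if (any(sds == 0))
            stop("zero-variance genes in module '", mod, "'")
        z <- t(scale(t(sub)))
        sv <- svd(z, nu = 0L, nv = 1L)
        me <- sv$v[, 1L]
        me <- me / stats::sd(me)
        if (mean(stats::cor(me, t(z))) < 0) me <- -me
        em[mod, ] <- me
        ve[mod] <- sv$d[1L]^2 / sum(sv$d^2)
    }
    list(eigengenes = em, varExplained = ve)
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively merges the module pair with the most correlated eigengenes
#' whenever their eigengene dissimilarity `1 - cor` falls below
#' `mergeHeight`, recomputing eigengenes after every merge, until no pair
#' qualifies. The merged module keeps the larger module's label.
#'
#' @inheritParams computeEigengenes
#' @param mergeHeight eigengene dissimilarity below which modules merge.
#' @return A list with the updated `labels`, `eigengenes`, `varExplained`.
#' @export
mergeCloseModules <- function(x, labels, mergeHeight = 0.25) {
    m <- if (is(x, "ExpressionExperiment")) exprValues(x) else as.matrix(x)
    eg <- computeEigengenes(m, labels)
    repeat {
        mods <- rownames(eg$eigengenes)
        if (length(mods) < 2L) break
        cc <- stats::cor(t(eg$eigengenes))
        diag(cc) <- -Inf
        i <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
        if (1 - cc[i[1L], i[2L]] >= mergeHeight) break
        m1 <- mods[i[1L]]; m2 <- mods[i[2L]]
        sizes <- table(labels)
        keepLab <- if (sizes[[m1]] >= sizes[[m2]]) m1 else m2
        dropLab <- setdiff(c(m1, m2), keepLab)
        labels[labels == dropLab] <- keepLab
        .log("merged module %s into %s (eigengene cor %.3f)", dropLab,
             keepLab, cc[i[1L], i[2L]])
        eg <- computeEigengenes(m, labels)
    }
    list(labels = labels, eigengenes = eg$eigengenes,
         varExplained = eg$varExplained)
}

#' Full co-expression module detection
#'
#' Soft-threshold selection (unless `power` is fixed), unsigned adjacency,
#' TOM, average-linkage clustering with static branch cut, eigengenes, and
#' eigengene-based module merging.
#'
#' @param x an [ExpressionExperiment-class] on a log scale or genes x
#'   samples matrix.
#' @param power soft power, or `"auto"` to select by scale-free fit.
#' @param minSize minimum module size.
#' @param mergeHeight eigengene dissimilarity threshold for merging.
#' @param cutHeightFrac static-cut height as a fraction of the tallest merge.
#' @param signed build a signed network.
#' @param minDensityContrast separability qualification for branches (see
#'   [clusterAndCut()]); 0 disables it.
#' @return A [ModuleSet-class].
#' @export
detectModules <- function(x, power = 8, minSize = 30L, mergeHeight = 0.25,
                          cutHeightFrac = 0.995, signed = FALSE,
                          minDensityContrast = 50) {
    m <- if (is(x, "ExpressionExperiment")) exprValues(x) else as.matrix(x)
    fitTable <- data.frame()
    if (identical(power, "auto")) {
        sel <- pickSoftThreshold(m)
        power <- sel$power
        fitTable <- sel$fitTable
        .log("selected soft power %d by scale-free fit", power)
    }
    net <- computeAdjacency(m, power = power, signed = signed)
    tom <- computeTOM(net)
    cut <- clusterAndCut(tomDissimilarity(tom), minSize = minSize,
                         cutHeightFrac = cutHeightFrac,
                         adjacency = adjacency(net),
                         minDensityContrast = minDensityContrast)
    labels <- cut$labels
    if (all(labels == "grey")) {
        return(new("ModuleSet", labels = labels,
                   eigengenes = matrix(numeric(), 0L, ncol(m)),
                   varExplained = numeric(), power = as.numeric(power),
                   dendrogram = cut$dendrogram, fitTable = fitTable))
    }
    merged <- mergeCloseModules(m, labels, mergeHeight = mergeHeight)
    .log("detected %d modules over %d genes (%d grey)",
         length(unique(setdiff(merged$labels, "grey"))), length(merged$labels),
         sum(merged$labels == "grey"))
    new("ModuleSet", labels = merged$labels, eigengenes = merged$eigengenes,
        varExplained = merged$varExplained, power = as.numeric(power),
        dendrogram = cut$dendrogram, fitTable = fitTable)
}
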