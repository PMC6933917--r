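# Independent brute-force oracles used to validate the package's
# implementations, plus small fixture builders. The oracles deliberately use
# naive formulations (loops, enumeration, direct formulas) independent of
# the code paths they check.

# step-up BH by direct evaluation of the rule
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (i in m:1) {
        val <- min(prev, p[o[i]] * m / i)
        adj[o[i]] <- val
        prev <- val
    }
    pmin(adj, 1)
}

# regression-based one-way F via explicit sums of squares
anovaOracle <- function(values, groups) {
    groups <- factor(groups)
    fit <- stats::lm(values ~ groups)
    av <- stats::anova(fit)
    list(statistic = av$`F value`[1L], p = av$`Pr(>F)`[1L])
}

# O(n^3) triple-loop topological overlap
tomOracle <- function(a) {
    n <- nrow(a)
    k <- rowSums(a) - 1
    out <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        s <- 0
        for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
        out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    out
}

# exhaustive hypergeometric upper tail via binomial coefficients
hyperOracle <- function(k, K, n, N) {
    js <- k:min(K, n)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

jaccardOracle <- function(a, b) {
    u <- union(a, b)
    if (!length(u)) return(0)
    length(intersect(a, b)) / length(u)
}

# balanced multi-strain metadata, single batch
makeMeta <- function(strains = c("B6", "mutA"), reps = 3L, control = "B6") {
    reps <- rep_len(reps, length(strains))
    data.frame(
        sample = unlist(lapply(seq_along(strains), function(i)
            sprintf("%s_%02d", strains[i], seq_len(reps[i])))),
        strain = rep(strains, reps),
        batch = "batch1", stringsAsFactors = FALSE)
}

# small expression object from a matrix, defaulting sample names/metadata
makeExpr <- function(m, scale = "tpm", meta = NULL, control = "B6") {
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
    ExpressionExperiment(m, meta = meta, scale = scale, control = control)
}
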