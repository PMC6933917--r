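# Statistical primitives shared by all stages. Each is a thin, validated
# surface over the corresponding base-R machinery (p.adjust, the F, the
# studentized range, t and hypergeometric distributions), with the degenerate
# conventions the module scan relies on made explicit.

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values, order preserving and capped at 1. Inputs
#' outside \[0, 1\] are an error.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as `p`.
#' @export
adjustBH <- function(p) {
    p <- as.numeric(p)
    if (anyNA(p) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' One-way ANOVA
#'
#' F = MSB/MSW with the upper tail of F(df1, df2). Degenerate inputs follow
#' the convention needed by the eigengene scan: zero between-group variance
#' gives F = 0, p = 1 (also when within-group variance is zero); zero
#' within-group variance with positive between-group variance gives
#' F = Inf, p = 0.
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 groups with data; total residual
#'   df >= 1).
#' @return A list with `statistic` (F), `p`, `df1`, `df2`, `n`.
#' @export
oneWayAnova <- function(values, groups) {
    values <- as.numeric(values)
    groups <- droplevels(factor(groups))
    if (length(values) != length(groups)) stop("length mismatch")
    k <- nlevels(groups)
    if (k < 2L) stop("at least two groups are required")
    n <- length(values)
    df1 <- k - 1L
    df2 <- n - k
    if (df2 < 1L) stop("no residual degrees of freedom")
    gm <- tapply(values, groups, mean)
    gn <- tabulate(groups)
    ssb <- sum(gn * (gm - mean(values))^2)
    ssw <- sum((values - gm[groups])^2)
    if (ssb <= .Machine$double.eps * sum(values^2 + 1)) {
        f <- 0; p <- 1
    } else if (ssw <= .Machine$double.eps * sum(values^2 + 1)) {
        f <- Inf; p <- 0
    } else {
        f <- (ssb / df1) / (ssw / df2)
        p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    }
    list(statistic = f, p = p, df1 = df1, df2 = df2, n = n)
}

#' Tukey HSD pairwise comparisons
#'
#' Tukey-Kramer studentized-range test on all group pairs (or only pairs
#' involving `control`), using the pooled within-group mean square. The
#' family size for the studentized-range distribution is always the total
#' number of groups. When both the mean difference and the pooled variance
#' vanish the pair is reported with q = 0, p = 1; p-values are clamped to
#' \[0, 1\].
#'
#' @param values numeric response.
#' @param groups grouping factor; every group needs at least 2 observations.
#' @param control optional level: restrict output to contrasts vs `control`.
#' @return Data frame with `group1`, `group2`, `diff` (group1 - group2),
#'   `q`, `p`.
#' @export
tukeyHSDTest <- function(values, groups, control = NULL) {
    values <- as.numeric(values)
    groups <- droplevels(factor(groups))
    k <- nlevels(groups)
    if (k < 2L) stop("at least two groups are required")
    gn <- tabulate(groups)
    if (any(gn < 2L))
        stop("every group needs >= 2 observations for Tukey HSD: ",
             paste(levels(groups)[gn < 2L], collapse = ", "))
    gm <- tapply(values, groups, mean)
    df2 <- length(values) - k
    msw <- sum((values - gm[groups])^2) / df2
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2L)
    if (!is.null(control)) {
        if (!control %in% lev) stop("control level '", control, "' not found")
        keep <- pairs[1L, ] == control | pairs[2L, ] == control
        pairs <- pairs[, keep, drop = FALSE]
        # orient contrasts as group vs control
        flip <- pairs[1L, ] == control
        pairs[, flip] <- rbind(pairs[2L, flip], pairs[1L, flip])
    }
    res <- apply(pairs, 2L, function(pr) {
        i <- pr[1L]; j <- pr[2L]
        d <- gm[[i]] - gm[[j]]
        se <- sqrt(msw / 2 * (1 / gn[match(i, lev)] + 1 / gn[match(j, lev)]))
        if (se == 0) {
            q <- if (abs(d) == 0) 0 else Inf
        } else q <- abs(d) / se
        p <- if (is.infinite(q)) 0 else
            stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
        if (!is.finite(p)) stop("studentized-range evaluation failed")
        c(diff = d, q = q, p = min(max(p, 0), 1))
    })
    data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
               diff = res["diff", ], q = res["q", ], p = res["p", ],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation test
#'
#' r with the two-sided p from t = r * sqrt((n-2)/(1-r^2)) on t(n-2);
#' |r| = 1 gives p = 0. Zero variance in either vector is an error flagged as
#' degenerate input.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return A list with `estimate` (r), `statistic` (t), `p`, `df`, `n`.
#' @export
pearsonCorTest <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) != length(y)) stop("length mismatch")
    n <- length(x)
    if (n < 3L) stop("at least 3 observations are required")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("degenerate input: zero variance")
    r <- stats::cor(x, y)
    df <- n - 2L
    if (abs(r) >= 1) {
        r <- sign(r)
        tstat <- sign(r) * Inf
        p <- 0
    } else {
        tstat <- r * sqrt(df / (1 - r^2))
        p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    }
    list(estimate = r, statistic = tstat, p = p, df = df, n = n)
}

#' Hypergeometric upper tail
#'
#' P\[X >= k\] for X ~ hypergeometric with `K` successes in a universe of
#' `N`, drawing `n`.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K gene-set size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return The upper-tail probability.
#' @export
hypergeomTail <- function(k, K, n, N) {
    stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
    if (K > N || n > N || k > min(K, n) || k < 0)
        stop("inconsistent sizes: need 0 <= k <= min(K, n) <= N")
    stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}
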