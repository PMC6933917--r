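# Generic over-representation analysis of a gene list against a gene-set
# catalog via the hypergeometric upper tail. The recommended universe is the
# analyzed transcriptome (genes surviving the low-expression filter), not
# the whole genome.

#' Over-representation analysis
#'
#' For each catalog set (intersected with the universe; empty intersections
#' are skipped), the hypergeometric upper-tail probability of the observed
#' overlap with the query, BH-adjusted across tested sets. Query genes
#' outside the universe are dropped with a logged count.
#'
#' @param query character vector of query genes (e.g. one module).
#' @param catalog a [GeneSetCatalog-class].
#' @param universe character vector of background genes.
#' @param alpha significance threshold recorded in the `significant` column.
#' @return Data frame sorted by p: `set`, `group`, `k` (overlap), `K` (set
#'   size in universe), `n` (query size), `N` (universe size), `p`, `padj`,
#'   `significant`, `genes` (comma-separated overlap).
#' @export
ora <- function(query, catalog, universe, alpha = 0.05) {
    universe <- unique(as.character(universe))
    query0 <- unique(as.character(query))
    query <- intersect(query0, universe)
    if (length(query) < length(query0))
        .log("ora: dropped %d query genes outside the universe",
             length(query0) - length(query))
    if (!length(query)) stop("empty query after intersection with universe")
    N <- length(universe)
    n <- length(query)
    rows <- lapply(names(catalog), function(nm) {
        set <- intersect(geneSets(catalog)[[nm]], universe)
        K <- length(set)
        if (!K) return(NULL)
        ov <- intersect(set, query)
        k <- length(ov)
        grp <- setGroups(catalog)
        data.frame(set = nm,
                   group = if (nm %in% names(grp)) grp[[nm]] else NA_character_,
                   k = k, K = K, n = n, N = N,
                   p = hypergeomTail(k, K, n, N),
                   genes = paste(sort(ov), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) stop("no catalog set intersects the universe")
    out <- do.call(rbind, rows)
    out$padj <- adjustBH(out$p)
    out$significant <- out$padj < alpha
    out <- out[order(out$p, out$set), ]
    rownames(out) <- NULL
    out[, c("set", "group", "k", "K", "n", "N", "p", "padj", "significant",
            "genes")]
}
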