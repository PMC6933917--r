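# internal helpers shared across stages

.log <- function(...) message("[crossmod] ", sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

.checkSeed <- function(seed) {
    if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("a single integer seed is required")
    as.integer(seed)
}

# Deterministic per-stage substream: each stochastic stage draws from its own
# seed derived from the global one, so changing one stage leaves others intact.
.stageSeed <- function(seed, stage) {
    offsets <- c(design = 101L, expression = 211L, human = 307L,
                 overlap = 401L, pipeline = 503L)
    (as.integer(seed) * 31L + offsets[[stage]]) %% .Machine$integer.max
}

.writeTSV <- function(df, path, rownames = FALSE) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = rownames, col.names = TRUE)
    invisible(path)
}
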