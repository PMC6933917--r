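# Readers and writers for the on-disk formats: TSV expression matrices,
# sample metadata, ortholog maps, human log2FC tables, and GMT gene sets.
# All readers validate before anything downstream runs. Dialect: tab
# separated, UTF-8, "." decimal, no quoting; the first header cell of a
# matrix file is ignored. Gene identifiers are opaque, case-sensitive
# strings: no case folding anywhere (cross-species identity is solely the
# ortholog map's job).

.readTSV <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "", colClasses = "character")
}

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Duplicate identifiers, missing or non-numeric cells, and
#' negative values (for `counts`/`tpm`) are hard errors that name the
#' offending gene/sample.
#'
#' @param path TSV file path.
#' @param scale measurement scale of the stored values (`"counts"`, `"tpm"`,
#'   `"log2tpm"`).
#' @param meta optional sample metadata data frame (see
#'   [readSampleMetadata()]); attached to the returned object.
#' @param control control strain level used when `meta` is supplied.
#' @return An [ExpressionExperiment-class].
#' @export
readExpression <- function(path, scale = c("counts", "tpm", "log2tpm"),
                           meta = NULL, control = "B6") {
    scale <- match.arg(scale)
    df <- .readTSV(path)
    if (ncol(df) < 2L) stop("expression file needs a gene column and >= 1 sample")
    genes <- df[[1L]]
    if (anyDuplicated(genes))
        stop("duplicated gene identifiers in ", path, ": ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    vals <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                   dimnames = list(genes, colnames(vals))))
    bad <- which(is.na(num), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-numeric or missing cell at gene '", genes[bad[1L, 1L]],
             "', sample '", colnames(num)[bad[1L, 2L]], "' in ", path)
    ExpressionExperiment(num, meta = meta, scale = scale, control = control)
}

#' Write an expression matrix to TSV
#'
#' @param x an [ExpressionExperiment-class] or a named numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
    m <- if (is(x, "ExpressionExperiment")) exprValues(x) else as.matrix(x)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .writeTSV(df, path)
}

#' Read sample metadata from TSV
#'
#' Columns: `sample`, `strain`, and optionally `batch` (missing batch
#' defaults to a single level `"batch1"` with a warning).
#'
#' @param path TSV file path.
#' @param control control strain level; must be present with at least two
#'   samples whenever more than one strain is listed.
#' @return A data frame with columns `sample`, `strain`, `batch`.
#' @export
readSampleMetadata <- function(path, control = "B6") {
    df <- .readTSV(path)
    .validateMetadata(df, control = control)
}

#' Write sample metadata to TSV
#' @param meta data frame with columns `sample`, `strain`, `batch`.
#' @param path output file path.
#' @export
writeSampleMetadata <- function(meta, path) {
    .writeTSV(meta[, c("sample", "strain", "batch")], path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, fields `name`, `description`, then gene
#' identifiers, all tab separated. Duplicate genes within a line are
#' collapsed silently (with a log line); duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return A [GeneSetCatalog-class].
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(GeneSetCatalog(list()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("GMT line ", short[1L], " has fewer than 3 fields in ", path)
    nm <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(nm))
        stop("duplicated gene-set names in ", path, ": ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    desc <- vapply(fields, `[[`, character(1), 2L)
    sets <- lapply(fields, function(f) f[-(1:2)])
    ndup <- sum(lengths(sets) - lengths(lapply(sets, unique)))
    if (ndup > 0L)
        .log("collapsed %d duplicate gene entries across GMT sets", ndup)
    sets <- lapply(sets, unique)
    names(sets) <- nm
    names(desc) <- nm
    GeneSetCatalog(sets, description = desc)
}

#' Write a gene-set catalog to GMT
#' @param catalog a [GeneSetCatalog-class].
#' @param path output file path.
#' @export
writeGMT <- function(catalog, path) {
    nm <- names(catalog)
    desc <- if (length(catalog@description)) catalog@description[nm] else
        setNames(rep("na", length(nm)), nm)
    desc[is.na(desc)] <- "na"
    lines <- vapply(nm, function(n)
        paste(c(n, desc[[n]], geneSets(catalog)[[n]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a mouse-human ortholog map from TSV
#'
#' Two or three columns: mouse gene, human gene, optional confidence flag.
#' Exactly duplicated rows are dropped with a warning; empty identifiers are
#' an error.
#'
#' @param path TSV file path.
#' @return A data frame with columns `mouse`, `human` (and `confidence` if
#'   present).
#' @export
readOrthologMap <- function(path) {
    df <- .readTSV(path)
    if (ncol(df) < 2L) stop("ortholog map needs at least 2 columns")
    names(df)[1:2] <- c("mouse", "human")
    if (ncol(df) >= 3L) names(df)[3L] <- "confidence"
    if (any(!nzchar(df$mouse)) || any(!nzchar(df$human)) ||
        anyNA(df$mouse) || anyNA(df$human))
        stop("empty gene identifiers in ortholog map ", path)
    dup <- duplicated(df[, c("mouse", "human")])
    if (any(dup)) {
        warning(sum(dup), " duplicated ortholog rows dropped")
        df <- df[!dup, , drop = FALSE]
    }
    rownames(df) <- NULL
    df
}

#' Write an ortholog map to TSV
#' @param map data frame with columns `mouse`, `human`.
#' @param path output file path.
#' @export
writeOrthologMap <- function(map, path) .writeTSV(map, path)

#' Read a human log2 fold-change table from TSV
#'
#' First column: human gene identifiers (unique); each further column: one
#' region/cohort label with finite log2FC(AD/control) values. Any missing or
#' non-numeric cell is an error.
#'
#' @param path TSV file path.
#' @return A data frame with column `gene` plus one numeric column per region.
#' @export
readLFCTable <- function(path) {
    df <- .readTSV(path)
    if (ncol(df) < 2L) stop("LFC table needs a gene column and >= 1 region")
    names(df)[1L] <- "gene"
    if (anyDuplicated(df$gene))
        stop("duplicated gene identifiers in LFC table ", path, ": ",
             paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
    for (j in 2:ncol(df)) {
        v <- suppressWarnings(as.numeric(df[[j]]))
        if (anyNA(v) || any(!is.finite(v)))
            stop("missing or non-finite value in LFC column '",
                 names(df)[j], "' of ", path)
        df[[j]] <- v
    }
    rownames(df) <- NULL
    df
}

#' Write a human log2 fold-change table to TSV
#' @param lfc data frame with column `gene` plus numeric region columns.
#' @param path output file path.
#' @export
writeLFCTable <- function(lfc, path) .writeTSV(lfc, path)
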