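#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

.SCALE_TAGS <- c("counts", "tpm", "log2tpm")

#' Gene-by-sample expression container
#'
#' An `ExpressionExperiment` is a [SummarizedExperiment::SummarizedExperiment]
#' holding one gene x sample assay tagged with its measurement scale
#' (`counts`, `tpm` or `log2tpm`), together with per-sample strain and batch
#' annotation in `colData` and the designated control strain level.
#'
#' Validity requires unique non-empty gene and sample identifiers, no missing
#' values, non-negative values for `counts`/`tpm` (integral for `counts`),
#' and that the strain/batch annotation covers every sample.
#'
#' @name ExpressionExperiment-class
#' @aliases ExpressionExperiment
#' @exportClass ExpressionExperiment
setClass("ExpressionExperiment", contains = "SummarizedExperiment")

setValidity("ExpressionExperiment", function(object) {
    msgs <- character()
    if (length(SummarizedExperiment::assays(object)) != 1L)
        msgs <- c(msgs, "exactly one assay is required")
    m <- SummarizedExperiment::assay(object)
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msgs <- c(msgs, "gene and sample identifiers are required")
    else {
        if (anyDuplicated(rownames(m)))
            msgs <- c(msgs, paste0("duplicate gene identifiers: ",
                paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
        if (anyDuplicated(colnames(m)))
            msgs <- c(msgs, paste0("duplicate sample identifiers: ",
                paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
        if (any(!nzchar(rownames(m))) || any(!nzchar(colnames(m))))
            msgs <- c(msgs, "empty gene or sample identifiers")
    }
    if (anyNA(m))
        msgs <- c(msgs, "missing values are not allowed")
    tag <- S4Vectors::metadata(object)$scale
    if (is.null(tag) || !tag %in% .SCALE_TAGS)
        msgs <- c(msgs, paste0("scale tag must be one of: ",
                               paste(.SCALE_TAGS, collapse = ", ")))
    else if (!anyNA(m)) {
        if (tag %in% c("counts", "tpm") && any(m < 0))
            msgs <- c(msgs, paste0("negative values are not allowed on scale '", tag, "'"))
        if (tag == "counts" && any(abs(m - round(m)) > 1e-8))
            msgs <- c(msgs, "counts must be integral")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("strain", "batch") %in% colnames(cd)))
        msgs <- c(msgs, "colData must contain 'strain' and 'batch'")
    if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionExperiment
#'
#' @param values numeric matrix, genes in rows (named), samples in columns (named).
#' @param meta data frame of sample metadata with columns `sample`, `strain`
#'   and optionally `batch` (defaults to a single level `"batch1"` with a
#'   warning), one row per expression sample. May be `NULL` only for
#'   intermediate objects that never reach strain-aware stages.
#' @param scale one of `"counts"`, `"tpm"`, `"log2tpm"`.
#' @param control control strain level, present in `meta$strain` with at least
#'   two samples when `meta` carries more than one strain.
#' @return An [ExpressionExperiment-class] object.
#' @export
ExpressionExperiment <- function(values, meta = NULL,
                                 scale = c("counts", "tpm", "log2tpm"),
                                 control = "B6") {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    if (is.null(meta)) {
        meta <- data.frame(sample = colnames(values),
                           strain = "unknown", batch = "batch1",
                           stringsAsFactors = FALSE)
        control <- "unknown"
    }
    meta <- .validateMetadata(meta, samples = colnames(values), control = control)
    cd <- S4Vectors::DataFrame(strain = factor(meta$strain),
                               batch = factor(meta$batch),
                               row.names = meta$sample)
    cd <- cd[colnames(values), , drop = FALSE]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), colData = cd)
    S4Vectors::metadata(se)$scale <- scale
    S4Vectors::metadata(se)$control <- control
    new("ExpressionExperiment", se)
}

.validateMetadata <- function(meta, samples = NULL, control = "B6") {
    meta <- as.data.frame(meta)
    if (!all(c("sample", "strain") %in% colnames(meta)))
        stop("sample metadata must contain columns 'sample' and 'strain'")
    if (!"batch" %in% colnames(meta)) {
        warning("metadata has no 'batch' column; assuming a single batch 'batch1'")
        meta$batch <- "batch1"
    }
    meta$sample <- as.character(meta$sample)
    if (anyDuplicated(meta$sample))
        stop("duplicated sample identifiers in metadata: ",
             paste(unique(meta$sample[duplicated(meta$sample)]), collapse = ", "))
    if (!is.null(samples)) {
        missing <- setdiff(samples, meta$sample)
        if (length(missing))
            stop("expression samples missing from metadata: ",
                 paste(missing, collapse = ", "))
        meta <- meta[match(samples, meta$sample), , drop = FALSE]
    }
    strains <- unique(as.character(meta$strain))
    if (length(strains) > 1L) {
        if (!control %in% strains)
            stop("control strain '", control, "' not present in metadata")
        if (sum(meta$strain == control) < 2L)
            stop("control strain '", control, "' must have at least 2 samples")
    }
    meta
}

#' @describeIn ExpressionExperiment-class the expression matrix (genes x samples).
#' @param x an `ExpressionExperiment`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x)

#' @describeIn ExpressionExperiment-class the measurement-scale tag.
#' @export
scaleTag <- function(x) S4Vectors::metadata(x)$scale

#' @describeIn ExpressionExperiment-class the control strain level.
#' @export
controlLevel <- function(x) S4Vectors::metadata(x)$control

#' @describeIn ExpressionExperiment-class per-sample strain factor.
#' @export
sampleStrains <- function(x) SummarizedExperiment::colData(x)$strain

#' @describeIn ExpressionExperiment-class per-sample batch factor.
#' @export
sampleBatches <- function(x) SummarizedExperiment::colData(x)$batch

.replaceValues <- function(x, values, scale = scaleTag(x)) {
    SummarizedExperiment::assay(x, withDimnames = FALSE) <- values
    S4Vectors::metadata(x)$scale <- scale
    validObject(x)
    x
}

setMethod("show", "ExpressionExperiment", function(object) {
    cat("ExpressionExperiment:", nrow(object), "genes x", ncol(object),
        "samples\n")
    cat("  scale:", scaleTag(object), " control:", controlLevel(object), "\n")
    cat("  strains:", paste(levels(droplevels(factor(sampleStrains(object)))),
                            collapse = ", "), "\n")
    cat("  batches:", paste(levels(droplevels(factor(sampleBatches(object)))),
                            collapse = ", "), "\n")
})

#' Catalog of named gene sets
#'
#' Holds a named list of gene identifier sets (e.g. the human AD brain
#' co-expression module catalog, or GO/KEGG/regulon collections read from
#' GMT), with an optional grouping label per set (e.g. consensus cluster
#' A-E). Set names must be unique and sets non-empty.
#'
#' @name GeneSetCatalog-class
#' @aliases GeneSetCatalog
#' @exportClass GeneSetCatalog
setClass("GeneSetCatalog",
         representation(sets = "list", groups = "character",
                        description = "character"))

setValidity("GeneSetCatalog", function(object) {
    msgs <- character()
    s <- object@sets
    if (length(s) && (is.null(names(s)) || any(!nzchar(names(s)))))
        msgs <- c(msgs, "all gene sets must be named")
    else if (anyDuplicated(names(s)))
        msgs <- c(msgs, paste0("duplicated set names: ",
            paste(unique(names(s)[duplicated(names(s))]), collapse = ", ")))
    if (any(lengths(s) == 0L))
        msgs <- c(msgs, "empty gene sets are not allowed")
    if (!all(vapply(s, is.character, logical(1))))
        msgs <- c(msgs, "gene sets must be character vectors")
    if (length(object@groups) && is.null(names(object@groups)))
        msgs <- c(msgs, "groups must be named by set")
    if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetCatalog
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param groups optional named character vector of grouping labels per set.
#' @param description optional named character vector of set descriptions.
#' @return A [GeneSetCatalog-class] object.
#' @export
GeneSetCatalog <- function(sets, groups = character(), description = character()) {
    sets <- lapply(sets, function(g) unique(as.character(g)))
    new("GeneSetCatalog", sets = sets, groups = groups, description = description)
}

#' @describeIn GeneSetCatalog-class the named list of gene sets.
#' @param x a `GeneSetCatalog`.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCatalog-class grouping labels (may be empty).
#' @export
setGroups <- function(x) x@groups

setMethod("names", "GeneSetCatalog", function(x) names(x@sets))
setMethod("length", "GeneSetCatalog", function(x) length(x@sets))
setMethod("[[", "GeneSetCatalog", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCatalog", function(object) {
    cat("GeneSetCatalog with", length(object@sets), "sets\n")
    sz <- lengths(object@sets)
    if (length(sz))
        cat("  set sizes:", min(sz), "-", max(sz),
            "(median", stats::median(sz), ")\n")
    if (length(object@groups))
        cat("  groups:", paste(sort(unique(object@groups)), collapse = ", "), "\n")
})

#' Co-expression module detection result
#'
#' Bundles the per-gene module assignment (reserved label `"grey"` marks
#' unassigned genes), the module eigengene matrix (modules x samples, each
#' eigengene unit variance and sign-oriented towards its members), the
#' fraction of member variance each eigengene explains, the soft power used,
#' the gene dendrogram, and the soft-threshold fit table.
#'
#' @name ModuleSet-class
#' @aliases ModuleSet
#' @exportClass ModuleSet
setClass("ModuleSet",
         representation(labels = "character", eigengenes = "matrix",
                        varExplained = "numeric", power = "numeric",
                        dendrogram = "ANY", fitTable = "data.frame"))

setValidity("ModuleSet", function(object) {
    msgs <- character()
    if (is.null(names(object@labels)))
        msgs <- c(msgs, "labels must be named by gene")
    mods <- setdiff(unique(object@labels), "grey")
    if (nrow(object@eigengenes) &&
        !setequal(rownames(object@eigengenes), mods))
        msgs <- c(msgs, "eigengene rows must match non-grey module labels")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn ModuleSet-class named character vector gene -> module label.
#' @param x a `ModuleSet`.
#' @export
moduleLabels <- function(x) x@labels

#' @describeIn ModuleSet-class non-grey module names, ordered by size.
#' @export
moduleNames <- function(x) {
    tab <- table(x@labels[x@labels != "grey"])
    names(sort(tab, decreasing = TRUE))
}

#' @describeIn ModuleSet-class list of member-gene vectors per module.
#' @param modules module names to extract; default all non-grey modules.
#' @export
moduleGenes <- function(x, modules = moduleNames(x)) {
    out <- lapply(modules, function(m) names(x@labels)[x@labels == m])
    names(out) <- modules
    out
}

#' @describeIn ModuleSet-class module x sample eigengene matrix.
#' @export
eigengenes <- function(x) x@eigengenes

#' @describeIn ModuleSet-class fraction of member variance per eigengene.
#' @export
varExplained <- function(x) x@varExplained

setMethod("show", "ModuleSet", function(object) {
    mods <- moduleNames(object)
    cat("ModuleSet:", length(mods), "modules over", length(object@labels),
        "genes (", sum(object@labels == "grey"), "grey )\n")
    if (length(object@power)) cat("  soft power:", object@power, "\n")
    if (length(mods)) {
        sizes <- table(object@labels)[mods]
        show_n <- head(mods, 8L)
        cat("  sizes:", paste(paste0(show_n, "=", sizes[show_n]),
                              collapse = " "),
            if (length(mods) > 8L) "..." else "", "\n")
    }
})
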