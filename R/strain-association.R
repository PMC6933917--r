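# Which modules are driven by which strains: one-way ANOVA on each module
# eigengene over strain groups (BH-adjusted across modules), followed by
# Tukey HSD contrasts against the control strain for significant modules.

#' Associate module eigengenes with strains
#'
#' Per module, a one-way ANOVA of the eigengene over strain groups; ANOVA
#' p-values are BH-adjusted across modules. Modules passing `alpha` get
#' Tukey HSD contrasts (strain vs control by default; all pairs via
#' `allPairs`). A strain is flagged as a driver of a module when the module's
#' BH-adjusted ANOVA p and the strain-vs-control Tukey family-wise p are both
#' below `alpha`. Strains with a single sample are excluded from the Tukey
#' step with a warning.
#'
#' @param modules a [ModuleSet-class], or a modules x samples eigengene
#'   matrix.
#' @param meta sample metadata data frame (`sample`, `strain`, `batch`) or
#'   an [ExpressionExperiment-class] carrying the annotation.
#' @param alpha significance threshold for both tests.
#' @param control control strain level.
#' @param allPairs report all pairwise Tukey contrasts instead of only
#'   strain vs control.
#' @return Data frame with one row per (module, strain) contrast: `module`,
#'   `anovaF`, `anovaP`, `anovaPadj`, `strain`, `diff` (eigengene mean
#'   difference vs control), `tukeyP`, `driver`.
#' @export
associateStrains <- function(modules, meta, alpha = 0.05, control = "B6",
                             allPairs = FALSE) {
    em <- if (is(modules, "ModuleSet")) eigengenes(modules) else
        as.matrix(modules)
    if (is(meta, "ExpressionExperiment")) {
        control <- controlLevel(meta)
        meta <- data.frame(sample = colnames(meta),
                           strain = as.character(sampleStrains(meta)),
                           batch = as.character(sampleBatches(meta)),
                           stringsAsFactors = FALSE)
    }
    meta <- .validateMetadata(meta, samples = colnames(em), control = control)
    strain <- factor(meta$strain)
    if (nlevels(strain) < 2L) stop("at least two strains are required")
    an <- lapply(rownames(em), function(mod) oneWayAnova(em[mod, ], strain))
    anovaP <- vapply(an, `[[`, numeric(1), "p")
    anovaPadj <- adjustBH(anovaP)
    singletons <- names(which(table(strain) < 2L))
    if (length(singletons))
        warning("strains with a single sample excluded from Tukey HSD: ",
                paste(singletons, collapse = ", "))
    rows <- list()
    for (i in seq_along(rownames(em))) {
        mod <- rownames(em)[i]
        keep <- !(as.character(strain) %in% singletons)
        tk <- if (anovaPadj[i] < alpha) {
            tukeyHSDTest(em[mod, keep], droplevels(strain[keep]),
                         control = if (allPairs) NULL else control)
        } else NULL
        contrasts <- setdiff(levels(strain), c(control, singletons))
        for (s in contrasts) {
            if (is.null(tk)) {
                d <- mean(em[mod, strain == s]) - mean(em[mod, strain == control])
                rows[[length(rows) + 1L]] <- data.frame(
                    module = mod, anovaF = an[[i]]$statistic, anovaP = anovaP[i],
                    anovaPadj = anovaPadj[i], strain = s, diff = d,
                    tukeyP = NA_real_, driver = FALSE,
                    stringsAsFactors = FALSE)
            } else {
                row <- tk[tk$group1 == s & tk$group2 == control, , drop = FALSE]
                if (!nrow(row))
                    row <- tk[tk$group1 == control & tk$group2 == s, , drop = FALSE]
                rows[[length(rows) + 1L]] <- data.frame(
                    module = mod, anovaF = an[[i]]$statistic, anovaP = anovaP[i],
                    anovaPadj = anovaPadj[i], strain = s, diff = row$diff[1L],
                    tukeyP = row$p[1L],
                    driver = anovaPadj[i] < alpha & row$p[1L] < alpha,
                    stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, rows)
    .log("strain association: %d of %d modules significant, %d driver calls",
         length(unique(out$module[out$anovaPadj < alpha])), nrow(em),
         sum(out$driver))
    out
}

#' Driver strains per module
#'
#' @param drivers output of [associateStrains()].
#' @return Named list: for each module with at least one driver, the driver
#'   strain labels.
#' @export
driverStrains <- function(drivers) {
    hit <- drivers[drivers$driver, , drop = FALSE]
    split(hit$strain, hit$module)
}
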