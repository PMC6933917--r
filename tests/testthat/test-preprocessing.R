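test_that("low-expression filter applies the strict-majority rule", {
    # gene1: >= 10 TPM in exactly 1 of 10 samples -> fraction below = 0.9,
    # not > 0.9, so it is kept; gene2 all zeros is removed
    m <- rbind(g1 = c(15, rep(1, 9)), g2 = rep(0, 10), g3 = rep(50, 10))
    colnames(m) <- paste0("s", 1:10)
    ee <- makeExpr(m, control = "unknown")
    out <- suppressMessages(filterLowExpression(ee))
    expect_setequal(rownames(out), c("g1", "g3"))
    # minTPM = 0 is the identity
    expect_equal(nrow(suppressMessages(filterLowExpression(ee, minTPM = 0))), 3L)
    # idempotent
    out2 <- suppressMessages(filterLowExpression(out))
    expect_identical(rownames(out2), rownames(out))
    # removing everything is an error
    low <- makeExpr(matrix(0.1, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4))),
                    control = "unknown")
    expect_error(suppressMessages(filterLowExpression(low)), "all genes")
})

test_that("log transform is exact and tags the scale", {
    m <- matrix(c(0, 1, 3, 7), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
    ee <- makeExpr(m, control = "unknown")
    lt <- logTransform(ee)
    expect_equal(exprValues(lt), matrix(c(0, 1, 2, 3), 2,
        dimnames = dimnames(m)))
    expect_identical(scaleTag(lt), "log2tpm")
    expect_error(logTransform(lt), "tpm")
})

test_that("single-batch correction is the identity", {
    meta <- makeMeta(c("B6", "Clu"), reps = 4)
    set.seed(21)
    m <- matrix(rnorm(40, 6), 5, 8,
                dimnames = list(paste0("g", 1:5), meta$sample))
    ee <- ExpressionExperiment(m, meta = meta, scale = "log2tpm")
    expect_equal(exprValues(suppressMessages(correctBatch(ee))), m)
})

test_that("pure location batch shift is removed exactly without shrinkage", {
    meta <- makeMeta(c("B6", "Clu"), reps = 6)
    meta$batch <- rep(c("b1", "b2"), 6)   # balanced: no strain confounding
    set.seed(22)
    m <- matrix(rnorm(20 * 12, 6), 20, 12,
                dimnames = list(paste0("g", 1:20), meta$sample))
    shift <- runif(20, -2, 2)
    m[, meta$batch == "b2"] <- m[, meta$batch == "b2"] + shift
    ee <- ExpressionExperiment(m, meta = meta, scale = "log2tpm")
    out <- exprValues(suppressMessages(correctBatch(ee, eb = FALSE)))
    b1mean <- rowMeans(out[, meta$batch == "b1"])
    b2mean <- rowMeans(out[, meta$batch == "b2"])
    expect_lt(max(abs(b1mean - b2mean)), 1e-10)
    # overall gene means preserved
    expect_equal(rowMeans(out), rowMeans(m), tolerance = 1e-10)
})

test_that("empirical-Bayes correction matches the sva ComBat reference", {
    meta <- makeMeta(c("B6", "Clu", "Apoe"), reps = 6)
    meta$batch <- rep(c("b1", "b1", "b2"), 6)
    set.seed(23)
    m <- matrix(rnorm(200 * 18, 6), 200, 18,
                dimnames = list(paste0("g", 1:200), meta$sample))
    m[, meta$batch == "b2"] <- m[, meta$batch == "b2"] +
        rnorm(200, 0.8, 0.4) + 0.2 * rnorm(200 * sum(meta$batch == "b2"))
    ee <- ExpressionExperiment(m, meta = meta, scale = "log2tpm")
    mine <- exprValues(suppressMessages(correctBatch(ee, eb = TRUE)))
    mod <- stats::model.matrix(~factor(meta$strain))
    ref <- sva::ComBat(m, batch = factor(meta$batch), mod = mod)
    expect_lt(max(abs(mine - ref)), 1e-3)
})

test_that("batch correction commutes with sample reordering", {
    meta <- makeMeta(c("B6", "Clu"), reps = 6)
    meta$batch <- rep(c("b1", "b2"), 6)
    set.seed(24)
    m <- matrix(rnorm(30 * 12, 6), 30, 12,
                dimnames = list(paste0("g", 1:30), meta$sample))
    m[, meta$batch == "b2"] <- m[, meta$batch == "b2"] + 1
    ee <- ExpressionExperiment(m, meta = meta, scale = "log2tpm")
    out1 <- exprValues(suppressMessages(correctBatch(ee)))
    perm <- sample(ncol(m))
    ee2 <- ExpressionExperiment(m[, perm], meta = meta[perm, ],
                                scale = "log2tpm")
    out2 <- exprValues(suppressMessages(correctBatch(ee2)))
    expect_equal(out2[, colnames(out1)], out1, tolerance = 1e-10)
})

test_that("correction removes planted batch structure but keeps strain signal", {
    # balanced strain-by-batch layout so batch variance is identifiable
    layout <- data.frame(strain = c("B6", "Clu", "B6", "Clu"),
                         batch = c("b1", "b1", "b2", "b2"),
                         n = c(6L, 6L, 6L, 6L))
    cfg <- simConfig(layout = layout, nGenes = 600, nModules = 3,
                     moduleSize = 40)
    sim <- simulateStudy(cfg, seed = 7)
    lg <- logTransform(sim$tpm)
    corrected <- suppressMessages(correctBatch(lg))
    batch <- as.integer(factor(sim$design$batch))
    # before: some leading PC separates batches; after: batch explains < 1%
    # of the variance of every leading component
    pcAfter <- runPCA(corrected)
    batchR2 <- function(scores) {
        apply(scores[, 1:5], 2, function(s)
            summary(stats::lm(s ~ factor(batch)))$r.squared)
    }
    r2a <- batchR2(pcAfter$scores)
    varByBatch <- sum(r2a * pcAfter$varExplained[1:5])
    expect_lt(varByBatch, 0.01)
    # planted strain differences preserved within 10% (ANOVA F on module genes)
    genes <- names(sim$truth$membership)[sim$truth$membership == "M01"][1:10]
    strain <- sim$design$strain
    keep <- strain %in% c("B6", sim$truth$driverStrains[["M01"]])
    fBefore <- vapply(genes, function(g)
        oneWayAnova(exprValues(lg)[g, keep], strain[keep])$statistic, numeric(1))
    fAfter <- vapply(genes, function(g)
        oneWayAnova(exprValues(corrected)[g, keep], strain[keep])$statistic,
        numeric(1))
    expect_gt(mean(fAfter) / mean(fBefore), 0.9)
})

test_that("PCA is deterministic, conservative and distance preserving", {
    set.seed(25)
    # samples on a line in gene space -> first component takes everything
    base <- rnorm(10)
    t_ <- seq(0, 1, length.out = 6)
    m <- outer(base, t_) + 5
    dimnames(m) <- list(paste0("g", 1:10), paste0("s", 1:6))
    p <- runPCA(m)
    expect_equal(p$varExplained[1], 1, tolerance = 1e-10)
    # variance fractions sum to 1 and are non-increasing
    m2 <- matrix(rnorm(80, 5), 10, 8,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
    p2 <- runPCA(m2)
    expect_equal(sum(p2$varExplained), 1, tolerance = 1e-10)
    expect_true(all(diff(p2$varExplained) <= 1e-12))
    # full scores reproduce pairwise distances of the centered data
    centered <- m2 - rowMeans(m2)
    expect_equal(as.matrix(dist(t(centered))), as.matrix(dist(p2$scores)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_error(runPCA(matrix(3, 4, 4,
        dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))), "constant")
})
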