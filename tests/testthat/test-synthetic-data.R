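test_that("the default design reproduces the emulated study layout", {
    meta <- simDesign(simConfig(), seed = 1)
    expect_equal(nrow(meta), 48L)
    expect_equal(sort(unique(meta$batch)), c("batch1", "batch2", "batch3"))
    expect_equal(unname(table(meta$batch)[c("batch1", "batch2", "batch3")]),
                 c(36L, 8L, 4L), ignore_attr = TRUE)
    expect_equal(sum(meta$strain == "B6"), 13L)
    expect_equal(sum(meta$strain == "APP_PS1"), 5L)
    # determinism
    expect_identical(meta, simDesign(simConfig(), seed = 1))
    # custom minimal design
    small <- simConfig(layout = data.frame(strain = c("B6", "mutA"),
                                           batch = "batch1", n = 3L))
    expect_equal(nrow(simDesign(small, seed = 2)), 6L)
    # zero control replicates is an error
    expect_error(simConfig(layout = data.frame(strain = "mutA",
                                               batch = "b1", n = 3L)),
                 "control")
})

test_that("the noise-free limit gives perfectly correlated module genes", {
    cfg <- simConfig(layout = data.frame(strain = c("B6", "Clu"),
                                         batch = "batch1", n = 6L),
                     nGenes = 200, nModules = 2, moduleSize = 30,
                     noiseSD = 0, loadingRange = c(1, 1), negLoadingFrac = 0,
                     baselineRange = c(8, 10), delta = 0)
    sim <- simulateStudy(cfg, seed = 3)
    lg <- exprValues(logTransform(sim$tpm))
    genes <- names(sim$truth$membership)[sim$truth$membership == "M01"]
    cors <- cor(t(lg[genes[1:10], ]))
    expect_true(all(cors > 0.999))
})

test_that("a planted shift appears as the stated mean log2 difference", {
    # module genes are a small transcriptome fraction so the constant-sum
    # TPM rescaling does not distort the planted contrast
    cfg <- simConfig(layout = data.frame(strain = c("B6", "Clu"),
                                         batch = "batch1", n = c(10L, 10L)),
                     nGenes = 3000, nModules = 1, moduleSize = 40,
                     noiseSD = 0, loadingRange = c(1, 1), negLoadingFrac = 0,
                     baselineRange = c(6, 10), delta = 1,
                     driverStrains = "Clu")
    sim <- simulateStudy(cfg, seed = 4)
    lg <- exprValues(logTransform(sim$tpm))
    genes <- names(sim$truth$membership)[sim$truth$membership == "M01"]
    d <- rowMeans(lg[genes, sim$design$strain == "Clu"]) -
        rowMeans(lg[genes, sim$design$strain == "B6"])
    # the realized group contrast of the module signal equals delta plus the
    # sampling noise of the shared per-sample signal; the expression contrast
    # must track it exactly (loadings = 1, sigma = 0)
    sdiff <- mean(sim$truth$signal["M01", sim$design$strain == "Clu"]) -
        mean(sim$truth$signal["M01", sim$design$strain == "B6"])
    expect_lt(abs(mean(d) - sdiff), 0.02)
    # averaging the realized contrast over seeds recovers delta = 1
    sdiffs <- vapply(1:10, function(s) {
        tr <- simulateStudy(cfg, seed = s)$truth
        mean(tr$signal["M01", 11:20]) - mean(tr$signal["M01", 1:10])
    }, numeric(1))
    expect_lt(abs(mean(sdiffs) - 1), 0.3)
    expect_equal(unname(sim$truth$beta[genes, "Clu"]), rep(1, length(genes)))
})

test_that("counts approach their means as dispersion vanishes", {
    cfg <- simConfig(layout = data.frame(strain = c("B6", "Clu"),
                                         batch = "batch1", n = 3L),
                     nGenes = 10000, nModules = 1, moduleSize = 50,
                     dispersion = 0)
    sim <- simulateStudy(cfg, seed = 5)
    cnt <- exprValues(sim$counts)
    tpm <- exprValues(sim$tpm)
    # standardized residuals (cnt - mu)/sqrt(mu) behave like unit noise
    mu <- colMeans(cnt) / colMeans(tpm)   # per-sample library scaling
    muMat <- sweep(tpm, 2, mu, `*`)
    z <- (cnt[muMat > 20] - muMat[muMat > 20]) / sqrt(muMat[muMat > 20])
    expect_lt(abs(mean(z)), 0.02)
    expect_lt(abs(sd(z) - 1), 0.05)
})

test_that("the generator is deterministic under a fixed seed", {
    cfg <- simConfig(nGenes = 300, nModules = 2, moduleSize = 30)
    s1 <- simulateStudy(cfg, seed = 11)
    s2 <- simulateStudy(cfg, seed = 11)
    expect_identical(exprValues(s1$tpm), exprValues(s2$tpm))
    expect_identical(exprValues(s1$counts), exprValues(s2$counts))
    expect_identical(s1$human$lfc, s2$human$lfc)
    expect_identical(geneSets(s1$human$catalog), geneSets(s2$human$catalog))
    s3 <- simulateStudy(cfg, seed = 12)
    expect_false(identical(exprValues(s1$tpm), exprValues(s3$tpm)))
})

test_that("the ortholog map has the configured coverage and multi-mappings", {
    cfg <- simConfig(nGenes = 1000, nModules = 2, moduleSize = 50,
                     orthologFrac = 0.9, oneToManyFrac = 0.05)
    sim <- simulateStudy(cfg, seed = 13)
    orth <- sim$human$orthologs
    expect_equal(length(unique(orth$mouse)), 900L)
    nMulti <- sum(table(orth$mouse) == 2L)
    expect_gt(nMulti, 20L)
    expect_lt(nMulti, 70L)
})

test_that("zero contamination with a complete map gives Jaccard 1", {
    cfg <- simConfig(nGenes = 300, nModules = 2, moduleSize = 40,
                     orthologFrac = 1, oneToManyFrac = 0, contamination = 0)
    sim <- simulateStudy(cfg, seed = 14)
    mGenes <- names(sim$truth$membership)[sim$truth$membership == "M01"]
    mapped <- unique(sim$human$orthologs$human[
        sim$human$orthologs$mouse %in% mGenes])
    hm <- geneSets(sim$human$catalog)[[sim$human$humanModuleOf[["M01"]]]]
    expect_equal(jaccardIndex(mapped, hm), 1)
})

test_that("realized log2FC correlation calibrates to the target", {
    # r_target = 0.5 with a 500-gene module: realized correlation against the
    # planted effects within +/- 0.1
    cfg <- simConfig(nGenes = 1500, nModules = 2, moduleSize = c(500, 500),
                     rTarget = c(0.5, 0), driverStrains = c("Clu", "Apoe"))
    devs <- numeric(4); nulls <- numeric(4)
    for (i in 1:4) {
        sim <- simulateStudy(cfg, seed = 20 + i)
        lfc <- setNames(sim$human$lfc$brain, sim$human$lfc$gene)
        orth <- sim$human$orthologs
        one2one <- orth[!duplicated(orth$mouse) &
                        orth$mouse %in% names(which(table(orth$mouse) == 1)), ]
        scoreMod <- function(mod, strain) {
            hm <- geneSets(sim$human$catalog)[[sim$human$humanModuleOf[[mod]]]]
            sub <- one2one[one2one$human %in% hm, ]
            cor(lfc[sub$human], sim$truth$beta[sub$mouse, strain])
        }
        devs[i] <- scoreMod("M01", "Clu")
        nulls[i] <- scoreMod("M02", "Apoe")
    }
    expect_lt(max(abs(devs - 0.5)), 0.1)
    # r_target = 0 modules of >= 200 genes stay near zero
    expect_lt(max(abs(nulls)), 0.1)
})
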