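test_that("Jaccard index matches set-operation oracle on random pairs", {
    expect_equal(jaccardIndex(c("A", "B", "C"), c("B", "C", "D")), 0.5)
    expect_equal(jaccardIndex(c("A", "B"), c("A", "B")), 1)
    expect_equal(jaccardIndex(c("A"), c("B")), 0)
    expect_equal(jaccardIndex(character(), character()), 0)
    set.seed(61)
    pool <- paste0("g", 1:50)
    for (i in 1:1000) {
        a <- sample(pool, sample(0:20, 1))
        b <- sample(pool, sample(0:20, 1))
        expect_identical(jaccardIndex(a, b), jaccardOracle(a, b))
    }
})

test_that("ortholog mapping policies behave as specified", {
    map <- data.frame(
        mouse = c("m1", "m2", "m3", "m3", "m5", "m6"),
        human = c("H1", "H2", "H3a", "H3b", "H5", "H5b"),
        stringsAsFactors = FALSE)
    # m3 has two human partners: kept twice under all_pairs, dropped 1:1
    ap <- suppressMessages(mapOrthologs(c("m1", "m3"), map, "all_pairs"))
    expect_equal(nrow(ap), 3L)
    oo <- suppressMessages(mapOrthologs(c("m1", "m3"), map, "one_to_one"))
    expect_equal(oo$mouse, "m1")
    # strictly one-to-one map: both policies agree
    map11 <- map[c(1, 2, 5), ]
    expect_equal(suppressMessages(mapOrthologs(c("m1", "m2", "m5"), map11, "all_pairs")),
                 suppressMessages(mapOrthologs(c("m1", "m2", "m5"), map11, "one_to_one")))
    # one_to_one is a bijection on the retained genes
    oo2 <- suppressMessages(mapOrthologs(map$mouse, map, "one_to_one"))
    expect_false(anyDuplicated(oo2$mouse) > 0)
    expect_false(anyDuplicated(oo2$human) > 0)
    expect_error(suppressMessages(mapOrthologs("absent", map)), "no genes")
})

test_that("permutation overlap test handles the degenerate cases", {
    universe <- paste0("m", 1:40)
    map <- data.frame(mouse = universe, human = paste0("H", 1:40))
    # human module disjoint from the mapped universe
    r <- permutationOverlapTest(universe[1:10], paste0("X", 1:5), universe,
                                map, nPerm = 200, seed = 1)
    expect_equal(r$jaccard, 0)
    expect_equal(r$p, 1)
    # module = universe: every null draw ties the observation
    r2 <- permutationOverlapTest(universe, paste0("H", 1:10), universe, map,
                                 nPerm = 200, seed = 1)
    expect_equal(r2$p, 1)
})

test_that("a planted overlap reaches the minimum attainable p", {
    set.seed(62)
    universe <- paste0("m", 1:1000)
    map <- data.frame(mouse = universe, human = paste0("H", 1:1000))
    module <- sample(universe, 50)
    human <- paste0("H", match(module, universe))  # exact image of the module
    r <- permutationOverlapTest(module, human, universe, map,
                                nPerm = 1000, seed = 7)
    expect_equal(r$jaccard, 1)
    expect_equal(r$p, 1 / 1001)
    # seed determinism and universe-order invariance
    r2 <- permutationOverlapTest(module, human, universe, map,
                                 nPerm = 500, seed = 11)
    r3 <- permutationOverlapTest(module, human, rev(universe), map,
                                 nPerm = 500, seed = 11)
    expect_identical(r2$p, r3$p)
    expect_identical(r2, permutationOverlapTest(module, human, universe, map,
                                                nPerm = 500, seed = 11))
})

test_that("perturbation regression equals group-mean differences", {
    meta <- makeMeta(c("B6", "Clu", "Apoe"), reps = 3)
    m <- matrix(0, 2, 9, dimnames = list(c("g1", "g2"), meta$sample))
    m["g1", ] <- rep(c(1, 2, 0.5), each = 3)   # noise free
    m["g2", ] <- 4                              # constant everywhere
    ee <- ExpressionExperiment(m, meta = meta, scale = "log2tpm")
    fit <- fitPerturbationModel(ee)
    expect_equal(fit$beta["g1", "Clu"], 1.0, tolerance = 1e-12)
    expect_equal(fit$beta["g1", "Apoe"], -0.5, tolerance = 1e-12)
    expect_equal(unname(fit$beta["g2", ]), c(0, 0), tolerance = 1e-12)
    expect_equal(unname(fit$intercept["g1"]), 1.0, tolerance = 1e-12)
    # noisy recovery: mean absolute error well under the planted scale
    set.seed(63)
    meta6 <- makeMeta(c("B6", "Clu"), reps = 6)
    beta <- matrix(rep(c(0.5, 1), each = 250), 500, 1,
                   dimnames = list(sprintf("Gene%03d", 1:500), "Clu"))
    ee6 <- simPerturbedLogExpression(meta6, beta, sigma = 0.3, seed = 64)
    fit6 <- fitPerturbationModel(ee6)
    expect_lt(mean(abs(fit6$beta[, "Clu"] - beta[, "Clu"])), 0.15)
})

test_that("rank-deficient designs are rejected with the column named", {
    meta <- makeMeta(c("B6", "Clu"), reps = 4)
    meta$batch <- ifelse(meta$strain == "Clu", "b2", "b1")  # confounded
    set.seed(65)
    m <- matrix(rnorm(40, 5), 5, 8,
                dimnames = list(paste0("g", 1:5), meta$sample))
    ee <- ExpressionExperiment(m, meta = meta, scale = "log2tpm")
    expect_error(fitPerturbationModel(ee, withBatch = TRUE), "collinear")
})

test_that("module concordance recovers the planted correlation", {
    cfg <- simConfig(nGenes = 1200, nModules = 2, moduleSize = c(500, 200),
                     rTarget = c(0.5, 0), driverStrains = c("Clu", "Apoe"))
    rs <- numeric(3)
    nullPadj <- numeric(3)
    for (i in 1:3) {
        sim <- simulateStudy(cfg, seed = 70 + i)
        corrected <- suppressMessages(preprocess(sim$tpm))
        fit <- fitPerturbationModel(corrected)
        cc <- suppressMessages(concordanceAnalysis(
            fit, sim$human$lfc, sim$human$catalog, sim$human$orthologs))
        rs[i] <- cc$r[cc$strain == "Clu" & cc$humanModule == "HM1"]
        nullPadj[i] <- cc$padj[cc$strain == "Apoe" & cc$humanModule == "HM2"]
    }
    expect_lt(abs(mean(rs) - 0.5), 0.15)
    expect_gt(mean(nullPadj > 0.05), 0.5)
})

test_that("negating planted effects flips the estimated correlation exactly", {
    set.seed(66)
    meta <- makeMeta(c("B6", "Clu"), reps = 6)
    genes <- sprintf("Gene%03d", 1:100)
    beta <- matrix(rnorm(100), 100, 1, dimnames = list(genes, "Clu"))
    map <- data.frame(mouse = genes, human = paste0("H", genes))
    lfc <- setNames(rnorm(100) + beta[, 1], paste0("H", genes))
    ee <- simPerturbedLogExpression(meta, beta, sigma = 0.2, seed = 67)
    fit <- fitPerturbationModel(ee)
    r1 <- moduleConcordance(fit, lfc, paste0("H", genes), map, "Clu")
    # negating all fitted effects flips the estimated correlation exactly
    fitNeg <- fit
    fitNeg$beta <- -fit$beta
    r2 <- moduleConcordance(fitNeg, lfc, paste0("H", genes), map, "Clu")
    expect_equal(r2$r, -r1$r, tolerance = 1e-12)
    expect_equal(r2$p, r1$p, tolerance = 1e-12)
    # degenerate: zero-variance effects are untestable, not an error
    fitZero <- fit
    fitZero$beta[, "Clu"] <- 0
    r3 <- moduleConcordance(fitZero, lfc, paste0("H", genes), map, "Clu")
    expect_identical(r3$status, "untestable")
})
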