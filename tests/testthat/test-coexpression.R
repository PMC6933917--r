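test_that("unsigned adjacency has the stated limiting cases", {
    set.seed(31)
    x <- rnorm(10)
    m <- rbind(g1 = x, g2 = 2 * x + 3, g3 = rnorm(10))
    colnames(m) <- paste0("s", 1:10)
    net <- computeAdjacency(m, power = 6)
    a <- adjacency(net)
    expect_equal(a["g1", "g2"], 1, tolerance = 1e-12)
    expect_equal(diag(a), c(g1 = 1, g2 = 1, g3 = 1))
    # power = 1 reduces to |correlation|
    net1 <- computeAdjacency(m, power = 1)
    expect_equal(adjacency(net1)["g1", "g3"], abs(cor(x, m["g3", ])),
                 tolerance = 1e-12)
    # exactly orthogonal genes give adjacency 0
    m2 <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1))
    colnames(m2) <- paste0("s", 1:4)
    expect_equal(adjacency(computeAdjacency(m2, power = 8))["g1", "g2"], 0)
    # zero-variance gene is an error naming the gene
    m3 <- rbind(g1 = rnorm(5), flat = rep(2, 5))
    colnames(m3) <- paste0("s", 1:5)
    expect_error(computeAdjacency(m3), "flat")
})

test_that("TOM matches the formula example and the O(n^3) oracle exactly", {
    a <- matrix(c(1, 0.8, 0.6, 0.8, 1, 0.4, 0.6, 0.4, 1), 3,
                dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
    net <- new("CoexpressionNetwork", adjacency = a, power = 1)
    tom <- computeTOM(net)
    expect_equal(tom["g1", "g2"], (0.6 * 0.4 + 0.8) / (min(1.4, 1.2) + 1 - 0.8),
                 tolerance = 1e-12)
    # identity adjacency: no shared neighbours, no direct links
    id <- diag(3)
    dimnames(id) <- dimnames(a)
    tomId <- computeTOM(new("CoexpressionNetwork", adjacency = id, power = 1))
    expect_true(all(tomId[upper.tri(tomId)] == 0))
    # exact agreement with a brute-force triple loop on random networks
    set.seed(32)
    for (i in 1:10) {
        n <- 20
        r <- matrix(runif(n * n), n)
        a <- (r + t(r)) / 2
        diag(a) <- 1
        dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
        net <- new("CoexpressionNetwork", adjacency = a, power = 1)
        tom <- computeTOM(net)
        expect_equal(tom, tomOracle(a), tolerance = 1e-12, ignore_attr = TRUE)
        expect_true(all(tom >= 0 & tom <= 1))
        expect_equal(tom, t(tom))
    }
})

test_that("clustering recovers clean planted blocks and applies the size rule", {
    # two planted 50-gene blocks, within-block correlation ~0.8, plus noise
    set.seed(33)
    nS <- 40
    f1 <- rnorm(nS); f2 <- rnorm(nS)
    mk <- function(f, n, rho) t(sapply(seq_len(n), function(i)
        sqrt(rho) * f + sqrt(1 - rho) * rnorm(nS)))
    m <- rbind(mk(f1, 50, 0.8), mk(f2, 50, 0.8))
    rownames(m) <- paste0("g", 1:100)
    colnames(m) <- paste0("s", 1:nS)
    tom <- computeTOM(computeAdjacency(m, power = 6))
    cut <- clusterAndCut(tomDissimilarity(tom), minSize = 30)
    truth <- rep(c(1, 2), each = 50)
    expect_equal(length(setdiff(unique(cut$labels), "grey")), 2L)
    expect_equal(mclust::adjustedRandIndex(cut$labels, truth), 1)
    # deterministic labels across runs
    cut2 <- clusterAndCut(tomDissimilarity(tom), minSize = 30)
    expect_identical(cut$labels, cut2$labels)
    # a 29-gene isolated block stays grey at minimum size 30 while larger
    # blocks in the same data become modules
    f3 <- rnorm(nS)
    m29 <- rbind(mk(f3, 29, 0.9), mk(f1, 35, 0.8), mk(f2, 35, 0.8))
    rownames(m29) <- paste0("g", 1:99)
    colnames(m29) <- paste0("s", 1:nS)
    tom29 <- computeTOM(computeAdjacency(m29, power = 6))
    cut29 <- suppressWarnings(clusterAndCut(tomDissimilarity(tom29),
                                            minSize = 30))
    expect_true(all(cut29$labels[1:29] == "grey"))
    expect_equal(length(setdiff(unique(cut29$labels), "grey")), 2L)
})

test_that("eigengenes are unit variance, oriented, and order invariant", {
    set.seed(34)
    nS <- 20
    f <- rnorm(nS)
    m <- rbind(t(sapply(1:10, function(i) 2 * f + rnorm(nS, sd = 0.01))),
               t(sapply(1:5, function(i) rnorm(nS))))
    rownames(m) <- paste0("g", 1:15)
    colnames(m) <- paste0("s", 1:nS)
    labels <- setNames(c(rep("blue", 10), rep("grey", 5)), rownames(m))
    eg <- computeEigengenes(m, labels)
    me <- eg$eigengenes["blue", ]
    expect_equal(sd(me), 1, tolerance = 1e-10)
    # near-identical members: eigengene correlates ~1 with each, ve ~ 1
    expect_true(all(cor(me, t(m[1:10, ])) > 0.999))
    expect_gt(eg$varExplained[["blue"]], 0.999)
    # invariance under gene reordering
    perm <- sample(15)
    eg2 <- computeEigengenes(m[perm, ], labels[perm])
    expect_equal(eg2$eigengenes["blue", ], me, tolerance = 1e-10)
    # singleton module equals the standardized gene
    labels2 <- setNames(c("blue", rep("grey", 14)), rownames(m))
    eg3 <- computeEigengenes(m, labels2)
    z <- as.numeric(scale(m[1, ]))
    expect_equal(unname(eg3$eigengenes["blue", ]), z * sign(cor(z, m[1, ])),
                 tolerance = 1e-10)
})

test_that("module merging follows the eigengene dissimilarity rule", {
    set.seed(35)
    nS <- 30
    f <- rnorm(nS)
    # two modules sharing one driver signal -> eigengene correlation ~ 0.9
    m1 <- t(sapply(1:20, function(i) f + rnorm(nS, sd = 0.3)))
    m2 <- t(sapply(1:15, function(i) f + rnorm(nS, sd = 0.3)))
    indep <- t(sapply(1:20, function(i) rnorm(nS)))
    m <- rbind(m1, m2, indep)
    rownames(m) <- paste0("g", seq_len(nrow(m)))
    colnames(m) <- paste0("s", 1:nS)
    labels <- setNames(c(rep("blue", 20), rep("red", 15), rep("green", 20)),
                       rownames(m))
    merged <- suppressMessages(mergeCloseModules(m, labels, mergeHeight = 0.25))
    expect_true(all(merged$labels[1:35] == "blue"))
    expect_true(all(merged$labels[36:55] == "green"))
    # modules on independent signals stay apart at the same threshold
    g <- rnorm(nS)
    mInd <- rbind(t(sapply(1:20, function(i) f + rnorm(nS, sd = 0.3))),
                  t(sapply(1:15, function(i) g + rnorm(nS, sd = 0.3))))
    rownames(mInd) <- paste0("g", seq_len(nrow(mInd)))
    colnames(mInd) <- paste0("s", 1:nS)
    labInd <- setNames(c(rep("blue", 20), rep("red", 15)), rownames(mInd))
    merged2 <- mergeCloseModules(mInd, labInd, mergeHeight = 0.25)
    expect_identical(merged2$labels, labInd)
})

test_that("soft-threshold selection finds a scale-free fit on hub-like data", {
    set.seed(36)
    nG <- 300; nS <- 60
    f <- rnorm(nS)
    rho <- runif(nG)^1.5       # heavy spread of hub strengths
    m <- t(sapply(seq_len(nG), function(i)
        rho[i] * f + sqrt(1 - rho[i]^2) * rnorm(nS)))
    rownames(m) <- paste0("g", 1:nG)
    colnames(m) <- paste0("s", 1:nS)
    sel <- pickSoftThreshold(m, powers = 1:12, r2Target = 0.8)
    best <- sel$fitTable[sel$fitTable$power == sel$power, ]
    expect_gte(best$signedR2, 0.8)
    expect_lt(best$slope, 0)
    # fit table reproducible under sample permutation
    sel2 <- pickSoftThreshold(m[, sample(nS)], powers = 1:12, r2Target = 0.8)
    expect_equal(sel2$fitTable$signedR2, sel$fitTable$signedR2,
                 tolerance = 1e-10)
})

test_that("full module detection is invariant to gene and sample permutation", {
    cfg <- simConfig(nGenes = 250, nModules = 3, moduleSize = 40,
                     layout = data.frame(strain = c("B6", "Clu"),
                                         batch = "b1", n = c(10L, 10L)))
    sim <- simulateStudy(cfg, seed = 9)
    m <- exprValues(logTransform(sim$tpm))
    ms1 <- suppressMessages(suppressWarnings(detectModules(m, power = 6,
        minSize = 30)))
    perm <- sample(nrow(m)); permS <- sample(ncol(m))
    ms2 <- suppressMessages(suppressWarnings(detectModules(
        m[perm, permS], power = 6, minSize = 30)))
    l1 <- moduleLabels(ms1)
    l2 <- moduleLabels(ms2)[names(l1)]
    expect_equal(mclust::adjustedRandIndex(l1, l2), 1)
})
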