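test_that("Fisher's ratio follows the defining formula", {
    # class 1: mean 1, var 1; class 2: mean 3, var 1 -> FR = 4/2 = 2
    v <- rbind(g1 = c(0, 1, 2, 2, 3, 4),
               g2 = c(5, 5, 5, 5, 5, 5),    # identical in both classes
               g3 = c(1, 1, 1, 9, 9, 9))    # zero variance, split means
    pe <- peFromMatrix(v, c(1, 1, 1, 2, 2, 2))
    st <- computeGeneStatistics(pe)
    expect_equal(st["g1", "fisherRatio"], 2)
    expect_equal(st["g1", "foldChange"], -2)
    expect_equal(st["g2", "fisherRatio"], 0)
    expect_identical(st["g3", "fisherRatio"], Inf)
})

test_that("Fisher's ratio is symmetric under label swap", {
    set.seed(3)
    v <- matrix(rnorm(80), 8, 10)
    labels <- rep(c(1L, 2L), each = 5L)
    a <- computeGeneStatistics(peFromMatrix(v, labels))
    b <- computeGeneStatistics(peFromMatrix(v, 3L - labels))
    expect_equal(a$fisherRatio, b$fisherRatio)
    expect_equal(a$foldChange, -b$foldChange)
})

test_that("statistics match a direct-formula oracle to 1e-12", {
    set.seed(17)
    v <- matrix(rnorm(200, sd = 2), 20, 10)
    labels <- rep(c(1L, 2L), each = 5L)
    st <- computeGeneStatistics(peFromMatrix(v, labels))
    orc <- oracleGeneStats(v, labels)
    expect_equal(st$mu1, unname(orc[, "mu1"]), tolerance = 1e-12)
    expect_equal(st$var1, unname(orc[, "var1"]), tolerance = 1e-12)
    expect_equal(st$var2, unname(orc[, "var2"]), tolerance = 1e-12)
    expect_equal(st$fisherRatio, unname(orc[, "fr"]), tolerance = 1e-12)
})

test_that("a class with fewer than two samples is rejected", {
    v <- matrix(rnorm(9), 3, 3,
                dimnames = list(letters[1:3], paste0("s", 1:3)))
    pe <- PhenotypeExperiment(v, c(1, 2, 2))
    expect_error(computeGeneStatistics(pe), "at least two samples")
})

test_that("the Fisher's-ratio cutoff is strict and matches the
           0.89-pooled-sd separation rule", {
    # engineered gene with FR exactly 0.8: per-class variance 2.5 each,
    # mean separation 2 -> FR = 4/5
    cls <- c(-2, -1, 0, 1, 2)
    v <- rbind(border = c(cls, cls + 2),
               strong = c(cls, cls + 10))
    pe <- peFromMatrix(v, rep(c(1L, 2L), each = 5L))
    st <- computeGeneStatistics(pe)
    expect_identical(st["border", "fisherRatio"], 0.8)
    cfg <- samplerConfig(survivorFloor = 0)   # disable relaxation
    rk <- filterAndRank(st, cfg)
    expect_identical(rk@probeIds, "strong")   # FR == 0.8 excluded

    # filter decisions equal the mean-separation rule to rounding
    set.seed(21)
    v <- matrix(rnorm(3000), 300, 10)
    v[1:150, 6:10] <- v[1:150, 6:10] + runif(150, 0, 2.5)
    pe <- peFromMatrix(v, rep(c(1L, 2L), each = 5L))
    st <- computeGeneStatistics(pe)
    rk <- suppressMessages(filterAndRank(st, samplerConfig(
        foldChangeThreshold = 0, survivorFloor = 0)))
    sep <- abs(st$mu1 - st$mu2) / sqrt(st$var1 + st$var2)
    kept <- rownames(st) %in% rk@probeIds
    expect_true(all(sep[kept] > 0.89))
    expect_true(all(sep[!kept] < 0.895))
})

test_that("ranking is by descending FR with documented tie-breaks", {
    sim <- simulateExpressionData(nGenes = 60, samplesPerClass = c(10, 10),
                                  nPlanted = 6, effectSize = 3, seed = 2)
    st <- computeGeneStatistics(sim$experiment)
    rk <- suppressMessages(filterAndRank(st, samplerConfig()))
    expect_true(all(diff(rk@fisherRatio) <= 1e-12))
    expect_identical(rk@fisherRatio,
                     unname(st$fisherRatio[rk@geneIndices]))
})

test_that("the cutoff relaxes to the fallback when survivors are scarce", {
    # genes with FR between 0.5 and 0.8 only
    set.seed(8)
    n <- 30
    shift <- sqrt(2 * 0.65)              # FR ~ 0.65 at unit variances
    v <- rbind(matrix(rnorm(5 * n), 5, n))
    v[, 16:30] <- v[, 16:30] + shift
    pe <- peFromMatrix(v, rep(c(1L, 2L), each = 15L))
    st <- computeGeneStatistics(pe)
    cfg <- samplerConfig(foldChangeThreshold = 0)
    expect_message(rk <- filterAndRank(st, cfg), "relaxing")
    expect_true(rk@relaxed)
    expect_identical(rk@frCutoff, 0.5)
    expect_true(all(rk@fisherRatio > 0.5))

    expect_error(
        filterAndRank(st, samplerConfig(foldChangeThreshold = 50)),
        "no gene passes")
})

test_that("planted discriminatory genes are exactly the filter survivors", {
    sim <- simulateExpressionData(seed = 4)
    st <- computeGeneStatistics(sim$experiment)
    rk <- filterAndRank(st, samplerConfig())
    expect_setequal(rk@geneIndices, sim$planted)
})
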