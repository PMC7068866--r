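rankedFixture <- function(fr, fc = NULL, probeIds = NULL) {
    n <- length(fr)
    if (is.null(fc)) fc <- rep(2, n)
    if (is.null(probeIds)) probeIds <- sprintf("p%02d", seq_len(n))
    new("RankedGenes", geneIndices = seq_len(n), probeIds = probeIds,
        fisherRatio = as.numeric(fr), foldChange = as.numeric(fc),
        foldChangeThreshold = 1, frCutoff = 0.8, relaxed = FALSE)
}

test_that("prior weights are proportional to Fisher's ratio", {
    rk <- rankedFixture(c(3, 1))
    pr <- buildFisherPrior(rk, config = samplerConfig(frMinHeader = 0))
    expect_equal(pr@headerWeights, c(0.75, 0.25))
    expect_identical(pr@helperIndices, integer(0))

    # equal ratios degenerate to a uniform prior
    pr <- buildFisherPrior(rankedFixture(rep(2, 5)),
                           config = samplerConfig(frMinHeader = 0))
    expect_equal(pr@headerWeights, rep(0.2, 5))

    expect_error(
        buildFisherPrior(rankedFixture(c(3, 1)),
                         config = samplerConfig(frMinHeader = 10)),
        "header pool is empty")
})

test_that("automatic frMin puts the minimum-scale genes in the header pool", {
    sim <- simulateExpressionData(seed = 4)
    cfg <- samplerConfig()
    fit <- fitDiscriminatoryGenes(sim$experiment, cfg, quiet = TRUE)
    pr <- buildFisherPrior(fit$ranked, fit$mss, cfg)
    expect_true(all(geneIndices(fit$mss) %in% pr@headerIndices))
    expect_identical(sort(c(pr@headerIndices, pr@helperIndices)),
                     sort(geneIndices(fit$ranked)))
})

test_that("inverse-cdf draw frequencies match the analytic weights", {
    set.seed(123)
    fr <- sort(runif(20, 0.9, 6), decreasing = TRUE)
    pr <- buildFisherPrior(rankedFixture(fr),
                           config = samplerConfig(frMinHeader = 0))
    draws <- samplePriorGenes(pr, 2e4, "header")
    counts <- tabulate(draws, nbins = 20)
    p <- suppressWarnings(
        chisq.test(counts, p = pr@headerWeights)$p.value)
    expect_gt(p, 0.01)
})

test_that("sampled networks honour bounds, contain a header, and are
           reproducible", {
    fr <- c(5, 4, 3, 1, 0.9, 0.85)
    pr <- buildFisherPrior(rankedFixture(fr),
                           config = samplerConfig(frMinHeader = 2))
    set.seed(1)
    nets <- replicate(200, sampleNetwork(pr, c(1L, 5L)), simplify = FALSE)
    lens <- lengths(nets)
    expect_true(all(lens >= 1L & lens <= 5L))
    expect_true(all(vapply(nets, function(s)
        any(s %in% pr@headerIndices), logical(1))))
    expect_true(all(vapply(nets, anyDuplicated, integer(1)) == 0L))
    set.seed(1)
    nets2 <- replicate(200, sampleNetwork(pr, c(1L, 5L)), simplify = FALSE)
    expect_identical(nets, nets2)

    expect_error(sampleNetwork(pr, c(1L, 7L)), "infeasible")
    expect_error(sampleNetwork(pr, c(0L, 3L)), "infeasible")
})

test_that("gene draw frequency is monotone in FR within the header pool", {
    set.seed(2)
    fr <- c(8, 4, 2, 1)
    pr <- buildFisherPrior(rankedFixture(fr),
                           config = samplerConfig(frMinHeader = 0))
    draws <- samplePriorGenes(pr, 2e4, "header")
    counts <- tabulate(draws, nbins = 4)
    expect_true(all(diff(counts) < 0))
})

test_that("retention follows the threshold semantics", {
    sim <- simulateExpressionData(nGenes = 200, samplesPerClass = c(15, 15),
                                  nPlanted = 5, effectSize = 3, seed = 3)
    cfg <- samplerConfig(nSamples = 300, accuracyThreshold = 0, seed = 3)
    fit <- fitDiscriminatoryGenes(sim$experiment, cfg, quiet = TRUE)
    res <- runFisherSampler(sim$experiment, fit$ranked, fit$mss, cfg)
    expect_identical(length(signatures(res)), 300L)

    # every retained network on planted data holds >= 1 planted gene
    cfg85 <- samplerConfig(nSamples = 300, seed = 3)
    res85 <- runFisherSampler(sim$experiment, fit$ranked, fit$mss, cfg85)
    expect_true(all(vapply(signatures(res85), function(s)
        any(s %in% sim$planted), logical(1))))
    expect_true(all(accuracy(res85) > 85))

    # an unreachable threshold on noise yields a warning, not an error
    simN <- simulateExpressionData(nGenes = 100,
                                   samplesPerClass = c(10, 10),
                                   nPlanted = 2, effectSize = 0.5,
                                   seed = 8)
    cfgN <- samplerConfig(foldChangeThreshold = 0, frCutoff = 0.05,
                          survivorFloor = 0, accuracyThreshold = 100,
                          nSamples = 100, seed = 8)
    fitN <- fitDiscriminatoryGenes(simN$experiment, cfgN, quiet = TRUE)
    expect_warning(
        resN <- runFisherSampler(simN$experiment, fitN$ranked, fitN$mss,
                                 cfgN),
        "no network")
    expect_identical(length(signatures(resN)), 0L)
})

test_that("the sampler run is reproducible under its seed", {
    sim <- simulateExpressionData(nGenes = 150, samplesPerClass = c(12, 12),
                                  nPlanted = 5, effectSize = 3, seed = 5)
    cfg <- samplerConfig(nSamples = 200, seed = 11)
    fit <- fitDiscriminatoryGenes(sim$experiment, cfg, quiet = TRUE)
    a <- runFisherSampler(sim$experiment, fit$ranked, fit$mss, cfg)
    b <- runFisherSampler(sim$experiment, fit$ranked, fit$mss, cfg)
    expect_identical(signatures(a), signatures(b))
    expect_identical(accuracy(a), accuracy(b))
    expect_identical(drawCounts(a), drawCounts(b))
})

test_that("header genes dominate helper genes in the posterior", {
    sim <- simulateExpressionData(seed = 6)
    cfg <- samplerConfig(nSamples = 1500, seed = 6)
    fit <- fitDiscriminatoryGenes(sim$experiment, cfg, quiet = TRUE)
    pr <- buildFisherPrior(fit$ranked, fit$mss, cfg)
    res <- runFisherSampler(sim$experiment, fit$ranked, fit$mss, cfg)
    tab <- geneFrequencies(res)
    freqOf <- function(ids) {
        f <- tab$frequency[match(ids, rownames(tab))]
        mean(ifelse(is.na(f), 0, f))
    }
    headerIds <- probeIds(sim$experiment)[pr@headerIndices]
    helperIds <- probeIds(sim$experiment)[pr@helperIndices]
    if (length(helperIds))
        expect_gte(freqOf(headerIds), freqOf(helperIds))
})
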