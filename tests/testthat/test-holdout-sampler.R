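test_that("stratified 75/25 bags have the forced shape on 4+4 samples", {
    v <- matrix(rnorm(40), 5, 8)
    pe <- peFromMatrix(v, rep(c(1L, 2L), each = 4L))
    set.seed(1)
    bags <- makeBags(pe, nBags = 25, fraction = 0.25)
    for (b in bags) {
        expect_identical(length(b$train), 6L)
        expect_identical(length(b$validation), 2L)
        expect_identical(sort(c(b$train, b$validation)), 1:8)
        ph <- phenotypeLabels(pe)
        expect_setequal(ph[b$validation], 1:2)
        expect_setequal(unique(ph[b$train]), 1:2)
    }
    set.seed(1)
    bags2 <- makeBags(pe, nBags = 25, fraction = 0.25)
    expect_identical(bags, bags2)
})

test_that("validation appearances follow the binomial expectation", {
    sim <- simulateExpressionData(nGenes = 10, samplesPerClass = c(20, 20),
                                  nPlanted = 0, seed = 2)
    set.seed(2)
    nBags <- 400
    bags <- makeBags(sim$experiment, nBags = nBags, fraction = 0.25)
    counts <- tabulate(unlist(lapply(bags, `[[`, "validation")),
                       nbins = 40)
    expected <- nBags * 0.25
    tol <- 3 * sqrt(nBags * 0.25 * 0.75)
    expect_true(all(abs(counts - expected) <= tol))
})

test_that("classes too small for both splits are rejected", {
    v <- matrix(rnorm(30), 5, 6,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
    pe <- PhenotypeExperiment(v, c(1, 1, 1, 1, 2, 2))
    expect_error(makeBags(pe, 5, 0.25), "both splits")
})

test_that("holdout signatures never see validation labels", {
    sim <- simulateExpressionData(nGenes = 150, samplesPerClass = c(15, 15),
                                  nPlanted = 5, effectSize = 3, seed = 4)
    x <- sim$experiment
    cfg <- samplerConfig(nBags = 25, accuracyThreshold = 0,
                         stratified = FALSE, seed = 21)
    resA <- suppressWarnings(runHoldoutSampler(x, cfg))

    # flip one sample's label; bags (unstratified) depend only on n + seed
    flip <- 7L
    labels2 <- phenotypeLabels(x)
    labels2[flip] <- 3L - labels2[flip]
    y <- PhenotypeExperiment(exprsMatrix(x), labels2)
    resB <- suppressWarnings(runHoldoutSampler(y, cfg))

    set.seed(21)
    bags <- makeBags(x, cfg@nBags, cfg@holdoutFraction, stratified = FALSE)
    mapA <- split(signatures(resA), resA@extras$bagId)
    mapB <- split(signatures(resB), resB@extras$bagId)
    checked <- 0L
    for (b in bags) {
        id <- as.character(b$bagId)
        if (flip %in% b$validation && !is.null(mapA[[id]]) &&
            !is.null(mapB[[id]])) {
            expect_identical(mapA[[id]], mapB[[id]])
            checked <- checked + 1L
        }
    }
    expect_gt(checked, 0L)
})

test_that("retained validation accuracies all exceed the threshold", {
    sim <- simulateExpressionData(nGenes = 200, samplesPerClass = c(16, 16),
                                  nPlanted = 6, effectSize = 3, seed = 5)
    cfg <- samplerConfig(nBags = 40, seed = 5)
    res <- suppressWarnings(runHoldoutSampler(sim$experiment, cfg))
    expect_true(all(accuracy(res) > 85))
    expect_true(all(vapply(signatures(res), function(s)
        any(s %in% sim$planted), logical(1))))
})

test_that("null data yields chance-level validation accuracy and sparse
           retention", {
    sim <- simulateExpressionData(nGenes = 100, samplesPerClass = c(12, 12),
                                  nPlanted = 0, effectSize = 0, seed = 6)
    cfg <- samplerConfig(foldChangeThreshold = 0, frCutoff = 0.05,
                         survivorFloor = 0, nBags = 40,
                         accuracyThreshold = 0, mssMaxLength = 25L,
                         seed = 6)
    res <- suppressWarnings(runHoldoutSampler(sim$experiment, cfg))
    accs <- res@extras$validationAccuracies
    accs <- accs[!is.na(accs)]
    # majority-class rate is 50%; mean over bags should hover there
    se <- sd(accs) / sqrt(length(accs))
    expect_lt(abs(mean(accs) - 50), 3 * se + 10)

    # at the 85% threshold the same bags retain (almost) nothing
    kept <- sum(accs > 85)
    expect_lte(kept, ceiling(0.05 * length(accs)))
})

test_that("bags with no discriminatory training genes are skipped with a
           warning", {
    # a constant matrix has no differentially expressed genes in any bag
    v <- matrix(5, 20, 16)
    pe <- peFromMatrix(v, rep(c(1L, 2L), each = 8L))
    cfg <- samplerConfig(nBags = 10, seed = 7)
    expect_warning(
        expect_warning(res <- runHoldoutSampler(pe, cfg), "no bag"),
        "skipped")
    expect_identical(length(signatures(res)), 0L)
})
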