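test_that("loader parses a small TSV matrix with labels", {
    dir <- withr::local_tempdir()
    writeLines(c("probe_id\ts1\ts2\ts3\ts4",
                 "gA\t1.5\t2.5\t3.5\t4.5",
                 "gB\t0\t0.1\t0.2\t0.3",
                 "gC\t-1\t-2\t-3\t-4"),
               file.path(dir, "m.tsv"))
    writeLines(c("s1\t1", "s2\t1", "s3\t2", "s4\t2"),
               file.path(dir, "l.tsv"))
    pe <- readExpressionDataset(file.path(dir, "m.tsv"),
                                file.path(dir, "l.tsv"))
    expect_s4_class(pe, "PhenotypeExperiment")
    expect_identical(dim(pe), c(3L, 4L))
    expect_identical(probeIds(pe), c("gA", "gB", "gC"))
    expect_identical(phenotypeLabels(pe), c(1L, 1L, 2L, 2L))
    expect_equal(exprsMatrix(pe)["gA", "s4"], 4.5)
})

test_that("loader rejects invalid inputs with informative errors", {
    dir <- withr::local_tempdir()
    m <- file.path(dir, "m.tsv"); l <- file.path(dir, "l.tsv")
    writeLines(c("probe_id\ts1\ts2\ts3\ts4",
                 "gA\t1\t2\t3\t4",
                 "gA\t5\t6\t7\t8"), m)
    writeLines(c("s1\t1", "s2\t1", "s3\t2", "s4\t2"), l)
    expect_error(readExpressionDataset(m, l), "gA")

    writeLines(c("probe_id\ts1\ts2\ts3\ts4",
                 "gA\t1\t2\t3\t4",
                 "gB\t5\t6\t7\t8"), m)
    writeLines(c("s1\t1", "s2\t1", "s3\t1", "s4\t1"), l)
    expect_error(readExpressionDataset(m, l), "both classes")

    writeLines(c("probe_id\ts1\ts2\ts3\ts4",
                 "gA\t1\t2\toops\t4",
                 "gB\t5\t6\t7\t8"), m)
    writeLines(c("s1\t1", "s2\t1", "s3\t2", "s4\t2"), l)
    expect_error(readExpressionDataset(m, l), "oops.*gA.*s3")

    # labels naming unknown samples are an error; unlabeled samples drop
    writeLines(c("probe_id\ts1\ts2\ts3\ts4",
                 "gA\t1\t2\t3\t4",
                 "gB\t5\t6\t7\t8"), m)
    writeLines(c("s1\t1", "s2\t1", "s3\t2", "s4\t2", "s9\t2"), l)
    expect_error(readExpressionDataset(m, l), "s9")
    writeLines(c("s1\t1", "s2\t1", "s3\t2"), l)
    expect_warning(pe <- readExpressionDataset(m, l), "s4")
    expect_identical(ncol(pe), 3L)

    # missing values rejected by default, imputable on request
    writeLines(c("probe_id\ts1\ts2\ts3\ts4",
                 "gA\t1\t\t3\t4",
                 "gB\t5\t6\t7\t8"), m)
    writeLines(c("s1\t1", "s2\t1", "s3\t2", "s4\t2"), l)
    expect_error(readExpressionDataset(m, l), "missing")
    pe <- readExpressionDataset(m, l, impute = "class-mean")
    expect_equal(exprsMatrix(pe)["gA", "s2"], 1)  # class-1 mean of gA
})

test_that("write/read round trip reproduces values bit-exactly", {
    set.seed(5)
    v <- matrix(rnorm(60) * 10^runif(60, -3, 3), 10, 6)
    pe <- peFromMatrix(v, c(1, 1, 1, 2, 2, 2))
    dir <- withr::local_tempdir()
    writeExpressionDataset(pe, file.path(dir, "m.tsv"),
                           file.path(dir, "l.tsv"))
    back <- readExpressionDataset(file.path(dir, "m.tsv"),
                                  file.path(dir, "l.tsv"))
    expect_identical(exprsMatrix(back), exprsMatrix(pe))
    expect_identical(phenotypeLabels(back), phenotypeLabels(pe))
})

test_that("sample order does not affect downstream statistics", {
    sim <- simulateExpressionData(nGenes = 40, samplesPerClass = c(8, 8),
                                  nPlanted = 4, seed = 9)
    x <- sim$experiment
    perm <- sample(ncol(x))
    y <- PhenotypeExperiment(exprsMatrix(x)[, perm],
                             phenotypeLabels(x)[perm])
    sx <- computeGeneStatistics(x)
    sy <- computeGeneStatistics(y)
    expect_equal(sx$fisherRatio, sy$fisherRatio)
    expect_equal(sx$foldChange, sy$foldChange)
})

test_that("frequency table TSV honours ordering and tie-break contracts", {
    res <- manualResult(list(c(1L, 2L), c(1L, 3L)), probeIds = c("A", "B", "C"))
    tab <- geneFrequencies(res)
    dir <- withr::local_tempdir()
    p <- file.path(dir, "freq.tsv")
    writeFrequencyTable(tab, p)
    got <- read.delim(p)
    expect_identical(got$probe_id, c("A", "B", "C"))
    expect_equal(got$frequency, c(0.5, 0.25, 0.25))
    expect_identical(got$rank, 1:3)
    expect_equal(sum(got$frequency), 1, tolerance = 1e-9)

    # equal frequencies: lexicographic probe order
    res2 <- manualResult(list(1L, 2L), probeIds = c("B", "A"))
    tab2 <- geneFrequencies(res2)
    expect_identical(rownames(tab2), c("A", "B"))

    empty <- new("FrequencyTable",
                 S4Vectors::DataFrame(count = integer(0),
                                      frequency = numeric(0),
                                      rank = integer(0),
                                      row.names = character(0)))
    expect_error(writeFrequencyTable(empty, p), "empty")
})

test_that("PhenotypeExperiment validity catches degenerate objects", {
    v <- matrix(1:8, 2, 4,
                dimnames = list(c("a", "b"), paste0("s", 1:4)))
    expect_error(PhenotypeExperiment(v, c(1, 1, 1, 1)), "both classes")
    expect_error(PhenotypeExperiment(v, c(1, 1, 2, 3)), "coded 1 or 2")
    rownames(v) <- c("a", "a")
    expect_error(PhenotypeExperiment(v, c(1, 1, 2, 2)), "unique")
})
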