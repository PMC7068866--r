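# Independent brute-force oracles and small fixture builders. The oracles
# use plain loops and sqrt-Euclidean distances on purpose: they share no
# code with the package internals they check.

peFromMatrix <- function(values, labels) {
    if (is.null(rownames(values)))
        rownames(values) <- paste0("g", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("s", seq_len(ncol(values)))
    PhenotypeExperiment(values, labels)
}

# predict one query sample from reference columns by brute-force k-NN;
# neighbour ties -> smallest reference index, vote ties -> class 1
oracleKnnPredict <- function(refValues, refLabels, query, k) {
    d <- numeric(ncol(refValues))
    for (j in seq_len(ncol(refValues)))
        d[j] <- sqrt(sum((refValues[, j] - query)^2))
    nn <- order(d)[seq_len(k)]
    if (sum(refLabels[nn] == 1L) >= sum(refLabels[nn] == 2L)) 1L else 2L
}

oracleLoocvAccuracy <- function(values, labels, signature, k = 1L) {
    v <- values[signature, , drop = FALSE]
    n <- length(labels)
    wrong <- 0L
    for (i in seq_len(n)) {
        p <- oracleKnnPredict(v[, -i, drop = FALSE], labels[-i], v[, i], k)
        if (p != labels[i]) wrong <- wrong + 1L
    }
    100 * (n - wrong) / n
}

oracleBlindAccuracy <- function(trainValues, trainLabels, validValues,
                                validLabels, signature, k = 1L) {
    tr <- trainValues[signature, , drop = FALSE]
    va <- validValues[signature, , drop = FALSE]
    wrong <- 0L
    for (i in seq_len(ncol(va))) {
        p <- oracleKnnPredict(tr, trainLabels, va[, i], k)
        if (p != validLabels[i]) wrong <- wrong + 1L
    }
    100 * (ncol(va) - wrong) / ncol(va)
}

# direct-formula per-gene statistics (mean / var / Fisher's ratio)
oracleGeneStats <- function(values, labels) {
    t(apply(values, 1L, function(g) {
        g1 <- g[labels == 1L]; g2 <- g[labels == 2L]
        c(mu1 = mean(g1), mu2 = mean(g2),
          var1 = var(g1), var2 = var(g2),
          fr = (mean(g1) - mean(g2))^2 / (var(g1) + var(g2)))
    }))
}

# a hand-built SamplerResult over probe space A, B, C, ... for posterior
# tests
manualResult <- function(signatures, accuracies = rep(90, length(signatures)),
                         probeIds = LETTERS[1:5], sampler = "RS",
                         threshold = 85) {
    new("SamplerResult", sampler = sampler, signatures = signatures,
        accuracies = accuracies, nSampled = length(signatures),
        accuracyThreshold = threshold, probeIds = probeIds,
        drawCounts = numeric(0), extras = list(), config = list())
}

# dataset with one perfectly separating gene (row 1) plus pure noise
separableDataset <- function(nGenes = 20L, nPerClass = 6L, seed = 42L) {
    set.seed(seed)
    labels <- rep(c(1L, 2L), each = nPerClass)
    v <- matrix(rnorm(nGenes * 2 * nPerClass, sd = 0.3),
                nGenes, 2 * nPerClass)
    v[1L, ] <- ifelse(labels == 1L, 0, 10) + rnorm(2 * nPerClass, sd = 0.1)
    peFromMatrix(v, labels)
}

writeTempDataset <- function(values, labels, dir = withr::local_tempdir(
                                 .local_envir = parent.frame())) {
    pe <- peFromMatrix(values, labels)
    m <- file.path(dir, "expr.tsv")
    l <- file.path(dir, "labels.tsv")
    writeExpressionDataset(pe, m, l)
    list(matrix = m, labels = l)
}
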