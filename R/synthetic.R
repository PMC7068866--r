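#' Simulate a two-class expression dataset with planted signal
#'
#' Generates a Gaussian genes-by-samples expression matrix in which a
#' known subset of genes ("planted" genes) is differentially expressed
#' between the two classes, emulating the shape of a real transcriptomic
#' phenotype-prediction problem (many more genes than samples) at desk
#' scale. Non-planted genes are `Normal(0, noiseSd^2)` in both classes;
#' planted genes' class means differ by `effectSize * noiseSd`, so under
#' this model a planted gene's population Fisher's ratio is analytically
#' `effectSize^2 / 2`.
#'
#' With `correlation = "block"`, the planted genes share a latent
#' per-sample factor (pairwise correlation `blockRho`), so correlated
#' planted genes can substitute for one another inside high-accuracy
#' networks — the equivalent-network phenomenon.
#'
#' @param nGenes total genes. Default 1000.
#' @param samplesPerClass integer(2), samples in class 1 and 2.
#'   Default `c(40, 40)`.
#' @param nPlanted number of planted discriminatory genes. Default 10.
#' @param effectSize class-mean separation in units of `noiseSd`.
#'   Default 3.
#' @param noiseSd within-class standard deviation. Default 1.
#' @param correlation `"independent"` (default) or `"block"`.
#' @param blockRho pairwise correlation of planted genes in block mode.
#' @param seed integer RNG seed; the same seed yields a bit-identical
#'   dataset.
#' @return A list: `experiment` ([PhenotypeExperiment-class]), `planted`
#'   (integer gene indices of the planted genes) and `spec` (the
#'   generating parameters).
#' @examples
#' sim <- simulateExpressionData(seed = 7)
#' sim$experiment
#' @export
simulateExpressionData <- function(nGenes = 1000L,
                                   samplesPerClass = c(40L, 40L),
                                   nPlanted = 10L,
                                   effectSize = 3,
                                   noiseSd = 1,
                                   correlation = c("independent", "block"),
                                   blockRho = 0.5,
                                   seed = 1L) {
    correlation <- match.arg(correlation)
    nGenes <- as.integer(nGenes)
    samplesPerClass <- as.integer(samplesPerClass)
    nPlanted <- as.integer(nPlanted)
    if (nPlanted > nGenes)
        stop("nPlanted may not exceed nGenes")
    if (effectSize < 0 || noiseSd <= 0)
        stop("effectSize must be >= 0 and noiseSd > 0")
    if (length(samplesPerClass) != 2L || any(samplesPerClass < 2L))
        stop("samplesPerClass must give >= 2 samples per class")
    set.seed(as.integer(seed))
    n <- sum(samplesPerClass)
    labels <- rep(c(1L, 2L), samplesPerClass)
    values <- matrix(stats::rnorm(nGenes * n, sd = noiseSd), nGenes, n)
    planted <- sort(sample.int(nGenes, nPlanted))
    if (nPlanted) {
        if (correlation == "block" && blockRho > 0) {
            z <- stats::rnorm(n)
            values[planted, ] <- noiseSd *
                (sqrt(blockRho) * matrix(z, nPlanted, n, byrow = TRUE) +
                 sqrt(1 - blockRho) *
                     matrix(stats::rnorm(nPlanted * n), nPlanted, n))
        }
        shift <- effectSize * noiseSd / 2
        values[planted, labels == 1L] <-
            values[planted, labels == 1L] + shift
        values[planted, labels == 2L] <-
            values[planted, labels == 2L] - shift
    }
    dimnames(values) <- list(
        sprintf("g%0*d", nchar(nGenes), seq_len(nGenes)),
        sprintf("s%0*d", nchar(n), seq_len(n)))
    list(experiment = PhenotypeExperiment(values, labels),
         planted = planted,
         spec = list(nGenes = nGenes, samplesPerClass = samplesPerClass,
                     nPlanted = nPlanted, effectSize = effectSize,
                     noiseSd = noiseSd, correlation = correlation,
                     blockRho = blockRho, seed = as.integer(seed)))
}

#' Fit the discriminatory-gene machinery on one dataset
#'
#' Convenience wrapper running the shared feature-selection chain once:
#' per-gene statistics, fold-change + Fisher's-ratio filtering and the
#' minimum-scale signature search.
#'
#' @param x a [PhenotypeExperiment-class].
#' @param config a [SamplerConfig-class].
#' @param quiet suppress filter-relaxation messages.
#' @return A list with `stats` ([GeneStatistics-class]), `ranked`
#'   ([RankedGenes-class]) and `mss` ([MinimumScaleSignature-class]).
#' @export
fitDiscriminatoryGenes <- function(x, config = samplerConfig(),
                                   quiet = FALSE) {
    st <- computeGeneStatistics(x)
    rk <- filterAndRank(st, config, quiet = quiet)
    mss <- minimumScaleSignature(x, rk, config)
    list(stats = st, ranked = rk, mss = mss)
}

#' Planted-gene recovery experiment
#'
#' The parameter-recovery harness: generates a synthetic dataset, runs one
#' sampler end to end (feature selection, sampling, posterior frequency
#' analysis) and reports how well the top-`nPlanted` frequency ranks
#' recover the planted genes.
#'
#' @param sim a simulation from [simulateExpressionData()], or `NULL` to
#'   generate one from `...`.
#' @param sampler `"frs"`, `"holdout"` or `"random"`.
#' @param config a [SamplerConfig-class] controlling the sampler run.
#' @param ... passed to [simulateExpressionData()] when `sim` is `NULL`.
#' @return A list: `recall` and `precision` of the planted genes within
#'   the top-`nPlanted` frequency ranks, `topGenes`, `nRetained`,
#'   `meanRetainedAccuracy`, the frequency `table` and the sampler
#'   `result`.
#' @export
recoveryExperiment <- function(sim = NULL,
                               sampler = c("frs", "holdout", "random"),
                               config = samplerConfig(), ...) {
    sampler <- match.arg(sampler)
    if (is.null(sim))
        sim <- simulateExpressionData(...)
    x <- sim$experiment
    result <- if (sampler == "holdout") {
        runHoldoutSampler(x, config)
    } else {
        fit <- fitDiscriminatoryGenes(x, config, quiet = TRUE)
        if (sampler == "frs")
            runFisherSampler(x, fit$ranked, fit$mss, config)
        else
            runRandomSampler(x, fit$ranked, fit$mss, config)
    }
    tab <- geneFrequencies(result)
    nP <- length(sim$planted)
    top <- rownames(tab)[seq_len(min(nP, nrow(tab)))]
    plantedIds <- probeIds(x)[sim$planted]
    hit <- length(intersect(top, plantedIds))
    list(recall = hit / nP,
         precision = if (length(top)) hit / length(top) else 0,
         topGenes = top,
         nRetained = length(signatures(result)),
         meanRetainedAccuracy = mean(accuracy(result)),
         table = tab,
         result = result)
}
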