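#' Build the Fisher's-ratio sampling prior
#'
#' Splits the ranked discriminatory genes into header genes (the genes
#' that carry the main discriminative power of the phenotype) and helper
#' genes (the genes that add high-frequency detail), and attaches to each
#' pool selection weights proportional to the genes' Fisher's ratios,
#' normalised within the pool. By default (`frMinHeader = NA`) the split
#' point is the Fisher's ratio of the last minimum-scale-signature gene,
#' so the header pool is (at least) the minimum-scale genes; an explicit
#' `frMinHeader` keeps genes with `FR > frMinHeader` as headers.
#'
#' Genes with infinite Fisher's ratio (zero pooled variance, different
#' means) share the pool's weight uniformly among themselves.
#'
#' @param ranked a non-empty [RankedGenes-class].
#' @param mss the [MinimumScaleSignature-class]; required when
#'   `frMinHeader` is automatic.
#' @param config a [SamplerConfig-class].
#' @return A [FisherPrior-class].
#' @export
buildFisherPrior <- function(ranked, mss = NULL, config = samplerConfig()) {
    stopifnot(is(ranked, "RankedGenes"))
    if (!length(ranked))
        stop("ranked gene list is empty")
    fr <- ranked@fisherRatio
    if (is.na(config@frMinHeader)) {
        if (is.null(mss))
            stop("automatic frMinHeader needs a minimum-scale signature")
        frMin <- min(fr[seq_len(min(length(mss), length(ranked)))])
        isHeader <- fr >= frMin - 1e-12
    } else {
        frMin <- config@frMinHeader
        isHeader <- fr > frMin
    }
    if (!any(isHeader))
        stop("header pool is empty; lower frMinHeader")
    new("FisherPrior",
        headerIndices = ranked@geneIndices[isHeader],
        helperIndices = ranked@geneIndices[!isHeader],
        headerWeights = .frWeights(fr[isHeader]),
        helperWeights = .frWeights(fr[!isHeader]),
        frMin = frMin)
}

# normalised FR-proportional weights; Inf shares the mass uniformly
.frWeights <- function(fr) {
    if (!length(fr)) return(numeric(0))
    w <- if (any(is.infinite(fr))) as.numeric(is.infinite(fr))
         else if (all(fr <= 0)) rep(1, length(fr))
         else fr
    w / sum(w)
}

#' Inverse-cdf draws from one pool of a Fisher prior
#'
#' Draws `n` genes independently (with replacement) from the header or
#' helper pool via the pool's empirical cumulative distribution; each gene
#' is selected with probability equal to its normalised Fisher's-ratio
#' weight. This is the elementary draw the network sampler composes (with
#' rejection of duplicates) and the one whose frequencies are directly
#' checkable against the analytic weights.
#'
#' @param prior a [FisherPrior-class].
#' @param n number of draws.
#' @param pool `"header"` or `"helper"`.
#' @return Integer vector of dataset gene indices, length `n`.
#' @export
samplePriorGenes <- function(prior, n, pool = c("header", "helper")) {
    stopifnot(is(prior, "FisherPrior"))
    pool <- match.arg(pool)
    idx <- if (pool == "header") prior@headerIndices else
        prior@helperIndices
    w <- if (pool == "header") prior@headerWeights else prior@helperWeights
    if (!length(idx))
        stop("the ", pool, " pool is empty")
    u <- stats::runif(n)
    idx[findInterval(u, cumsum(w), left.open = TRUE) + 1L]
}

#' Draw one genetic network from a Fisher prior
#'
#' Draws a network length uniformly within `lengthBounds`, a header count
#' uniformly in `1..min(length, header pool)` (every network contains at
#' least one header gene, since helpers alone cannot discriminate), and
#' fills the network by Fisher's-ratio-weighted draws without replacement
#' from each pool (inverse-cdf draws, duplicates rejected). If the helper
#' pool cannot supply the remainder, the deficit is filled from the header
#' pool.
#'
#' Uses the current RNG state; seed via `set.seed()` or the samplers'
#' `config@seed` for reproducibility.
#'
#' @param prior a [FisherPrior-class].
#' @param lengthBounds integer(2), inclusive bounds on the network length;
#'   the upper bound may not exceed the total pool size.
#' @return Integer vector of distinct dataset gene indices.
#' @export
sampleNetwork <- function(prior, lengthBounds) {
    stopifnot(is(prior, "FisherPrior"))
    nHead <- length(prior@headerIndices)
    nHelp <- length(prior@helperIndices)
    lo <- as.integer(lengthBounds[1L]); hi <- as.integer(lengthBounds[2L])
    if (lo < 1L || hi < lo || hi > nHead + nHelp)
        stop("infeasible length bounds")
    len <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
    hMax <- min(len, nHead)
    h <- if (hMax > 1L) sample.int(hMax, 1L) else 1L
    e <- min(len - h, nHelp)
    h <- len - e                        # refill from headers if helpers short
    picks <- .weightedNoReplace(prior@headerIndices, prior@headerWeights, h)
    if (e > 0L)
        picks <- c(picks,
                   .weightedNoReplace(prior@helperIndices,
                                      prior@helperWeights, e))
    picks
}

# successive renormalised weighted draws == inverse-cdf with duplicate
# rejection
.weightedNoReplace <- function(idx, w, n) {
    if (n == length(idx)) return(idx)
    idx[sample.int(length(idx), n, replace = FALSE, prob = w)]
}

#' Run the Fisher's-ratio sampler
#'
#' Draws `config@nSamples` genetic networks from the Fisher's-ratio prior
#' (see [sampleNetwork()]), scores each by LOOCV k-NN accuracy on the full
#' dataset, and retains the networks whose accuracy exceeds
#' `config@accuracyThreshold` (a threshold of 0 retains everything). The
#' network length is drawn uniformly in `config@lengthBounds`, by default
#' `[1, length(mss)]` — the minimum-scale signature estimates the length
#' scale of the high-accuracy networks.
#'
#' @param x a [PhenotypeExperiment-class].
#' @param ranked the [RankedGenes-class] of discriminatory genes.
#' @param mss the dataset's [MinimumScaleSignature-class].
#' @param config a [SamplerConfig-class]; `seed` makes the run
#'   reproducible.
#' @return A [SamplerResult-class] tagged `"FRS"`.
#' @export
runFisherSampler <- function(x, ranked, mss, config = samplerConfig()) {
    prior <- buildFisherPrior(ranked, mss, config)
    bounds <- .resolveBounds(config, mss,
                             length(prior@headerIndices) +
                             length(prior@helperIndices))
    set.seed(config@seed)
    .runNetworkSampler(x, config, "FRS",
                       draw = function() sampleNetwork(prior, bounds),
                       poolIndices = c(prior@headerIndices,
                                       prior@helperIndices),
                       extras = list(frMin = prior@frMin,
                                     lengthBounds = bounds,
                                     nHeader = length(prior@headerIndices)))
}

.resolveBounds <- function(config, mss, poolSize) {
    lb <- config@lengthBounds
    if (length(lb) != 2L || anyNA(lb)) {
        lb <- c(1L, min(length(mss), poolSize))
    } else if (lb[2L] > poolSize) {
        stop("lengthBounds exceed the sampling pool size (", poolSize, ")")
    }
    as.integer(lb)
}

# shared FRS/RS loop: draw, score, retain; records pre-retention draw
# counts over the pool
.runNetworkSampler <- function(x, config, tag, draw, poolIndices, extras) {
    labels <- phenotypeLabels(x)
    v <- exprsMatrix(x)
    nDraw <- config@nSamples
    thr <- config@accuracyThreshold
    k <- config@knnK
    counts <- structure(numeric(length(poolIndices)),
                        names = rownames(v)[poolIndices])
    sigs <- vector("list", nDraw)
    accs <- numeric(nDraw)
    iter <- integer(nDraw)
    kept <- 0L
    for (i in seq_len(nDraw)) {
        sig <- draw()
        counts[match(sig, poolIndices)] <-
            counts[match(sig, poolIndices)] + 1
        D <- .pairwiseSqDist(t(v[sig, , drop = FALSE]))
        acc <- .loocvFromDist(D, labels, k)
        if (acc > thr || thr <= 0) {
            kept <- kept + 1L
            sigs[[kept]] <- sig
            accs[kept] <- acc
            iter[kept] <- i
        }
    }
    if (!kept)
        warning("no network exceeded the ", thr, "% accuracy threshold")
    res <- new("SamplerResult",
        sampler = tag,
        signatures = sigs[seq_len(kept)],
        accuracies = accs[seq_len(kept)],
        nSampled = as.integer(nDraw),
        accuracyThreshold = thr,
        probeIds = rownames(v),
        drawCounts = counts,
        extras = c(extras, list(iteration = iter[seq_len(kept)])),
        config = .configList(config))
    validObject(res)
    res
}

#' @rdname accessors
#' @export
setMethod("signatures", "SamplerResult", function(x) x@signatures)

#' @rdname accessors
#' @export
setMethod("samplerName", "SamplerResult", function(x) x@sampler)

#' @rdname accessors
#' @export
setMethod("probeIds", "SamplerResult", function(x) x@probeIds)

#' @rdname accessors
#' @export
setMethod("accuracy", "SamplerResult", function(x) x@accuracies)

#' @rdname accessors
#' @export
setMethod("drawCounts", "SamplerResult", function(x) x@drawCounts)

setMethod("length", "SamplerResult", function(x) length(x@signatures))

setMethod("show", "SamplerResult", function(object) {
    cat(sprintf(
        "SamplerResult [%s]: %d of %d networks retained (accuracy > %g%%)\n",
        object@sampler, length(object@signatures), object@nSampled,
        object@accuracyThreshold))
    if (length(object@accuracies))
        cat(sprintf("  retained accuracy: %.1f-%.1f%%, median %.1f%%\n",
                    min(object@accuracies), max(object@accuracies),
                    stats::median(object@accuracies)))
})

#' Merge two sampler results
#'
#' Pools the retained networks of two runs over the same probe space
#' (e.g. two seeds of the same sampler). Frequencies recomputed on the
#' merge equal the count-wise sum of the separate tables before
#' normalisation.
#'
#' @param a,b [SamplerResult-class] objects with identical probe spaces.
#' @return A merged [SamplerResult-class].
#' @export
mergeSamplerResults <- function(a, b) {
    stopifnot(is(a, "SamplerResult"), is(b, "SamplerResult"))
    if (!identical(a@probeIds, b@probeIds))
        stop("results cover different probe spaces")
    dc <- a@drawCounts
    for (nm in names(b@drawCounts))
        dc[nm] <- (if (nm %in% names(dc)) dc[nm] else 0) + b@drawCounts[nm]
    new("SamplerResult",
        sampler = if (identical(a@sampler, b@sampler)) a@sampler
                  else paste(a@sampler, b@sampler, sep = "+"),
        signatures = c(a@signatures, b@signatures),
        accuracies = c(a@accuracies, b@accuracies),
        nSampled = a@nSampled + b@nSampled,
        accuracyThreshold = min(a@accuracyThreshold, b@accuracyThreshold),
        probeIds = a@probeIds,
        drawCounts = dc,
        extras = list(merged = TRUE),
        config = a@config)
}
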