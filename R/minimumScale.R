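#' Minimum-scale signature by recursive feature elimination
#'
#' Searches the nested prefixes of a Fisher's-ratio-ranked gene list for
#' the minimum-scale signature: the shortest prefix attaining the maximal
#' LOOCV k-NN accuracy. Evaluating prefixes of an FR-ranked list is the
#' deterministic form of recursive backward elimination on that ranking
#' (each step removes the lowest-ranked gene; the ranking is never
#' recomputed). The full accuracy-vs-length profile is kept for reporting,
#' and the signature length later bounds the networks the samplers draw.
#'
#' @param x the [PhenotypeExperiment-class] the ranking was computed on.
#' @param ranked a non-empty [RankedGenes-class].
#' @param config a [SamplerConfig-class]; `mssMaxLength` caps the examined
#'   prefix length, `knnK` sets the classifier.
#' @return A [MinimumScaleSignature-class].
#' @examples
#' sim <- simulateExpressionData(nGenes = 100, samplesPerClass = c(15, 15),
#'                               nPlanted = 5, effectSize = 3)
#' cfg <- samplerConfig()
#' rk <- filterAndRank(computeGeneStatistics(sim$experiment), cfg)
#' mss <- minimumScaleSignature(sim$experiment, rk, cfg)
#' accuracy(mss); length(geneIndices(mss))
#' @export
minimumScaleSignature <- function(x, ranked, config = samplerConfig()) {
    stopifnot(is(x, "PhenotypeExperiment"), is(ranked, "RankedGenes"))
    if (!length(ranked))
        stop("ranked gene list is empty")
    L <- min(length(ranked), config@mssMaxLength)
    if (L < length(ranked))
        message("minimum-scale search capped at the top ", L,
                " of ", length(ranked), " ranked genes")
    labels <- phenotypeLabels(x)
    n <- length(labels)
    v <- exprsMatrix(x)[ranked@geneIndices[seq_len(L)], , drop = FALSE]
    profile <- numeric(L)
    D <- matrix(0, n, n)
    for (len in seq_len(L)) {
        g <- v[len, ]
        D <- D + (matrix(g, n, n) - matrix(g, n, n, byrow = TRUE))^2
        profile[len] <- .loocvFromDist(D, labels, config@knnK)
    }
    best <- max(profile)
    lenBest <- which(profile >= best - 1e-9)[1L]
    out <- new("MinimumScaleSignature",
        geneIndices = ranked@geneIndices[seq_len(lenBest)],
        probeIds = ranked@probeIds[seq_len(lenBest)],
        accuracy = profile[lenBest],
        profile = profile)
    validObject(out)
    out
}

#' @rdname accessors
#' @export
setMethod("geneIndices", "MinimumScaleSignature", function(x) x@geneIndices)

#' @rdname accessors
#' @export
setMethod("probeIds", "MinimumScaleSignature", function(x) x@probeIds)

#' @rdname accessors
#' @export
setMethod("accuracy", "MinimumScaleSignature", function(x) x@accuracy)

#' @rdname accessors
#' @export
setMethod("accuracyProfile", "MinimumScaleSignature", function(x) x@profile)

setMethod("length", "MinimumScaleSignature",
          function(x) length(x@geneIndices))

setMethod("show", "MinimumScaleSignature", function(object) {
    cat(sprintf(
        "MinimumScaleSignature: %d gene(s), LOOCV accuracy %.2f%%\n",
        length(object), object@accuracy))
    cat("  genes:", paste(utils::head(object@probeIds, 10L),
                          collapse = ", "),
        if (length(object) > 10L) "..." else "", "\n")
})
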