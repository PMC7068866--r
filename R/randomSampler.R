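#' Run the random sampler
#'
#' The maximally explorative sampler: draws genetic networks from the
#' differentially expressed gene pool with a uniform prior — network
#' length uniform in `config@lengthBounds` (default
#' `[1, length(mss)]`), genes uniform without replacement — scores each
#' by LOOCV k-NN accuracy, and retains networks whose accuracy exceeds
#' `config@accuracyThreshold`.
#'
#' @param x a [PhenotypeExperiment-class].
#' @param ranked the [RankedGenes-class] pool of differentially expressed
#'   genes (fold-change and Fisher's-ratio survivors; set `useFrCutoff =
#'   FALSE` in [filterAndRank()] callers to widen the pool if desired).
#' @param mss the dataset's [MinimumScaleSignature-class]; its length
#'   bounds the sampled network lengths.
#' @param config a [SamplerConfig-class].
#' @return A [SamplerResult-class] tagged `"RS"`.
#' @export
runRandomSampler <- function(x, ranked, mss, config = samplerConfig()) {
    stopifnot(is(ranked, "RankedGenes"))
    if (!length(ranked))
        stop("ranked gene list is empty")
    pool <- ranked@geneIndices
    bounds <- .resolveBounds(config, mss, length(pool))
    lo <- bounds[1L]; hi <- bounds[2L]
    set.seed(config@seed)
    .runNetworkSampler(x, config, "RS",
        draw = function() {
            len <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L
                   else lo
            pool[sample.int(length(pool), len)]
        },
        poolIndices = pool,
        extras = list(lengthBounds = bounds))
}
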