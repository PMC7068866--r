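#' Sampler configuration
#'
#' Bundles every tunable parameter of the feature-selection step and the
#' three samplers. Defaults are the study conditions of the method:
#' fold-change screen at |log2 FC| >= 1, Fisher's-ratio cutoff 0.8 with a
#' fallback relaxation to 0.5 when fewer than `survivorFloor` genes
#' survive, an 85% retention threshold, 1e5 drawn networks for the
#' Fisher's-ratio and random samplers, 1000 holdout bags with a 75/25
#' train/validation split, and a nearest-neighbour (k = 1) classifier.
#'
#' @param foldChangeThreshold minimum |log2 fold change| for a gene to be
#'   considered differentially expressed. Default 1.
#' @param frCutoff Fisher's-ratio cutoff; genes must exceed it strictly.
#'   Default 0.8, i.e. class centers separated by more than
#'   `sqrt(0.8) ~ 0.89` pooled standard deviations.
#' @param frFallback relaxed cutoff applied automatically when fewer than
#'   `survivorFloor` genes survive. Default 0.5.
#' @param survivorFloor survivor count triggering the relaxation. Default 10.
#' @param frMinHeader Fisher's-ratio split between header and helper genes;
#'   `NA` (default) resolves to the Fisher's ratio of the last
#'   minimum-scale-signature gene, so the header pool is (at least) the
#'   minimum-scale genes.
#' @param accuracyThreshold retention threshold in percent (strict `>`);
#'   `0` retains every sampled network. Default 85.
#' @param nSamples networks drawn by the Fisher's-ratio and random
#'   samplers. Default 1e5.
#' @param nBags holdout bags. Default 1000.
#' @param holdoutFraction validation fraction of each bag. Default 0.25.
#' @param knnK odd number of nearest neighbours. Default 1.
#' @param mssMaxLength cap on the prefix lengths examined by the
#'   minimum-scale search (bounds runtime on wide survivor lists).
#'   Default 200.
#' @param lengthBounds integer(2) network length bounds for FRS/RS; `NA`
#'   (default) resolves to `c(1, length(minimum-scale signature))`.
#' @param stratified stratify holdout bags by class (default `TRUE`), so a
#'   small class cannot drop out of either split.
#' @param seed integer RNG seed used by every stochastic operation.
#' @return A validated [SamplerConfig-class].
#' @examples
#' samplerConfig(nSamples = 1000, seed = 7)
#' @export
samplerConfig <- function(foldChangeThreshold = 1,
                          frCutoff = 0.8,
                          frFallback = 0.5,
                          survivorFloor = 10L,
                          frMinHeader = NA_real_,
                          accuracyThreshold = 85,
                          nSamples = 1e5,
                          nBags = 1000L,
                          holdoutFraction = 0.25,
                          knnK = 1L,
                          mssMaxLength = 200L,
                          lengthBounds = NA,
                          stratified = TRUE,
                          seed = 1L) {
    lb <- if (length(lengthBounds) == 2L && !anyNA(lengthBounds))
        as.integer(lengthBounds) else c(NA_integer_, NA_integer_)
    new("SamplerConfig",
        foldChangeThreshold = as.numeric(foldChangeThreshold),
        frCutoff = as.numeric(frCutoff),
        frFallback = as.numeric(frFallback),
        survivorFloor = as.integer(survivorFloor),
        frMinHeader = as.numeric(frMinHeader),
        accuracyThreshold = as.numeric(accuracyThreshold),
        nSamples = as.integer(nSamples),
        nBags = as.integer(nBags),
        holdoutFraction = as.numeric(holdoutFraction),
        knnK = as.integer(knnK),
        mssMaxLength = as.integer(mssMaxLength),
        lengthBounds = lb,
        stratified = isTRUE(stratified),
        seed = as.integer(seed))
}

setMethod("show", "SamplerConfig", function(object) {
    cat("SamplerConfig\n")
    cat("  filter: |log2FC| >=", object@foldChangeThreshold,
        " FR >", object@frCutoff,
        " (fallback", object@frFallback,
        "below", object@survivorFloor, "survivors)\n")
    cat("  retention: accuracy >", object@accuracyThreshold, "%\n")
    cat("  draws:", object@nSamples, " bags:", object@nBags,
        " holdout:", object@holdoutFraction, "\n")
    cat("  k-NN k:", object@knnK, " seed:", object@seed, "\n")
})

# config snapshot used in SamplerResult provenance
.configList <- function(config) {
    nm <- slotNames("SamplerConfig")
    stats::setNames(lapply(nm, function(s) slot(config, s)), nm)
}
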