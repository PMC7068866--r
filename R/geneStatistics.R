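#' Per-gene class statistics and Fisher's ratio
#'
#' Computes, for every gene, the class means, unbiased class variances, the
#' log2 fold change (difference of class means on the assumed-log2
#' expression scale) and the Fisher's ratio
#' \deqn{FR_j = \frac{(\mu_{j1} - \mu_{j2})^2}{\sigma^2_{j1} + \sigma^2_{j2}},}
#' the per-gene discrimination score: large when the class centers are far
#' apart relative to the within-class dispersion. `FR` is symmetric in the
#' class labels and zero exactly when the class means coincide.
#'
#' Degenerate genes with zero pooled variance get `Inf` (means differ;
#' perfect separation, ranked first) or `0` (means agree).
#'
#' @param x a [PhenotypeExperiment-class]; both classes need at least two
#'   samples for the variance estimates.
#' @param center `"mean"` (default) or `"median"` class center.
#' @return A [GeneStatistics-class] with one row per gene.
#' @examples
#' sim <- simulateExpressionData(nGenes = 50, samplesPerClass = c(10, 10))
#' st <- computeGeneStatistics(sim$experiment)
#' head(st$fisherRatio)
#' @export
computeGeneStatistics <- function(x, center = c("mean", "median")) {
    stopifnot(is(x, "PhenotypeExperiment"))
    center <- match.arg(center)
    ph <- phenotypeLabels(x)
    if (sum(ph == 1L) < 2L || sum(ph == 2L) < 2L)
        stop("each class needs at least two samples")
    v <- exprsMatrix(x)
    v1 <- v[, ph == 1L, drop = FALSE]
    v2 <- v[, ph == 2L, drop = FALSE]
    mu1 <- if (center == "mean") rowMeans(v1) else
        apply(v1, 1L, stats::median)
    mu2 <- if (center == "mean") rowMeans(v2) else
        apply(v2, 1L, stats::median)
    var1 <- .rowVar(v1)
    var2 <- .rowVar(v2)
    num <- (mu1 - mu2)^2
    den <- var1 + var2
    fr <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
    out <- new("GeneStatistics", DataFrame(
        mu1 = unname(mu1), mu2 = unname(mu2),
        var1 = unname(var1), var2 = unname(var2),
        foldChange = unname(mu1 - mu2), fisherRatio = unname(fr),
        row.names = rownames(v)))
    validObject(out)
    out
}

# unbiased (n - 1) row variances
.rowVar <- function(m) {
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (ncol(m) - 1L)
}

#' Filter and rank discriminatory genes
#'
#' Keeps genes that are differentially expressed
#' (`|log2 FC| >= foldChangeThreshold`) with a Fisher's ratio strictly
#' above `frCutoff`, and ranks them by decreasing Fisher's ratio (ties by
#' decreasing |log2 FC|, then probe identifier). At the default cutoff 0.8
#' a kept gene's class centers are separated by more than
#' `sqrt(0.8) ~ 0.89` pooled standard deviations.
#'
#' When fewer than `survivorFloor` genes survive, the cutoff is relaxed
#' automatically to `frFallback` (default 0.5) with a message; zero
#' survivors even then is an error.
#'
#' @param stats a [GeneStatistics-class].
#' @param config a [SamplerConfig-class] supplying the thresholds.
#' @param quiet suppress the relaxation message (used in per-bag loops).
#' @return A [RankedGenes-class].
#' @export
filterAndRank <- function(stats, config = samplerConfig(), quiet = FALSE) {
    stopifnot(is(stats, "GeneStatistics"), is(config, "SamplerConfig"))
    fc <- stats$foldChange
    fr <- stats$fisherRatio
    keepAt <- function(cut) which(abs(fc) >= config@foldChangeThreshold &
                                  fr > cut)
    cutoff <- config@frCutoff
    keep <- keepAt(cutoff)
    relaxed <- FALSE
    if (length(keep) < config@survivorFloor &&
        config@frFallback < cutoff) {
        if (!quiet)
            message("only ", length(keep), " genes pass FR > ", cutoff,
                    "; relaxing cutoff to ", config@frFallback)
        cutoff <- config@frFallback
        keep <- keepAt(cutoff)
        relaxed <- TRUE
    }
    if (!length(keep))
        stop("no gene passes the filters; lower foldChangeThreshold or ",
             "frCutoff")
    pid <- rownames(stats)[keep]
    ord <- order(-fr[keep], -abs(fc[keep]), pid)
    keep <- keep[ord]
    out <- new("RankedGenes",
        geneIndices = as.integer(keep),
        probeIds = rownames(stats)[keep],
        fisherRatio = fr[keep],
        foldChange = fc[keep],
        foldChangeThreshold = config@foldChangeThreshold,
        frCutoff = cutoff,
        relaxed = relaxed)
    validObject(out)
    out
}

#' @rdname accessors
#' @export
setMethod("geneIndices", "RankedGenes", function(x) x@geneIndices)

#' @rdname accessors
#' @export
setMethod("probeIds", "RankedGenes", function(x) x@probeIds)

setMethod("length", "RankedGenes", function(x) length(x@geneIndices))

setMethod("show", "RankedGenes", function(object) {
    cat("RankedGenes:", length(object), "discriminatory genes",
        sprintf("(|log2FC| >= %g, FR > %g%s)\n",
                object@foldChangeThreshold, object@frCutoff,
                if (object@relaxed) ", relaxed" else ""))
    n <- min(5L, length(object))
    if (n)
        cat("  top:", paste(sprintf("%s (FR %.3g)",
                                    object@probeIds[seq_len(n)],
                                    object@fisherRatio[seq_len(n)]),
                            collapse = ", "), "\n")
})

#' Export a ranked-gene report
#'
#' Writes a TSV with columns `rank`, `probe_id`, `mu1`, `mu2`, `var1`,
#' `var2`, `fold_change`, `fisher_ratio` for the genes of a
#' [RankedGenes-class] (the layout of a per-class means / dispersions /
#' fold-change supplementary table).
#'
#' @param ranked a [RankedGenes-class].
#' @param stats the [GeneStatistics-class] it was derived from.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeRankedGenes <- function(ranked, stats, path) {
    idx <- ranked@geneIndices
    df <- data.frame(rank = seq_along(idx),
                     probe_id = ranked@probeIds,
                     mu1 = stats$mu1[idx], mu2 = stats$mu2[idx],
                     var1 = stats$var1[idx], var2 = stats$var2[idx],
                     fold_change = stats$foldChange[idx],
                     fisher_ratio = stats$fisherRatio[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
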