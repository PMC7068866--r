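#' Posterior gene-frequency analysis
#'
#' Counts each gene's occurrences across the retained high-accuracy
#' networks of a sampler run and normalises by the total number of gene
#' occurrences (the summed lengths of the retained networks), yielding
#' each gene's posterior sampling frequency. Genes are ranked by
#' decreasing frequency, ties broken by probe identifier; only genes
#' appearing in at least one retained network are listed.
#'
#' @param result a [SamplerResult-class] with at least one retained
#'   network.
#' @return A [FrequencyTable-class]; `metadata()` records the sampler,
#'   accuracy threshold, number of retained networks, total gene
#'   occurrences and the full probe space.
#' @examples
#' sim <- simulateExpressionData()
#' cfg <- samplerConfig(nSamples = 200, seed = 3)
#' fit <- fitDiscriminatoryGenes(sim$experiment, cfg)
#' res <- runRandomSampler(sim$experiment, fit$ranked, fit$mss, cfg)
#' head(geneFrequencies(res))
#' @export
geneFrequencies <- function(result) {
    stopifnot(is(result, "SamplerResult"))
    if (!length(result@signatures))
        stop("no retained networks: raise nSamples or lower the accuracy ",
             "threshold")
    occ <- unlist(result@signatures, use.names = FALSE)
    counts <- table(occ)
    pid <- result@probeIds[as.integer(names(counts))]
    cnt <- as.integer(counts)
    freq <- cnt / length(occ)
    ord <- order(-freq, pid)
    out <- new("FrequencyTable", DataFrame(
        count = cnt[ord],
        frequency = freq[ord],
        rank = seq_along(ord),
        row.names = pid[ord]))
    metadata(out) <- list(sampler = samplerName(result),
                          accuracyThreshold = result@accuracyThreshold,
                          nRetained = length(result@signatures),
                          totalGeneDraws = length(occ),
                          probeSpace = result@probeIds)
    validObject(out)
    out
}

#' Threshold a frequency table to a discriminatory gene list
#'
#' Selects the genes a user would carry forward to an external pathway /
#' ontology tool: either every gene with frequency at or above a numeric
#' threshold, or the top `N` by rank (`threshold = "top-30"` style, the
#' default scale of the reported gene lists). Rank order is preserved.
#'
#' @param table a non-empty [FrequencyTable-class].
#' @param threshold numeric frequency cutoff, or a string `"top-N"`.
#' @return Character vector of probe identifiers (possibly empty, with a
#'   warning, if the cutoff excludes every gene).
#' @export
applyFrequencyThreshold <- function(table, threshold = "top-30") {
    stopifnot(is(table, "FrequencyTable"))
    if (!nrow(table))
        stop("frequency table is empty")
    if (is.character(threshold)) {
        n <- suppressWarnings(as.integer(sub("^top-", "", threshold)))
        if (is.na(n) || n < 1L)
            stop("threshold must be numeric or 'top-N'")
        return(rownames(table)[seq_len(min(n, nrow(table)))])
    }
    keep <- table$frequency >= threshold
    if (!any(keep))
        warning("frequency threshold ", threshold, " excludes all genes")
    rownames(table)[keep]
}

#' Cross-sampler concordance of top-ranked genes
#'
#' Quantifies how far the samplers agree on the discriminatory genes — the
#' package's handle on biological invariance: pairwise overlap counts and
#' Jaccard indices of the samplers' top-`nTop` gene lists, plus the
#' intersection across all samplers.
#'
#' @param tables named list of two or more [FrequencyTable-class] objects
#'   over the same probe space.
#' @param nTop number of top-ranked genes compared. Default 10.
#' @return A list with `topGenes` (per-sampler top lists), `pairwise`
#'   (data.frame: pair, overlap, jaccard) and `intersection` (genes in
#'   every list).
#' @export
samplerConcordance <- function(tables, nTop = 10L) {
    if (length(tables) < 2L)
        stop("at least two frequency tables are required")
    if (is.null(names(tables)))
        names(tables) <- vapply(tables, function(t)
            metadata(t)$sampler, character(1))
    spaces <- lapply(tables, function(t) metadata(t)$probeSpace)
    for (i in seq_along(spaces)[-1L])
        if (!setequal(spaces[[1L]], spaces[[i]]))
            stop("frequency tables cover different probe spaces")
    tops <- lapply(tables, function(t)
        rownames(t)[seq_len(min(nTop, nrow(t)))])
    pairs <- utils::combn(names(tables), 2L)
    pw <- data.frame(
        pair = apply(pairs, 2L, paste, collapse = "-"),
        overlap = apply(pairs, 2L, function(p)
            length(intersect(tops[[p[1L]]], tops[[p[2L]]]))),
        jaccard = apply(pairs, 2L, function(p) {
            a <- tops[[p[1L]]]; b <- tops[[p[2L]]]
            length(intersect(a, b)) / length(union(a, b))
        }))
    list(topGenes = tops,
         pairwise = pw,
         intersection = Reduce(intersect, tops))
}

#' Write a concordance report
#'
#' Serialises the output of [samplerConcordance()] as JSON (and,
#' optionally, a human-readable text summary alongside).
#'
#' @param concordance a list from [samplerConcordance()].
#' @param path output JSON path.
#' @param text optional path for a plain-text summary.
#' @return Invisibly, `path`.
#' @export
writeConcordance <- function(concordance, path, text = NULL) {
    jsonlite::write_json(concordance, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    if (!is.null(text)) {
        con <- file(text, "w")
        on.exit(close(con))
        writeLines("Cross-sampler concordance", con)
        for (i in seq_len(nrow(concordance$pairwise)))
            writeLines(sprintf("  %s: overlap %d, Jaccard %.3f",
                               concordance$pairwise$pair[i],
                               concordance$pairwise$overlap[i],
                               concordance$pairwise$jaccard[i]), con)
        writeLines(paste("  common to all:",
                         paste(concordance$intersection, collapse = ", ")),
                   con)
    }
    invisible(path)
}
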