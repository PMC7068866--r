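#' Construct a PhenotypeExperiment
#'
#' Wraps a genes-by-samples expression matrix and a two-class label vector
#' into a validated [PhenotypeExperiment-class]. Expression values are used
#' as supplied (assumed normalised, typically log2 scale).
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names supply probe and sample identifiers unless overridden.
#' @param labels vector coercible to integer, one entry per sample, each
#'   `1` or `2`; both classes must be present. A named vector is matched to
#'   `sampleIds` by name.
#' @param probeIds,sampleIds optional character identifiers overriding the
#'   dimnames of `values`.
#' @return A [PhenotypeExperiment-class].
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' pe <- PhenotypeExperiment(m, c(1, 1, 2, 2))
#' phenotypeLabels(pe)
#' @export
PhenotypeExperiment <- function(values, labels,
                                probeIds = rownames(values),
                                sampleIds = colnames(values)) {
    values <- as.matrix(values)
    if (is.null(probeIds))
        probeIds <- paste0("g", seq_len(nrow(values)))
    if (is.null(sampleIds))
        sampleIds <- paste0("s", seq_len(ncol(values)))
    dimnames(values) <- list(probeIds, sampleIds)
    if (!is.null(names(labels))) {
        if (!all(sampleIds %in% names(labels)))
            stop("labels missing for samples: ",
                 paste(setdiff(sampleIds, names(labels)), collapse = ", "))
        labels <- labels[sampleIds]
    }
    labels <- as.integer(labels)
    se <- SummarizedExperiment(
        assays = list(exprs = values),
        colData = DataFrame(phenotype = labels, row.names = sampleIds)
    )
    new("PhenotypeExperiment", se)
}

#' @rdname accessors
#' @export
setMethod("phenotypeLabels", "PhenotypeExperiment", function(x) {
    as.integer(colData(x)$phenotype)
})

#' @rdname accessors
#' @export
setMethod("probeIds", "PhenotypeExperiment", function(x) rownames(x))

#' Expression matrix of a PhenotypeExperiment
#'
#' @param x a [PhenotypeExperiment-class].
#' @return The numeric genes-by-samples matrix (assay `"exprs"`).
#' @export
exprsMatrix <- function(x) {
    stopifnot(is(x, "PhenotypeExperiment"))
    assay(x, "exprs")
}

#' Per-class sample counts
#'
#' @param x a [PhenotypeExperiment-class].
#' @return Integer vector of length 2: samples in class 1 and class 2.
#' @export
classSizes <- function(x) {
    ph <- phenotypeLabels(x)
    c(sum(ph == 1L), sum(ph == 2L))
}

setMethod("show", "PhenotypeExperiment", function(object) {
    cs <- classSizes(object)
    cat("PhenotypeExperiment with", nrow(object), "genes x",
        ncol(object), "samples\n")
    cat("  class 1:", cs[1], " class 2:", cs[2], "\n")
    callNextMethod()
})

#' Subset a PhenotypeExperiment by samples
#'
#' Keeps validated class semantics when selecting a subset of samples
#' (e.g. a holdout bag's training split). Both classes must remain present.
#'
#' @param x a [PhenotypeExperiment-class].
#' @param samples integer, logical or character index of samples to keep.
#' @return A [PhenotypeExperiment-class] with the selected samples.
#' @export
selectSamples <- function(x, samples) {
    stopifnot(is(x, "PhenotypeExperiment"))
    out <- x[, samples]
    validObject(out)
    out
}
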