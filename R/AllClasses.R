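#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' PhenotypeExperiment: a two-class expression experiment
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with the constraints
#' a binary phenotype-prediction problem needs: a single numeric expression
#' assay (`"exprs"`, genes in rows, samples in columns) with no missing
#' values, unique probe and sample identifiers, and a `phenotype` column in
#' `colData` holding the class of every sample, coded `1` or `2`, with both
#' classes present.
#'
#' Expression values are taken as already normalised (typically log scale);
#' no normalisation is performed anywhere in the package.
#'
#' @seealso [PhenotypeExperiment()] for construction from a matrix,
#'   [readExpressionDataset()] for construction from delimited text files.
#' @export
setClass("PhenotypeExperiment", contains = "SummarizedExperiment")

setValidity("PhenotypeExperiment", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        v <- assay(object, "exprs")
        if (!is.numeric(v))
            msg <- c(msg, "assay 'exprs' must be numeric")
        else if (anyNA(v))
            msg <- c(msg, "assay 'exprs' must not contain missing values")
    }
    if (nrow(object) < 1L)
        msg <- c(msg, "at least one gene is required")
    if (ncol(object) < 2L)
        msg <- c(msg, "at least two samples are required")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "probe identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (!"phenotype" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'phenotype' is required")
    else {
        ph <- colData(object)$phenotype
        if (!all(ph %in% c(1L, 2L)))
            msg <- c(msg, "phenotype labels must be coded 1 or 2")
        else if (length(unique(ph)) < 2L)
            msg <- c(msg, "both classes required")
    }
    if (length(msg)) msg else TRUE
})

#' Per-gene class statistics
#'
#' A [S4Vectors::DataFrame] (one row per gene, rownames = probe identifiers)
#' holding per-gene class centers (`mu1`, `mu2`), class dispersions (`var1`,
#' `var2`, unbiased sample variances), the log2 fold change
#' (`foldChange = mu1 - mu2`, a difference of class means on the, assumed
#' log2, expression scale) and the Fisher's ratio
#' `fisherRatio = (mu1 - mu2)^2 / (var1 + var2)`.
#'
#' Genes whose pooled dispersion is exactly zero get `fisherRatio = Inf`
#' when the class means differ (perfect separation sentinel, ranked first)
#' and `0` when they agree.
#'
#' @seealso [computeGeneStatistics()]
#' @export
setClass("GeneStatistics", contains = "DFrame")

setValidity("GeneStatistics", function(object) {
    need <- c("mu1", "mu2", "var1", "var2", "foldChange", "fisherRatio")
    msg <- character()
    if (!all(need %in% colnames(object)))
        msg <- c(msg, paste("columns required:", paste(need, collapse = ", ")))
    else {
        fr <- object$fisherRatio
        if (any(fr < 0, na.rm = TRUE))
            msg <- c(msg, "fisherRatio must be non-negative")
    }
    if (is.null(rownames(object)))
        msg <- c(msg, "rownames (probe identifiers) are required")
    if (length(msg)) msg else TRUE
})

#' Ranked discriminatory gene list
#'
#' The genes surviving the fold-change and Fisher's-ratio filters, ordered
#' by decreasing Fisher's ratio (ties broken by decreasing absolute fold
#' change, then by probe identifier). `geneIndices` index into the
#' originating [PhenotypeExperiment].
#'
#' @slot geneIndices integer, row indices of the kept genes in the dataset.
#' @slot probeIds character, the kept genes' probe identifiers.
#' @slot fisherRatio numeric, non-increasing along the list.
#' @slot foldChange numeric, log2 fold change of the kept genes.
#' @slot foldChangeThreshold numeric, the applied |log2 FC| threshold.
#' @slot frCutoff numeric, the Fisher's-ratio cutoff actually applied
#'   (after any automatic relaxation).
#' @slot relaxed logical, whether the cutoff was relaxed to the fallback.
#' @seealso [filterAndRank()]
#' @export
setClass("RankedGenes",
    representation(
        geneIndices = "integer",
        probeIds = "character",
        fisherRatio = "numeric",
        foldChange = "numeric",
        foldChangeThreshold = "numeric",
        frCutoff = "numeric",
        relaxed = "logical"
    )
)

setValidity("RankedGenes", function(object) {
    msg <- character()
    n <- length(object@geneIndices)
    if (length(object@probeIds) != n || length(object@fisherRatio) != n ||
        length(object@foldChange) != n)
        msg <- c(msg, "parallel slots must have equal length")
    if (n > 0L && anyDuplicated(object@geneIndices))
        msg <- c(msg, "gene indices must be distinct")
    fr <- object@fisherRatio
    if (n > 1L && any(diff(fr) > 1e-12))
        msg <- c(msg, "fisherRatio must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' Minimum-scale signature
#'
#' The shortest prefix of a Fisher's-ratio-ranked gene list attaining the
#' maximal LOOCV k-NN accuracy, together with the full accuracy-vs-length
#' profile examined during recursive (backward) feature elimination.
#'
#' @slot geneIndices integer, dataset row indices of the signature genes
#'   (a prefix of the ranked list).
#' @slot probeIds character, their probe identifiers.
#' @slot accuracy numeric, LOOCV accuracy (percent) of the signature.
#' @slot profile numeric, LOOCV accuracy of every examined prefix length
#'   (element `l` = accuracy of the first `l` ranked genes).
#' @seealso [minimumScaleSignature()]
#' @export
setClass("MinimumScaleSignature",
    representation(
        geneIndices = "integer",
        probeIds = "character",
        accuracy = "numeric",
        profile = "numeric"
    )
)

setValidity("MinimumScaleSignature", function(object) {
    msg <- character()
    L <- length(object@geneIndices)
    if (L < 1L)
        msg <- c(msg, "signature must contain at least one gene")
    if (length(object@profile) < L)
        msg <- c(msg, "profile must cover the signature length")
    else {
        if (abs(object@accuracy - max(object@profile)) > 1e-9)
            msg <- c(msg, "accuracy must equal the profile maximum")
        if (L > 1L && any(object@profile[seq_len(L - 1L)] >=
                          object@accuracy - 1e-9))
            msg <- c(msg, "a shorter prefix attains the maximum accuracy")
    }
    if (length(msg)) msg else TRUE
})

#' Classification accuracy result
#'
#' @slot accuracy numeric, percent in \[0, 100\]:
#'   `100 * (nEvaluated - misclassified) / nEvaluated`.
#' @slot nEvaluated integer, number of samples evaluated.
#' @slot misclassified character, identifiers of the misclassified samples.
#' @seealso [loocvAccuracy()], [blindValidationAccuracy()]
#' @export
setClass("AccuracyResult",
    representation(
        accuracy = "numeric",
        nEvaluated = "integer",
        misclassified = "character"
    )
)

setValidity("AccuracyResult", function(object) {
    n <- object@nEvaluated
    m <- length(object@misclassified)
    expect <- 100 * (n - m) / n
    if (n < 1L)
        "nEvaluated must be positive"
    else if (abs(object@accuracy - expect) > 1e-9)
        "accuracy inconsistent with misclassified count"
    else TRUE
})

#' Fisher's-ratio sampling prior
#'
#' The prior of the Fisher's ratio sampler: the ranked discriminatory genes
#' split into a header pool (Fisher's ratio at or above `frMin`) and a
#' helper pool (below `frMin`), each with selection weights proportional to
#' the genes' Fisher's ratios (normalised within the pool) and the implied
#' empirical cumulative distribution used for inverse-cdf draws.
#'
#' @slot headerIndices,helperIndices integer, dataset row indices per pool.
#' @slot headerWeights,helperWeights numeric, positive, sum to 1 per
#'   (non-empty) pool.
#' @slot frMin numeric, the header/helper split point actually used.
#' @seealso [buildFisherPrior()], [sampleNetwork()]
#' @export
setClass("FisherPrior",
    representation(
        headerIndices = "integer",
        helperIndices = "integer",
        headerWeights = "numeric",
        helperWeights = "numeric",
        frMin = "numeric"
    )
)

setValidity("FisherPrior", function(object) {
    msg <- character()
    if (length(object@headerIndices) < 1L)
        msg <- c(msg, "header pool must not be empty")
    if (length(object@headerWeights) != length(object@headerIndices) ||
        length(object@helperWeights) != length(object@helperIndices))
        msg <- c(msg, "weights must parallel pool indices")
    if (length(intersect(object@headerIndices, object@helperIndices)))
        msg <- c(msg, "header and helper pools must be disjoint")
    for (w in list(object@headerWeights, object@helperWeights)) {
        if (length(w) && (any(w <= 0) || abs(sum(w) - 1) > 1e-9))
            msg <- c(msg, "pool weights must be positive and sum to 1")
    }
    if (length(msg)) msg else TRUE
})

#' Result of one sampler run
#'
#' The retained high-accuracy genetic networks of one sampler run, plus
#' provenance: the sampler name, how many networks were drawn, the accuracy
#' threshold, per-gene pre-retention draw counts, and a configuration
#' snapshot.
#'
#' @slot sampler character, `"FRS"`, `"HS"` or `"RS"`.
#' @slot signatures list of integer vectors, the retained networks as
#'   dataset row indices.
#' @slot accuracies numeric, the retained networks' accuracies (percent).
#' @slot nSampled integer, networks drawn (or bags processed) in total.
#' @slot accuracyThreshold numeric, the retention threshold (percent).
#' @slot probeIds character, the full probe space of the dataset.
#' @slot drawCounts numeric, named per-gene draw counts before retention
#'   (for HS: gene occurrences over all non-skipped bag signatures).
#' @slot extras list, sampler-specific extras (all accuracies, bag ids,
#'   skipped-bag count, ...).
#' @slot config list, snapshot of the [SamplerConfig] used.
#' @export
setClass("SamplerResult",
    representation(
        sampler = "character",
        signatures = "list",
        accuracies = "numeric",
        nSampled = "integer",
        accuracyThreshold = "numeric",
        probeIds = "character",
        drawCounts = "numeric",
        extras = "list",
        config = "list"
    )
)

setValidity("SamplerResult", function(object) {
    msg <- character()
    if (length(object@signatures) != length(object@accuracies))
        msg <- c(msg, "one accuracy per retained signature required")
    if (length(object@accuracies) &&
        (any(object@accuracies < 0) || any(object@accuracies > 100)))
        msg <- c(msg, "accuracies must lie in [0, 100]")
    thr <- object@accuracyThreshold
    if (thr > 0 && length(object@accuracies) &&
        any(object@accuracies <= thr - 1e-9))
        msg <- c(msg, "retained accuracies must exceed the threshold")
    if (length(msg)) msg else TRUE
})

#' Posterior gene-frequency table
#'
#' A [S4Vectors::DataFrame] (rownames = probe identifiers, ordered by rank)
#' with columns `count` (occurrences of the gene over the retained
#' high-accuracy networks), `frequency` (count divided by the total number
#' of gene occurrences, i.e. the summed lengths of the retained networks)
#' and `rank` (descending frequency, ties broken by probe identifier).
#' Provenance (sampler, accuracy threshold, number of retained networks,
#' full probe space) lives in `metadata()`.
#'
#' @seealso [geneFrequencies()], [writeFrequencyTable()]
#' @export
setClass("FrequencyTable", contains = "DFrame")

setValidity("FrequencyTable", function(object) {
    msg <- character()
    need <- c("count", "frequency", "rank")
    if (!all(need %in% colnames(object)))
        msg <- c(msg, "columns count, frequency, rank required")
    else if (nrow(object)) {
        if (abs(sum(object$frequency) - 1) > 1e-9)
            msg <- c(msg, "frequencies must sum to 1")
        if (any(object$count < 0) ||
            any(object$count != round(object$count)))
            msg <- c(msg, "counts must be non-negative integers")
        if (any(diff(object$frequency) > 1e-12))
            msg <- c(msg, "rows must be ordered by non-increasing frequency")
    }
    if (is.null(rownames(object)))
        msg <- c(msg, "rownames (probe identifiers) required")
    if (length(msg)) msg else TRUE
})

#' Sampler configuration
#'
#' All tunable parameters of the samplers in one validated object; see
#' [samplerConfig()] for the defaults and their meaning.
#'
#' @slot foldChangeThreshold numeric, minimum |log2 fold change|.
#' @slot frCutoff numeric (> 0), Fisher's-ratio cutoff (strict >).
#' @slot frFallback numeric, relaxed cutoff used when too few genes survive.
#' @slot survivorFloor integer, survivor count below which the cutoff is
#'   relaxed.
#' @slot frMinHeader numeric, header/helper split point; `NA` = automatic
#'   (Fisher's ratio of the last minimum-scale-signature gene).
#' @slot accuracyThreshold numeric, retention threshold in percent.
#' @slot nSamples integer, networks to draw (FRS/RS).
#' @slot nBags integer, holdout bags (HS).
#' @slot holdoutFraction numeric in (0, 1), validation fraction per bag.
#' @slot knnK integer, odd, neighbours for the k-NN classifier.
#' @slot mssMaxLength integer, cap on the examined prefix length.
#' @slot lengthBounds integer(2), network length bounds; `NA` = automatic
#'   (`[1, length(minimum-scale signature)]`).
#' @slot stratified logical, stratify holdout bags by class.
#' @slot seed integer, RNG seed.
#' @export
setClass("SamplerConfig",
    representation(
        foldChangeThreshold = "numeric",
        frCutoff = "numeric",
        frFallback = "numeric",
        survivorFloor = "integer",
        frMinHeader = "numeric",
        accuracyThreshold = "numeric",
        nSamples = "integer",
        nBags = "integer",
        holdoutFraction = "numeric",
        knnK = "integer",
        mssMaxLength = "integer",
        lengthBounds = "integer",
        stratified = "logical",
        seed = "integer"
    )
)

setValidity("SamplerConfig", function(object) {
    msg <- character()
    if (object@frCutoff <= 0)
        msg <- c(msg, "frCutoff must be positive")
    if (object@holdoutFraction <= 0 || object@holdoutFraction >= 1)
        msg <- c(msg, "holdoutFraction must lie in (0, 1)")
    if (object@accuracyThreshold < 0 || object@accuracyThreshold > 100)
        msg <- c(msg, "accuracyThreshold must lie in [0, 100]")
    if (object@knnK < 1L || object@knnK %% 2L == 0L)
        msg <- c(msg, "knnK must be a positive odd integer")
    if (object@nSamples < 1L || object@nBags < 1L)
        msg <- c(msg, "nSamples and nBags must be positive")
    if (object@mssMaxLength < 1L)
        msg <- c(msg, "mssMaxLength must be positive")
    lb <- object@lengthBounds
    if (length(lb) == 2L && !anyNA(lb) && (lb[1] < 1L || lb[2] < lb[1]))
        msg <- c(msg, "lengthBounds must satisfy 1 <= min <= max")
    if (length(msg)) msg else TRUE
})
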