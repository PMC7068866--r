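#' k-NN classification accuracy
#'
#' The likelihood engine shared by all samplers: a k-nearest-neighbour
#' classifier (Euclidean distance restricted to the signature's genes)
#' scored either by leave-one-out cross-validation over one dataset
#' (`loocvAccuracy`) or by blind prediction of a validation set from a
#' training set (`blindValidationAccuracy`). The accuracy of a signature
#' `g` is `Acc(g) = 100 - O(g)` where `O(g)` is the percentage of
#' misclassified samples.
#'
#' Ties are deterministic: equidistant neighbours are resolved toward the
#' smallest training-sample index, and (for even effective votes) vote ties
#' toward class 1. Repeated evaluation of the same inputs is bit-identical;
#' there is no hidden randomness.
#'
#' @param x,train,valid [PhenotypeExperiment-class] objects; `train` and
#'   `valid` must share the same probe space.
#' @param signature integer vector of gene (row) indices; gene order is
#'   irrelevant.
#' @param k odd number of neighbours, less than the number of training
#'   samples. Default 1 (nearest neighbour).
#' @return An [AccuracyResult-class].
#' @examples
#' sim <- simulateExpressionData(nGenes = 20, samplesPerClass = c(10, 10),
#'                               nPlanted = 2, effectSize = 4)
#' accuracy(loocvAccuracy(sim$experiment, sim$planted))
#' @export
loocvAccuracy <- function(x, signature, k = 1L) {
    stopifnot(is(x, "PhenotypeExperiment"))
    signature <- .checkSignature(signature, nrow(x))
    n <- ncol(x)
    if (k >= n)
        stop("k must be smaller than the number of samples")
    labels <- phenotypeLabels(x)
    D <- .pairwiseSqDist(t(exprsMatrix(x)[signature, , drop = FALSE]))
    pred <- .knnFromDist(D, labels, k, excludeSelf = TRUE)
    .accuracyResult(pred, labels, colnames(x))
}

#' @rdname loocvAccuracy
#' @export
blindValidationAccuracy <- function(train, valid, signature, k = 1L) {
    stopifnot(is(train, "PhenotypeExperiment"),
              is(valid, "PhenotypeExperiment"))
    if (!identical(rownames(train), rownames(valid)))
        stop("train and validation sets must share the same probe space")
    if (ncol(valid) < 1L)
        stop("validation set is empty")
    signature <- .checkSignature(signature, nrow(train))
    if (k > ncol(train))
        stop("k must not exceed the number of training samples")
    trainLabels <- phenotypeLabels(train)
    Mt <- t(exprsMatrix(train)[signature, , drop = FALSE])
    Mv <- t(exprsMatrix(valid)[signature, , drop = FALSE])
    D <- .crossSqDist(Mv, Mt)
    pred <- .knnFromDist(D, trainLabels, k, excludeSelf = FALSE)
    .accuracyResult(pred, phenotypeLabels(valid), colnames(valid))
}

.checkSignature <- function(signature, nGenes) {
    signature <- as.integer(signature)
    if (!length(signature))
        stop("signature must contain at least one gene")
    if (anyDuplicated(signature))
        stop("signature gene indices must be distinct")
    if (any(signature < 1L) || any(signature > nGenes))
        stop("signature index out of range")
    signature
}

.accuracyResult <- function(pred, truth, ids) {
    wrong <- which(pred != truth)
    new("AccuracyResult",
        accuracy = 100 * (length(truth) - length(wrong)) / length(truth),
        nEvaluated = length(truth),
        misclassified = ids[wrong])
}

# squared Euclidean distances between rows of M (samples x genes)
.pairwiseSqDist <- function(M) {
    G <- tcrossprod(M)
    s <- diag(G)
    D <- outer(s, s, "+") - 2 * G
    D[D < 0] <- 0
    D
}

# squared distances rows(A) x rows(B)
.crossSqDist <- function(A, B) {
    D <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    D[D < 0] <- 0
    D
}

# predictions from a query x reference squared-distance matrix;
# excludeSelf = TRUE for LOOCV (square D, self on the diagonal)
.knnFromDist <- function(D, refLabels, k, excludeSelf) {
    if (excludeSelf)
        diag(D) <- Inf
    if (k == 1L) {
        # max.col(ties = "first") = argmin distance, smallest index on ties
        nn <- max.col(-D, ties.method = "first")
        return(refLabels[nn])
    }
    apply(D, 1L, function(d) {
        nn <- order(d)[seq_len(k)]          # order() is stable: index ties
        votes <- tabulate(refLabels[nn], 2L)
        if (votes[1L] >= votes[2L]) 1L else 2L
    })
}

#' @rdname accessors
#' @export
setMethod("accuracy", "AccuracyResult", function(x) x@accuracy)

#' Misclassified sample identifiers
#'
#' @param x an [AccuracyResult-class].
#' @return Character vector of misclassified sample identifiers.
#' @export
misclassifiedSamples <- function(x) {
    stopifnot(is(x, "AccuracyResult"))
    x@misclassified
}

setMethod("show", "AccuracyResult", function(object) {
    cat(sprintf("AccuracyResult: %.2f%% (%d of %d correct)\n",
                object@accuracy,
                object@nEvaluated - length(object@misclassified),
                object@nEvaluated))
})

# LOOCV accuracy (percent) from a precomputed squared-distance matrix;
# hot path used by the minimum-scale search and the samplers
.loocvFromDist <- function(D, labels, k) {
    pred <- .knnFromDist(D, labels, k, excludeSelf = TRUE)
    100 * sum(pred == labels) / length(labels)
}
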