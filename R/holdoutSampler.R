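#' Build random train/validation bags
#'
#' Splits the samples into `nBags` independent random holdout partitions
#' with a `1 - fraction` / `fraction` train/validation split (default
#' 75/25). Splits are stratified by class by default (per class, the
#' validation count is `floor(fraction * n_class)` with a minimum of 1),
#' so both classes appear in both parts of every bag; an unstratified mode
#' draws the validation set from the pooled samples.
#'
#' Uses the current RNG state; [runHoldoutSampler()] seeds it from the
#' configuration.
#'
#' @param x a [PhenotypeExperiment-class] with at least 4 samples.
#' @param nBags number of bags.
#' @param fraction validation fraction in (0, 1).
#' @param stratified stratify by class (default `TRUE`).
#' @return A list of bags, each a list with `bagId`, `train` and
#'   `validation` integer sample indices.
#' @export
makeBags <- function(x, nBags = 1000L, fraction = 0.25,
                     stratified = TRUE) {
    stopifnot(is(x, "PhenotypeExperiment"))
    n <- ncol(x)
    if (n < 4L)
        stop("at least 4 samples are required for holdout bagging")
    ph <- phenotypeLabels(x)
    idx1 <- which(ph == 1L); idx2 <- which(ph == 2L)
    if (stratified) {
        if (length(idx1) < 3L || length(idx2) < 3L)
            stop("each class needs >= 3 samples to appear in both splits ",
                 "(>= 2 in training)")
        v1 <- max(1L, floor(fraction * length(idx1)))
        v2 <- max(1L, floor(fraction * length(idx2)))
    } else {
        nv <- max(2L, floor(fraction * n))
        if (nv >= n - 1L)
            stop("validation fraction leaves no training samples")
    }
    lapply(seq_len(nBags), function(b) {
        if (stratified) {
            val <- c(idx1[sample.int(length(idx1), v1)],
                     idx2[sample.int(length(idx2), v2)])
        } else {
            val <- sample.int(n, nv)
        }
        val <- sort(val)
        list(bagId = b, train = setdiff(seq_len(n), val),
             validation = val)
    })
}

#' Run the holdout sampler
#'
#' For each of `config@nBags` random 75/25 train/validation bags, the full
#' feature-selection chain — per-gene statistics, fold-change +
#' Fisher's-ratio filter, minimum-scale signature search — is run on the
#' training split alone, and the resulting signature is scored blindly on
#' the bag's validation split (validation labels are used only for
#' scoring, never for selection). Signatures whose validation accuracy
#' exceeds `config@accuracyThreshold` are retained. Bags whose training
#' split yields no discriminatory gene are skipped with a warning.
#'
#' @param x a [PhenotypeExperiment-class].
#' @param config a [SamplerConfig-class]; `nBags`, `holdoutFraction`,
#'   `stratified`, the filter thresholds and `seed` are honoured.
#' @return A [SamplerResult-class] tagged `"HS"`; `extras` carries per-bag
#'   ids, signature lengths and the skipped-bag count.
#' @export
runHoldoutSampler <- function(x, config = samplerConfig()) {
    stopifnot(is(x, "PhenotypeExperiment"))
    set.seed(config@seed)
    bags <- makeBags(x, config@nBags, config@holdoutFraction,
                     config@stratified)
    n <- ncol(x)
    nBags <- length(bags)
    sigs <- vector("list", nBags)
    accs <- numeric(nBags)
    bagIds <- integer(nBags)
    allAcc <- rep(NA_real_, nBags)
    counts <- structure(numeric(nrow(x)), names = rownames(x))
    kept <- 0L; skipped <- 0L
    for (bag in bags) {
        train <- NULL
        sig <- tryCatch({
            train <- selectSamples(x, bag$train)
            st <- computeGeneStatistics(train)
            rk <- filterAndRank(st, config, quiet = TRUE)
            geneIndices(minimumScaleSignature(train, rk, config))
        }, error = function(e) NULL)
        if (is.null(sig)) {
            skipped <- skipped + 1L
            next
        }
        counts[sig] <- counts[sig] + 1
        # plain subset: an unstratified validation split may hold one class
        valid <- x[, bag$validation]
        acc <- accuracy(blindValidationAccuracy(train, valid, sig,
                                                config@knnK))
        allAcc[bag$bagId] <- acc
        if (acc > config@accuracyThreshold || config@accuracyThreshold <= 0) {
            kept <- kept + 1L
            sigs[[kept]] <- sig
            accs[kept] <- acc
            bagIds[kept] <- bag$bagId
        }
    }
    if (skipped)
        warning(skipped, " bag(s) skipped: no discriminatory genes in the ",
                "training split")
    if (!kept)
        warning("no bag exceeded the ", config@accuracyThreshold,
                "% validation accuracy threshold")
    res <- new("SamplerResult",
        sampler = "HS",
        signatures = sigs[seq_len(kept)],
        accuracies = accs[seq_len(kept)],
        nSampled = as.integer(nBags),
        accuracyThreshold = config@accuracyThreshold,
        probeIds = rownames(x),
        drawCounts = counts[counts > 0],
        extras = list(iteration = bagIds[seq_len(kept)],
                      bagId = bagIds[seq_len(kept)],
                      validationAccuracies = allAcc,
                      skippedBags = skipped),
        config = .configList(config))
    validObject(res)
    res
}
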