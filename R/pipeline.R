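#' Run the full sampling pipeline on expression files
#'
#' End-to-end orchestration: load the matrix and labels, run the shared
#' feature selection, run the requested sampler(s), compute the posterior
#' gene-frequency tables (plus cross-sampler concordance when more than
#' one sampler runs), and write every artifact to `outDir`:
#' `frequencies_<S>.tsv`, `signatures_<S>.jsonl`, `ranked_genes.tsv`,
#' `concordance.json`/`.txt`, and a `manifest.json` capturing the
#' configuration snapshot, input digests, seed and per-sampler counts so a
#' re-run with the same inputs and seed reproduces all outputs.
#'
#' @param matrixPath,labelsPath input files (see
#'   [readExpressionDataset()]); alternatively pass a ready
#'   [PhenotypeExperiment-class] as `dataset`.
#' @param samplers subset of `c("frs", "holdout", "random")`, or `"all"`.
#' @param config a [SamplerConfig-class].
#' @param outDir output directory (created if missing).
#' @param dataset optional [PhenotypeExperiment-class] overriding the file
#'   inputs.
#' @param nTop top-list size used for the concordance report.
#' @return Invisibly, the manifest as a list.
#' @export
runPipeline <- function(matrixPath = NULL, labelsPath = NULL,
                        samplers = "all", config = samplerConfig(),
                        outDir = ".", dataset = NULL, nTop = 10L) {
    if (identical(samplers, "all"))
        samplers <- c("frs", "holdout", "random")
    samplers <- match.arg(samplers, c("frs", "holdout", "random"),
                          several.ok = TRUE)
    if (is.null(dataset)) {
        if (is.null(matrixPath) || is.null(labelsPath))
            stop("provide matrixPath and labelsPath, or a dataset")
        dataset <- readExpressionDataset(matrixPath, labelsPath)
    }
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    fit <- fitDiscriminatoryGenes(dataset, config)
    writeRankedGenes(fit$ranked, fit$stats,
                     file.path(outDir, "ranked_genes.tsv"))

    results <- list()
    tables <- list()
    outputs <- file.path(outDir, "ranked_genes.tsv")
    for (s in samplers) {
        res <- switch(s,
            frs = runFisherSampler(dataset, fit$ranked, fit$mss, config),
            holdout = runHoldoutSampler(dataset, config),
            random = runRandomSampler(dataset, fit$ranked, fit$mss, config))
        tag <- samplerName(res)
        results[[tag]] <- res
        sigPath <- file.path(outDir, paste0("signatures_", tag, ".jsonl"))
        writeSignatures(res, sigPath)
        outputs <- c(outputs, sigPath)
        if (length(signatures(res))) {
            tables[[tag]] <- geneFrequencies(res)
            tabPath <- file.path(outDir,
                                 paste0("frequencies_", tag, ".tsv"))
            writeFrequencyTable(tables[[tag]], tabPath)
            outputs <- c(outputs, tabPath)
        }
    }
    concord <- NULL
    if (length(tables) >= 2L) {
        concord <- samplerConcordance(tables, nTop = nTop)
        writeConcordance(concord, file.path(outDir, "concordance.json"),
                         text = file.path(outDir, "concordance.txt"))
        outputs <- c(outputs, file.path(outDir, "concordance.json"),
                     file.path(outDir, "concordance.txt"))
    }
    manifest <- list(
        config = .configList(config),
        inputs = .inputDigests(matrixPath, labelsPath),
        seed = config@seed,
        samplers = lapply(results, function(r)
            list(sampled = r@nSampled, retained = length(signatures(r)))),
        minimumScaleSignature = list(
            length = length(fit$mss),
            loocvAccuracy = accuracy(fit$mss)),
        outputs = outputs,
        timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(manifest)
}

.inputDigests <- function(matrixPath, labelsPath) {
    paths <- c(matrix = matrixPath, labels = labelsPath)
    if (is.null(matrixPath)) return(list(source = "in-memory dataset"))
    as.list(tools::md5sum(paths))
}

#' Simulate a dataset to disk
#'
#' Writes a synthetic dataset (see [simulateExpressionData()]) in the
#' standard matrix/labels text format, plus a `truth.json` listing the
#' planted gene identifiers and the generating parameters.
#'
#' @param outDir output directory (created if missing).
#' @param ... passed to [simulateExpressionData()].
#' @return Invisibly, a named character vector of the three file paths.
#' @export
simulateToFiles <- function(outDir = ".", ...) {
    sim <- simulateExpressionData(...)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(matrix = file.path(outDir, "expression.tsv"),
               labels = file.path(outDir, "labels.tsv"),
               truth = file.path(outDir, "truth.json"))
    writeExpressionDataset(sim$experiment, paths[["matrix"]],
                           paths[["labels"]])
    jsonlite::write_json(
        list(plantedGenes = probeIds(sim$experiment)[sim$planted],
             plantedIndices = sim$planted,
             spec = sim$spec),
        paths[["truth"]], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
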