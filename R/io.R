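#' Read an expression matrix and labels from delimited text
#'
#' Loads a genes-by-samples expression matrix (first column = probe
#' identifier, header row = sample identifiers) together with a two-column
#' label file mapping sample identifiers to classes 1/2, and returns a
#' validated [PhenotypeExperiment-class]. The delimiter is auto-detected
#' from the file extension (`.csv` = comma, anything else = tab).
#'
#' Samples present in the matrix but absent from the label file are dropped
#' with a warning; label entries without a matrix column are an error. No
#' normalisation is performed: values are assumed already normalised
#' (typically log2 scale).
#'
#' @param matrixPath path to the expression matrix file.
#' @param labelsPath path to the label file (`sample_id<TAB>class`, with or
#'   without a header row).
#' @param log2Transform if `TRUE`, apply `log2(x + 1)` to the values after
#'   loading (for matrices supplied on the linear scale). Default `FALSE`.
#' @param impute `"reject"` (default) errors on any missing cell;
#'   `"class-mean"` replaces a missing cell by the gene's mean within the
#'   sample's class.
#' @return A [PhenotypeExperiment-class].
#' @seealso [writeExpressionDataset()] for the inverse.
#' @export
readExpressionDataset <- function(matrixPath, labelsPath,
                                  log2Transform = FALSE,
                                  impute = c("reject", "class-mean")) {
    impute <- match.arg(impute)
    sep <- .sepFor(matrixPath)
    raw <- utils::read.table(matrixPath, sep = sep, header = TRUE,
                             check.names = FALSE, quote = "",
                             comment.char = "", stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(raw) < 2L)
        stop("expression matrix needs a probe column and >= 1 sample column")
    probes <- raw[[1L]]
    if (anyDuplicated(probes))
        stop("duplicated probe identifier(s): ",
             paste(unique(probes[duplicated(probes)]), collapse = ", "))
    sampleIds <- colnames(raw)[-1L]
    values <- matrix(NA_real_, nrow(raw), length(sampleIds),
                     dimnames = list(probes, sampleIds))
    for (j in seq_along(sampleIds)) {
        cell <- raw[[j + 1L]]
        num <- suppressWarnings(as.numeric(cell))
        bad <- is.na(num) & !(is.na(cell) | cell %in% c("", "NA"))
        if (any(bad))
            stop(sprintf("non-numeric value '%s' at probe '%s', sample '%s'",
                         cell[which(bad)[1L]], probes[which(bad)[1L]],
                         sampleIds[j]))
        values[, j] <- num
    }

    labels <- .readLabels(labelsPath)
    unknown <- setdiff(names(labels), sampleIds)
    if (length(unknown))
        stop("label file lists samples absent from the matrix: ",
             paste(unknown, collapse = ", "))
    unlabeled <- setdiff(sampleIds, names(labels))
    if (length(unlabeled)) {
        warning("dropping ", length(unlabeled),
                " unlabeled sample(s): ", paste(unlabeled, collapse = ", "))
        values <- values[, setdiff(sampleIds, unlabeled), drop = FALSE]
    }
    labels <- labels[colnames(values)]
    if (length(unique(labels)) < 2L)
        stop("both classes required in the label file")

    if (anyNA(values)) {
        if (impute == "reject") {
            bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
            stop(sprintf("missing value at probe '%s', sample '%s'",
                         rownames(values)[bad[1L]],
                         colnames(values)[bad[2L]]))
        }
        for (cls in c(1L, 2L)) {
            cols <- labels == cls
            sub <- values[, cols, drop = FALSE]
            mu <- rowMeans(sub, na.rm = TRUE)
            idx <- which(is.na(sub), arr.ind = TRUE)
            if (nrow(idx)) sub[idx] <- mu[idx[, 1L]]
            values[, cols] <- sub
        }
        if (anyNA(values))
            stop("imputation failed: a gene has no observed value in a class")
    }
    if (log2Transform)
        values <- log2(values + 1)
    PhenotypeExperiment(values, labels)
}

.sepFor <- function(path) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.readLabels <- function(path) {
    tab <- utils::read.table(path, sep = .sepFor(path), header = FALSE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "", colClasses = "character")
    if (ncol(tab) < 2L)
        stop("label file must have two columns: sample_id, class")
    # tolerate a header row
    if (!tab[1L, 2L] %in% c("1", "2"))
        tab <- tab[-1L, , drop = FALSE]
    if (!nrow(tab))
        stop("label file is empty")
    cls <- tab[[2L]]
    if (!all(cls %in% c("1", "2")))
        stop("class labels must be 1 or 2; offending value(s): ",
             paste(unique(cls[!cls %in% c("1", "2")]), collapse = ", "))
    if (anyDuplicated(tab[[1L]]))
        stop("duplicated sample identifier(s) in label file")
    stats::setNames(as.integer(cls), tab[[1L]])
}

#' Write an expression dataset to delimited text
#'
#' Serialises a [PhenotypeExperiment-class] to the matrix/label text format
#' read by [readExpressionDataset()]. Values are printed with 17
#' significant digits so a write/read round trip reproduces doubles
#' bit-exactly.
#'
#' @param x a [PhenotypeExperiment-class].
#' @param matrixPath,labelsPath output file paths; the matrix delimiter
#'   follows the extension (`.csv` = comma, else tab).
#' @return Invisibly, the two paths.
#' @export
writeExpressionDataset <- function(x, matrixPath, labelsPath) {
    stopifnot(is(x, "PhenotypeExperiment"))
    sep <- .sepFor(matrixPath)
    v <- exprsMatrix(x)
    con <- file(matrixPath, "w")
    on.exit(close(con))
    writeLines(paste(c("probe_id", colnames(v)), collapse = sep), con)
    body <- vapply(seq_len(nrow(v)), function(i) {
        paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = sep)
    }, character(1))
    writeLines(body, con)
    writeLines(paste(colnames(v), phenotypeLabels(x), sep = "\t"),
               labelsPath)
    invisible(c(matrixPath, labelsPath))
}

#' Write a posterior gene-frequency table
#'
#' Writes a [FrequencyTable-class] as a three-column TSV
#' (`probe_id`, `frequency`, `rank`), ordered by decreasing frequency with
#' ties broken by probe identifier.
#'
#' @param table a non-empty [FrequencyTable-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeFrequencyTable <- function(table, path) {
    stopifnot(is(table, "FrequencyTable"))
    if (!nrow(table))
        stop("frequency table is empty")
    out <- data.frame(probe_id = rownames(table),
                      frequency = sprintf("%.12g", table$frequency),
                      rank = table$rank)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("probe_id\tfrequency\trank", con)
    writeLines(do.call(paste, c(out, sep = "\t")), con)
    invisible(path)
}

#' Write retained signatures as JSON lines
#'
#' One JSON object per retained network:
#' `{"genes": [...], "accuracy": x, "sampler": "FRS", "iteration": i}`,
#' with genes given as probe identifiers.
#'
#' @param result a [SamplerResult-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeSignatures <- function(result, path) {
    stopifnot(is(result, "SamplerResult"))
    iter <- result@extras$iteration
    if (is.null(iter)) iter <- seq_along(result@signatures)
    lines <- vapply(seq_along(result@signatures), function(i) {
        jsonlite::toJSON(list(
            genes = result@probeIds[result@signatures[[i]]],
            accuracy = result@accuracies[i],
            sampler = samplerName(result),
            iteration = iter[i]
        ), auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
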