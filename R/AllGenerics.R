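#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes: `phenotypeLabels`
#' returns the integer class labels (1/2) of a [PhenotypeExperiment];
#' `probeIds` the probe identifiers carried by an object; `geneIndices` the
#' dataset row indices of a gene list, signature or prior; `accuracy` the
#' accuracy (percent) attached to a result; `signatures` the retained
#' networks of a [SamplerResult]; `samplerName` its sampler tag; and
#' `accuracyProfile` the accuracy-vs-length profile of a
#' [MinimumScaleSignature].
#'
#' @param x an object of the documented classes.
#' @return See each method's class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("phenotypeLabels", function(x) standardGeneric("phenotypeLabels"))

#' @rdname accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname accessors
#' @export
setGeneric("geneIndices", function(x) standardGeneric("geneIndices"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setGeneric("accuracyProfile", function(x) standardGeneric("accuracyProfile"))

#' @rdname accessors
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))

#' @rdname accessors
#' @export
setGeneric("samplerName", function(x) standardGeneric("samplerName"))

#' @rdname accessors
#' @export
setGeneric("drawCounts", function(x) standardGeneric("drawCounts"))
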