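#' Accessors for CentroidSet
#'
#' @param x a [CentroidSet-class].
#' @return `centroidValues` the genes x centroids matrix; `centroidGenes`
#'   the signature gene ids; `centroidLabels` the centroid (cell-type)
#'   labels; `centroidProvenance` the provenance list.
#' @name centroid-accessors
NULL

#' @rdname centroid-accessors
#' @export
setGeneric("centroidValues", function(x) standardGeneric("centroidValues"))

#' @rdname centroid-accessors
#' @export
setGeneric("centroidGenes", function(x) standardGeneric("centroidGenes"))

#' @rdname centroid-accessors
#' @export
setGeneric("centroidLabels", function(x) standardGeneric("centroidLabels"))

#' @rdname centroid-accessors
#' @export
setGeneric("centroidProvenance", function(x) standardGeneric("centroidProvenance"))

#' @rdname centroid-accessors
setMethod("centroidValues", "CentroidSet", function(x) x@values)

#' @rdname centroid-accessors
setMethod("centroidGenes", "CentroidSet", function(x) rownames(x@values))

#' @rdname centroid-accessors
setMethod("centroidLabels", "CentroidSet", function(x) colnames(x@values))

#' @rdname centroid-accessors
setMethod("centroidProvenance", "CentroidSet", function(x) x@provenance)

#' Filter genes by across-sample variability
#'
#' Retains the `ceiling(keep_fraction * G)` genes of highest across-sample
#' variance, preserving the original gene order among survivors. This is the
#' unsupervised pre-filter applied before differential-expression ranking; it
#' uses no group labels, so it cannot bias the subsequent moderated-t tests.
#'
#' @param x a genes x samples numeric matrix or a
#'   [SummarizedExperiment::SummarizedExperiment-class].
#' @param keep_fraction fraction of genes to keep, in (0, 1].
#' @return An object of the same class as `x` with only the retained genes.
#' @examples
#' m <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("G", 1:10), paste0("S", 1:4)))
#' nrow(filterByVariability(m, 0.5))
#' @export
setGeneric("filterByVariability",
           function(x, keep_fraction = 0.5) standardGeneric("filterByVariability"))

#' Accessors for LDResult
#'
#' @param x an [LDResult-class].
#' @return `ldFrequency` the estimated frequency; `ldConfint` a length-2
#'   numeric of 95 percent bounds; `ldDegenerate` the degeneracy flag.
#' @name ld-accessors
NULL

#' @rdname ld-accessors
#' @export
setGeneric("ldFrequency", function(x) standardGeneric("ldFrequency"))

#' @rdname ld-accessors
#' @export
setGeneric("ldConfint", function(x) standardGeneric("ldConfint"))

#' @rdname ld-accessors
#' @export
setGeneric("ldDegenerate", function(x) standardGeneric("ldDegenerate"))

#' @rdname ld-accessors
setMethod("ldFrequency", "LDResult", function(x) x@frequency)

#' @rdname ld-accessors
setMethod("ldConfint", "LDResult",
          function(x) c(lower = x@ci_lower, upper = x@ci_upper))

#' @rdname ld-accessors
setMethod("ldDegenerate", "LDResult", function(x) x@degenerate)
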