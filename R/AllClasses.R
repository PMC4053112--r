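#' @import methods
NULL

#' Signature size specification
#'
#' Numbers of up- and downregulated genes to take from each pairwise
#' differential-expression comparison when assembling a signature.
#'
#' @slot n_up number of top upregulated genes per comparison.
#' @slot n_down number of top downregulated genes per comparison.
#' @export
setClass("SignatureSpec",
         representation(n_up = "integer", n_down = "integer"))

setValidity("SignatureSpec", function(object) {
  if (length(object@n_up) != 1L || length(object@n_down) != 1L)
    return("n_up and n_down must be single counts")
  if (is.na(object@n_up) || is.na(object@n_down) ||
      object@n_up < 0L || object@n_down < 0L)
    return("n_up and n_down must be nonnegative")
  TRUE
})

#' Create a SignatureSpec
#'
#' @param n_up,n_down nonnegative counts of up-/downregulated genes to select
#'   per pairwise comparison.
#' @return A [SignatureSpec-class] object.
#' @examples
#' SignatureSpec(250, 250)
#' @export
SignatureSpec <- function(n_up = 250, n_down = 250) {
  new("SignatureSpec", n_up = as.integer(n_up), n_down = as.integer(n_down))
}

setMethod("show", "SignatureSpec", function(object) {
  cat(sprintf("SignatureSpec: top %d up / %d down per comparison\n",
              object@n_up, object@n_down))
})

#' Cell-type centroid set
#'
#' A genes x centroids matrix of per-cell-type mean log2 expression over a
#' signature gene set, with a provenance record of how the signature was
#' assembled (signature sizes, pairwise comparisons, FDR cap).
#'
#' @slot values numeric matrix, signature genes (rows, named) by centroid
#'   labels (columns, named).
#' @slot provenance list recording signature specs and comparisons used.
#' @export
setClass("CentroidSet",
         representation(values = "matrix", provenance = "list"))

setValidity("CentroidSet", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 1L) return("values must be non-empty")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("gene ids (rownames) must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    return("centroid labels (colnames) must be present and unique")
  if (!all(is.finite(v))) return("all centroid values must be finite")
  TRUE
})

#' Create a CentroidSet
#'
#' @param values numeric matrix of mean log2 expression, genes (rownames) by
#'   centroid labels (colnames).
#' @param provenance optional list describing how the signature was built.
#' @return A [CentroidSet-class] object.
#' @export
CentroidSet <- function(values, provenance = list()) {
  new("CentroidSet", values = as.matrix(values), provenance = provenance)
}

setMethod("show", "CentroidSet", function(object) {
  cat(sprintf("CentroidSet: %d signature genes x %d centroids\n",
              nrow(object@values), ncol(object@values)))
  cat("  centroids:", paste(colnames(object@values), collapse = ", "), "\n")
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

#' Limiting-dilution transplant assay
#'
#' Dose-response table for one cell population: cells injected per transplant,
#' number of transplants tested, and number scoring positive (an outgrowth
#' with both lobular and ductal elements).
#'
#' @slot population population label.
#' @slot data data.frame with columns `dose`, `n_tested`, `n_positive`.
#' @export
setClass("LDAssay",
         representation(population = "character", data = "data.frame"))

setValidity("LDAssay", function(object) {
  d <- object@data
  if (!all(c("dose", "n_tested", "n_positive") %in% names(d)))
    return("data must have columns dose, n_tested, n_positive")
  if (nrow(d) < 1L) return("at least one dose row is required")
  if (any(!is.finite(d$dose)) || any(d$dose <= 0))
    return("all doses must be positive")
  if (any(d$n_tested < 1L)) return("n_tested must be >= 1")
  if (any(d$n_positive < 0L) || any(d$n_positive > d$n_tested))
    return("n_positive must satisfy 0 <= n_positive <= n_tested")
  if (length(object@population) != 1L) return("population must be a single label")
  TRUE
})

#' Create a limiting-dilution assay
#'
#' @param dose numeric vector of cells injected per transplant.
#' @param n_tested integer vector, transplants performed at each dose.
#' @param n_positive integer vector, transplants scoring positive.
#' @param population population label.
#' @return An [LDAssay-class] object.
#' @examples
#' LDAssay(dose = c(100, 1000), n_tested = c(6, 6), n_positive = c(1, 5))
#' @export
LDAssay <- function(dose, n_tested, n_positive, population = "population") {
  new("LDAssay", population = as.character(population),
      data = data.frame(dose = as.numeric(dose),
                        n_tested = as.integer(n_tested),
                        n_positive = as.integer(n_positive)))
}

setMethod("show", "LDAssay", function(object) {
  cat(sprintf("LDAssay '%s': %d dose levels, %d/%d transplants positive\n",
              object@population, nrow(object@data),
              sum(object@data$n_positive), sum(object@data$n_tested)))
})

#' Fitted single-hit Poisson limiting-dilution result
#'
#' @slot population population label.
#' @slot frequency estimated repopulating units per cell (MRU frequency).
#' @slot ci_lower,ci_upper 95 percent confidence bounds on the frequency.
#' @slot log_frequency_se standard error of log frequency (NA for degenerate
#'   tables).
#' @slot degenerate one of "none", "all_negative", "all_positive".
#' @export
setClass("LDResult",
         representation(population = "character", frequency = "numeric",
                        ci_lower = "numeric", ci_upper = "numeric",
                        log_frequency_se = "numeric", degenerate = "character"))

setValidity("LDResult", function(object) {
  if (!object@degenerate %in% c("none", "all_negative", "all_positive"))
    return("degenerate must be none, all_negative or all_positive")
  if (object@degenerate == "none") {
    if (!(object@ci_lower <= object@frequency &&
          object@frequency <= object@ci_upper))
      return("ci_lower <= frequency <= ci_upper must hold for non-degenerate fits")
  }
  if (is.finite(object@frequency) && object@frequency < 0)
    return("frequency must be nonnegative")
  TRUE
})

setMethod("show", "LDResult", function(object) {
  cat(sprintf("LDResult '%s' [%s]\n", object@population, object@degenerate))
  cat(sprintf("  frequency: %.4g (%s)\n", object@frequency,
              formatFrequency(object@frequency)))
  cat(sprintf("  95%% CI: %.4g - %.4g (%s - %s)\n",
              object@ci_lower, object@ci_upper,
              formatFrequency(object@ci_upper),  # upper f = fewer cells per unit
              formatFrequency(object@ci_lower)))
})

#' qPCR plate with triplicate Ct values
#'
#' Holds well-level cycle-threshold measurements for (sample, gene) pairs,
#' the two housekeeping genes used for normalization, the comparator sample,
#' and optional no-template-control wells (NA Ct = no amplification).
#'
#' @slot wells data.frame with columns `sample`, `gene`, `ct`, `well_type`
#'   (`"sample"` or `"ntc"`).
#' @slot housekeepers exactly two housekeeping gene labels.
#' @slot comparator comparator sample label (relative quantity 1 by
#'   definition).
#' @export
setClass("QPCRPlate",
         representation(wells = "data.frame", housekeepers = "character",
                        comparator = "character"))

setValidity("QPCRPlate", function(object) {
  w <- object@wells
  if (!all(c("sample", "gene", "ct", "well_type") %in% names(w)))
    return("wells must have columns sample, gene, ct, well_type")
  if (!all(w$well_type %in% c("sample", "ntc")))
    return("well_type must be 'sample' or 'ntc'")
  if (length(object@housekeepers) != 2L ||
      anyDuplicated(object@housekeepers))
    return("exactly two distinct housekeeping genes are required")
  sw <- w[w$well_type == "sample", , drop = FALSE]
  if (nrow(sw) < 1L) return("at least one sample well is required")
  if (any(!is.finite(sw$ct))) return("sample wells must have finite Ct values")
  if (length(object@comparator) != 1L ||
      !object@comparator %in% sw$sample)
    return("comparator sample must be present on the plate")
  samples <- unique(sw$sample)
  for (hk in object@housekeepers) {
    have <- unique(sw$sample[sw$gene == hk])
    miss <- setdiff(samples, have)
    if (length(miss))
      return(sprintf("housekeeping gene '%s' missing for sample(s): %s",
                     hk, paste(miss, collapse = ", ")))
  }
  TRUE
})

#' Create a qPCR plate
#'
#' @param wells data.frame with columns `sample`, `gene`, `ct`, and
#'   optionally `well_type` (defaults to `"sample"`); NTC wells use
#'   `well_type = "ntc"` and may carry `NA` Ct for no amplification.
#' @param housekeepers character(2), the housekeeping genes.
#' @param comparator comparator sample label.
#' @return A [QPCRPlate-class] object.
#' @export
QPCRPlate <- function(wells, housekeepers, comparator) {
  wells <- as.data.frame(wells)
  if (is.null(wells$well_type)) wells$well_type <- "sample"
  wells$sample <- as.character(wells$sample)
  wells$gene <- as.character(wells$gene)
  wells$ct <- as.numeric(wells$ct)
  wells$well_type <- as.character(wells$well_type)
  new("QPCRPlate", wells = wells, housekeepers = as.character(housekeepers),
      comparator = as.character(comparator))
}

setMethod("show", "QPCRPlate", function(object) {
  sw <- object@wells[object@wells$well_type == "sample", ]
  cat(sprintf("QPCRPlate: %d samples x %d genes (%d wells, %d NTC wells)\n",
              length(unique(sw$sample)), length(unique(sw$gene)), nrow(sw),
              sum(object@wells$well_type == "ntc")))
  cat("  housekeepers:", paste(object@housekeepers, collapse = ", "),
      "| comparator:", object@comparator, "\n")
})
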