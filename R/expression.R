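#' Declared cell-type label sets
#'
#' The sorted mammary subpopulations profiled in each species. Human: basal,
#' stromal, nonclonogenic luminal (NCL) and the three luminal-progenitor (LP)
#' subtypes ALDH_neg, ALDH_pos, ERBB3_neg. Mouse: NCL, ER+ and ER- luminal
#' progenitors, basal.
#'
#' @return Character vector of cell-type labels; the `lp` attribute marks the
#'   LP-subtype subset.
#' @examples
#' humanCellTypes()
#' @export
humanCellTypes <- function() {
  structure(c("NCL", "ALDH_neg", "ALDH_pos", "ERBB3_neg", "basal", "stromal"),
            lp = c("ALDH_neg", "ALDH_pos", "ERBB3_neg"))
}

#' @rdname humanCellTypes
#' @export
mouseCellTypes <- function() {
  structure(c("NCL", "ER_pos_prog", "ER_neg_prog", "basal"),
            lp = c("ER_pos_prog", "ER_neg_prog"))
}

.sepForPath <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene-by-sample log-expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of gene ids; values
#' are log2-scale expression. Duplicate gene ids are collapsed by per-gene
#' mean with a warning. Missing or non-numeric cells are load errors that
#' name the offending gene/sample.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return A numeric matrix, genes x samples.
#' @export
readExpressionMatrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  sep <- .sepForPath(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty or malformed expression file: ", path, call. = FALSE)
  genes <- as.character(raw[[1L]])
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      if (is.na(bad)) bad <- which(is.na(col))[1L]
      stop(sprintf("non-numeric entry for gene '%s', sample '%s'",
                   genes[bad], names(vals)[j]), call. = FALSE)
    }
    if (anyNA(col)) {
      bad <- which(is.na(col))[1L]
      stop(sprintf("missing value for gene '%s', sample '%s'",
                   genes[bad], names(vals)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(sprintf("collapsing %d duplicated gene id(s) by mean: %s",
                    length(dup), paste(utils::head(dup, 5L), collapse = ", ")),
            call. = FALSE)
    m <- rowsum(m, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(m) <- genes
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample ids in header", call. = FALSE)
  m
}

#' Write a gene-by-sample matrix as delimited text
#'
#' @param m numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(m, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample annotations from delimited text
#'
#' Two or three columns: `sample_id`, `cell_type` and optionally `cohort`.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return data.frame with columns `sample_id`, `cell_type`, `cohort`.
#' @export
readSampleAnnotation <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  sep <- .sepForPath(path, sep)
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "cell_type") %in% names(ann)))
    stop("annotation must have columns sample_id and cell_type", call. = FALSE)
  if (is.null(ann$cohort)) ann$cohort <- NA_character_
  ann[, c("sample_id", "cell_type", "cohort")]
}

#' Assemble an annotated expression experiment
#'
#' Combines a validated log2 expression matrix with per-sample cell-type
#' annotations into a `SummarizedExperiment` (assay `"exprs"`, colData
#' columns `cell_type` and `cohort`). Every annotated sample must exist in
#' the matrix and every cell-type label must come from the declared set.
#'
#' @param m genes x samples numeric matrix.
#' @param annotation data.frame as returned by [readSampleAnnotation()], or a
#'   character vector of cell types named by (or ordered as) the samples.
#' @param label_set allowed cell-type labels; defaults to [humanCellTypes()].
#'   Use [mouseCellTypes()] or a custom vector for other designs.
#' @return A [SummarizedExperiment::SummarizedExperiment-class].
#' @export
ExpressionExperiment <- function(m, annotation, label_set = humanCellTypes()) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("'m' must be a numeric matrix", call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("at least 2 genes and 2 samples are required", call. = FALSE)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("gene ids must be present and unique", call. = FALSE)
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("sample ids must be present and unique", call. = FALSE)
  if (anyNA(m)) stop("expression matrix contains missing values", call. = FALSE)
  if (is.character(annotation)) {
    annotation <- data.frame(
      sample_id = names(annotation) %||% colnames(m),
      cell_type = unname(annotation), cohort = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (is.null(annotation$cohort)) annotation$cohort <- NA_character_
  missing_s <- setdiff(annotation$sample_id, colnames(m))
  if (length(missing_s))
    stop("annotated sample(s) absent from matrix: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(annotation$cell_type), label_set)
  if (length(bad))
    stop("cell type(s) not in the declared label set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  idx <- match(colnames(m), annotation$sample_id)
  if (anyNA(idx))
    stop("sample(s) without annotation: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  cd <- S4Vectors::DataFrame(cell_type = annotation$cell_type[idx],
                             cohort = annotation$cohort[idx],
                             row.names = colnames(m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m), colData = cd)
}

#' @rdname cellTypes
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' Cell-type labels of an expression experiment
#'
#' @param x a `SummarizedExperiment` built by [ExpressionExperiment()].
#' @return Character vector of per-sample cell-type labels, named by sample.
#' @name cellTypes
#' @export
setMethod("cellTypes", "SummarizedExperiment", function(x) {
  ct <- SummarizedExperiment::colData(x)$cell_type
  if (is.null(ct)) stop("no 'cell_type' column in colData", call. = FALSE)
  stats::setNames(as.character(ct), colnames(x))
})

.exprs <- function(x) {
  if (is.matrix(x)) return(x)
  SummarizedExperiment::assay(x, "exprs")
}

.filterIdx <- function(m, keep_fraction) {
  .assertScalarFraction(keep_fraction, "keep_fraction")
  if (ncol(m) < 2L) stop("at least 2 samples are required", call. = FALSE)
  v <- .rowVars(m)
  keep_n <- ceiling(keep_fraction * nrow(m))
  ## order() is stable: ties at the cut keep the earlier gene in input order
  sort(order(-v)[seq_len(keep_n)])
}

#' @rdname filterByVariability
setMethod("filterByVariability", "matrix", function(x, keep_fraction = 0.5) {
  x[.filterIdx(x, keep_fraction), , drop = FALSE]
})

#' @rdname filterByVariability
setMethod("filterByVariability", "SummarizedExperiment",
          function(x, keep_fraction = 0.5) {
  x[.filterIdx(.exprs(x), keep_fraction), ]
})
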