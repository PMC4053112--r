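## Cell-type centroid construction over signature gene sets.

#' Average expression of one cell type over a gene set
#'
#' The centroid of a cell type is the per-gene arithmetic mean of log2
#' expression across the samples annotated with that type, restricted to the
#' requested genes.
#'
#' @param x annotated `SummarizedExperiment` (see [ExpressionExperiment()]).
#' @param cell_type cell-type label; at least one sample required.
#' @param genes gene ids to restrict to; default all genes.
#' @return Named numeric vector, one mean per gene.
#' @export
buildCentroid <- function(x, cell_type, genes = NULL) {
  m <- .exprs(x)
  ct <- cellTypes(x)
  sel <- which(ct == cell_type)
  if (!length(sel))
    stop(sprintf("no samples of cell type '%s'", cell_type), call. = FALSE)
  genes <- genes %||% rownames(m)
  missing_g <- setdiff(genes, rownames(m))
  if (length(missing_g))
    stop("requested gene(s) absent from matrix: ",
         paste(utils::head(missing_g, 5L), collapse = ", "), call. = FALSE)
  rowMeans(m[genes, sel, drop = FALSE])
}

## Relabel LP subtypes as one pooled "LP" group on a copy of the colData.
.poolLP <- function(x, lp_types, pooled_label = "LP") {
  ct <- cellTypes(x)
  ct[ct %in% lp_types] <- pooled_label
  SummarizedExperiment::colData(x)$cell_type <- unname(ct)
  x
}

.centroidMatrix <- function(x, groups, genes, labels = groups) {
  vals <- vapply(groups, function(g) buildCentroid(x, g, genes),
                 numeric(length(genes)))
  colnames(vals) <- labels
  rownames(vals) <- genes
  vals
}

#' Build the first-level (major) centroid set
#'
#' Assembles the major signature as the union of top `spec@n_up` up / top
#' `spec@n_down` down genes (default 250/250) over all six pairwise
#' comparisons among four reference groups -- luminal (the NCL population),
#' basal, stromal, and the LP subtypes pooled as one group -- then averages
#' expression per group over that signature. The pooled-LP centroid is
#' labelled `LP_combined`.
#'
#' @param x annotated `SummarizedExperiment`; each reference group needs
#'   >= 2 samples.
#' @param spec a [SignatureSpec-class] for the pairwise comparisons.
#' @param lp_types labels of the LP subtypes to pool; default from the
#'   `lp` attribute of [humanCellTypes()].
#' @param luminal_type the mature-luminal reference population.
#' @param other_types remaining first-level reference types.
#' @param fdr_cap q-value cap each signature gene must pass.
#' @return A [CentroidSet-class] with centroids for `luminal_type`,
#'   `other_types` and `LP_combined`, and provenance recording the
#'   comparisons.
#' @export
buildMajorCentroids <- function(x, spec = SignatureSpec(250, 250),
                                lp_types = attr(humanCellTypes(), "lp"),
                                luminal_type = "NCL",
                                other_types = c("basal", "stromal"),
                                fdr_cap = 0.05) {
  pooled <- .poolLP(x, lp_types)
  groups <- c(luminal_type, other_types, "LP")
  sig <- pairwiseSignatureUnion(pooled, groups, spec, fdr_cap)
  if (!length(sig))
    stop("empty signature: no genes passed selection in any comparison",
         call. = FALSE)
  comparisons <- attr(sig, "comparisons")
  sig <- as.vector(sig)
  labels <- c(luminal_type, other_types, "LP_combined")
  vals <- .centroidMatrix(pooled, groups, sig, labels)
  CentroidSet(vals, provenance = list(
    level = "major", n_up = spec@n_up, n_down = spec@n_down,
    fdr_cap = fdr_cap, lp_types = lp_types, luminal_type = luminal_type,
    comparisons = comparisons))
}

#' Build the LP-subtype centroid set
#'
#' The three LP subpopulations are more similar to each other than to any
#' other cell type, so their centroids use a dedicated signature: the union
#' of the top `spec@n_up` up / `spec@n_down` down genes (default 100/100)
#' for each of the three pairwise LP-subtype comparisons.
#'
#' @param x annotated `SummarizedExperiment`; each LP subtype needs >= 2
#'   samples.
#' @param spec a [SignatureSpec-class] for the LP comparisons.
#' @param lp_types the LP subtype labels.
#' @param fdr_cap q-value cap each signature gene must pass.
#' @return A [CentroidSet-class] with one centroid per LP subtype.
#' @export
buildLPCentroids <- function(x, spec = SignatureSpec(100, 100),
                             lp_types = attr(humanCellTypes(), "lp"),
                             fdr_cap = 0.05) {
  sig <- pairwiseSignatureUnion(x, lp_types, spec, fdr_cap)
  if (!length(sig))
    stop("empty signature: LP subtypes are indistinguishable at this FDR cap",
         call. = FALSE)
  comparisons <- attr(sig, "comparisons")
  sig <- as.vector(sig)
  vals <- .centroidMatrix(x, lp_types, sig)
  CentroidSet(vals, provenance = list(
    level = "lp", n_up = spec@n_up, n_down = spec@n_down, fdr_cap = fdr_cap,
    comparisons = comparisons))
}

#' Read / write a centroid set as delimited text
#'
#' The table has a `gene_id` first column and one column per centroid.
#' Provenance, when present, travels in a JSON sidecar at
#' `<path>.provenance.json`.
#'
#' @param x a [CentroidSet-class] (for writing).
#' @param path file path.
#' @param sep field separator.
#' @return `writeCentroidSet`: `path`, invisibly. `readCentroidSet`: a
#'   [CentroidSet-class].
#' @export
writeCentroidSet <- function(x, path, sep = "\t") {
  df <- data.frame(gene_id = centroidGenes(x), centroidValues(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  prov <- centroidProvenance(x)
  if (length(prov))
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname writeCentroidSet
#' @export
readCentroidSet <- function(path, sep = NULL) {
  m <- readExpressionMatrix(path, sep)
  prov_path <- paste0(path, ".provenance.json")
  prov <- if (file.exists(prov_path))
    jsonlite::read_json(prov_path, simplifyVector = TRUE) else list()
  CentroidSet(m, provenance = as.list(prov))
}
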