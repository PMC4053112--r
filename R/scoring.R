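## Tumour scoring against centroids: Pearson correlation via unit-variance
## regression, mixture decomposition (partial correlations), the two-level
## nearest-centroid decision tree, and intrinsic subtyping.

#' Center and scale a vector to unit variance
#'
#' @param v numeric vector of length >= 2 with nonzero variance.
#' @param id label used in the zero-variance error message.
#' @return Vector with mean 0 and sample variance 1.
#' @export
zscale <- function(v, id = "profile") {
  if (length(v) < 2L)
    stop("zscale requires at least 2 values", call. = FALSE)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop(sprintf("zero variance in '%s': cannot scale to unit variance", id),
         call. = FALSE)
  (v - mean(v)) / s
}

.tumorMatrix <- function(t) {
  if (is.numeric(t) && is.null(dim(t))) {
    t <- matrix(t, ncol = 1L, dimnames = list(names(t), "tumor"))
  }
  if (is.null(rownames(t))) stop("tumour profiles need gene ids", call. = FALSE)
  t
}

.centroidMat <- function(c) if (is(c, "CentroidSet")) centroidValues(c) else c

.sharedGenes <- function(tumor_genes, cmat, min_overlap) {
  shared <- intersect(tumor_genes, rownames(cmat))
  frac <- length(shared) / nrow(cmat)
  if (frac < min_overlap)
    stop(sprintf(
      "insufficient gene overlap: %.1f%% of %d signature genes (minimum %.0f%%)",
      100 * frac, nrow(cmat), 100 * min_overlap), call. = FALSE)
  shared
}

#' Pearson correlation scores of tumours against centroids
#'
#' Each tumour profile and each centroid profile is scaled to unit variance
#' over their shared genes; the simple-regression coefficient of the scaled
#' tumour on each scaled centroid is then numerically the Pearson
#' correlation. Scores are comparable across centroids and tumours.
#'
#' @param t tumour profile: named numeric vector, or genes x tumours matrix.
#' @param c a [CentroidSet-class] (or genes x centroids matrix).
#' @param min_overlap minimum fraction of the signature genes that must be
#'   present among the tumour's genes.
#' @return Numeric matrix, tumours x centroids, of correlations in \[-1, 1\].
#' @export
correlationScores <- function(t, c, min_overlap = 0.5) {
  tm <- .tumorMatrix(t)
  cm <- .centroidMat(c)
  shared <- .sharedGenes(rownames(tm), cm, min_overlap)
  n <- length(shared)
  zc <- apply(cm[shared, , drop = FALSE], 2L, zscale, id = "centroid")
  ids <- colnames(tm) %||% paste0("tumor", seq_len(ncol(tm)))
  zt <- vapply(seq_len(ncol(tm)),
               function(j) zscale(tm[shared, j], id = ids[j]), numeric(n))
  scores <- crossprod(zt, zc) / (n - 1)
  rownames(scores) <- ids
  scores
}

#' Mixture decomposition of tumours over all centroids
#'
#' Models each tumour as an explicit mixture of the normal cell-type
#' centroids: ordinary least squares of the unit-variance tumour on all
#' unit-variance centroids jointly (no intercept; all inputs are centered by
#' scaling). Each standardized coefficient reflects the association with one
#' centroid after accounting for the others; the corresponding partial
#' correlation is recovered exactly from the coefficient's t statistic as
#' `r_k = t_k / sqrt(t_k^2 + df)` with `df = n_genes - K`.
#'
#' @inheritParams correlationScores
#' @return List with `coefficients` and `partial_correlations` (both
#'   tumours x centroids matrices), `df` (residual degrees of freedom) and
#'   `genes_used`.
#' @export
mixtureScores <- function(t, c, min_overlap = 0.5) {
  tm <- .tumorMatrix(t)
  cm <- .centroidMat(c)
  shared <- .sharedGenes(rownames(tm), cm, min_overlap)
  n <- length(shared)
  K <- ncol(cm)
  if (n <= K + 1L)
    stop("need more shared genes than centroids + 1 for the mixture fit",
         call. = FALSE)
  Z <- apply(cm[shared, , drop = FALSE], 2L, zscale, id = "centroid")
  qrZ <- qr(Z)
  if (qrZ$rank < K) {
    dep <- colnames(Z)[qrZ$pivot[(qrZ$rank + 1L):K]]
    stop("collinear centroid column(s): ", paste(dep, collapse = ", "),
         call. = FALSE)
  }
  XtXinv <- chol2inv(qr.R(qrZ))
  df <- n - K
  ids <- colnames(tm) %||% paste0("tumor", seq_len(ncol(tm)))
  coefs <- pcors <- matrix(NA_real_, ncol(tm), K,
                           dimnames = list(ids, colnames(cm)))
  for (j in seq_len(ncol(tm))) {
    y <- zscale(tm[shared, j], id = ids[j])
    beta <- qr.coef(qrZ, y)
    rss <- sum((y - Z %*% beta)^2)
    sigma2 <- rss / df
    se <- sqrt(pmax(sigma2, 0) * diag(XtXinv))
    tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
    coefs[j, ] <- beta
    pcors[j, ] <- ifelse(is.finite(tstat), tstat / sqrt(tstat^2 + df),
                         sign(tstat))
  }
  list(coefficients = coefs, partial_correlations = pcors, df = df,
       genes_used = n)
}

## Fixed ascending tie-priority: in an exact tie the later label wins.
.argmaxWithPriority <- function(scores, priority) {
  mx <- max(scores)
  tied <- names(scores)[scores == mx]
  tie <- length(tied) > 1L
  win <- tied[which.max(match(tied, priority))]
  list(label = win, tie = tie)
}

#' Two-level nearest-centroid decision-tree classification
#'
#' Level 1 assigns each tumour to stromal, basal, luminal or LP by the
#' nearest-centroid rule on the Pearson correlation scores against the major
#' centroids. Tumours assigned to LP are then assigned a further LP subtype
#' by the same rule against the LP-subtype centroids, computed on the LP
#' signature. Exact ties are broken by a fixed ascending priority
#' (stromal < basal < luminal < LP; ALDH_neg < ALDH_pos < ERBB3_neg, the
#' later label winning) and flagged.
#'
#' @param t tumour profiles (named vector or genes x tumours matrix).
#' @param major a [CentroidSet-class] from [buildMajorCentroids()].
#' @param lp a [CentroidSet-class] from [buildLPCentroids()].
#' @param min_overlap minimum signature overlap fraction per level.
#' @param luminal_type centroid label interpreted as the luminal class.
#' @return data.frame with columns `tumor_id`, `level1` (stromal / basal /
#'   luminal / LP), `level2` (LP subtype, NA unless `level1 == "LP"`),
#'   `tie_flag`, `genes_used_level1`, `genes_used_level2`.
#' @export
classifyDecisionTree <- function(t, major, lp, min_overlap = 0.5,
                                 luminal_type = "NCL") {
  tm <- .tumorMatrix(t)
  s1 <- correlationScores(tm, major, min_overlap)
  label_map <- stats::setNames(colnames(s1), colnames(s1))
  label_map[luminal_type] <- "luminal"
  label_map["LP_combined"] <- "LP"
  colnames(s1) <- unname(label_map[colnames(s1)])
  prio1 <- c("stromal", "basal", "luminal", "LP")
  prio2 <- c("ALDH_neg", "ALDH_pos", "ERBB3_neg")

  out <- data.frame(tumor_id = rownames(s1),
                    level1 = NA_character_, level2 = NA_character_,
                    tie_flag = FALSE,
                    genes_used_level1 = length(.sharedGenes(
                      rownames(tm), .centroidMat(major), min_overlap)),
                    genes_used_level2 = NA_integer_,
                    stringsAsFactors = FALSE)
  need_lp <- logical(nrow(s1))
  for (i in seq_len(nrow(s1))) {
    a <- .argmaxWithPriority(s1[i, ], prio1)
    out$level1[i] <- a$label
    out$tie_flag[i] <- a$tie
    need_lp[i] <- a$label == "LP"
  }
  if (any(need_lp)) {
    s2 <- correlationScores(tm[, need_lp, drop = FALSE], lp, min_overlap)
    prio2 <- unique(c(prio2, colnames(s2)))
    for (k in seq_len(nrow(s2))) {
      i <- which(need_lp)[k]
      a <- .argmaxWithPriority(s2[k, ], prio2)
      out$level2[i] <- a$label
      out$tie_flag[i] <- out$tie_flag[i] || a$tie
      out$genes_used_level2[i] <- length(.sharedGenes(
        rownames(tm), .centroidMat(lp), min_overlap))
    }
  }
  out
}

#' Assign intrinsic subtypes from a supplied SSP centroid table
#'
#' Nearest-centroid assignment by Pearson correlation over the genes shared
#' between tumour and the user-supplied single-sample-predictor (SSP)
#' centroid table (gene x subtype). Tumours carrying a precomputed
#' Claudin-low label keep it: that call is made externally and passes
#' through unchanged.
#'
#' @param t tumour profiles (named vector or genes x tumours matrix).
#' @param ssp SSP centroid table: [CentroidSet-class] or genes x subtypes
#'   matrix with subtype column labels.
#' @param claudin_low character vector of tumour ids with a precomputed
#'   Claudin-low assignment.
#' @param min_overlap minimum fraction of SSP genes that must be shared.
#' @return Named character vector of subtype labels, one per tumour.
#' @export
assignIntrinsicSubtype <- function(t, ssp, claudin_low = character(0),
                                   min_overlap = 0.5) {
  if (missing(ssp) || is.null(ssp))
    stop("an SSP centroid table must be supplied", call. = FALSE)
  tm <- .tumorMatrix(t)
  sc <- correlationScores(tm, ssp, min_overlap)
  lab <- colnames(sc)[max.col(sc, ties.method = "first")]
  names(lab) <- rownames(sc)
  lab[names(lab) %in% claudin_low] <- "Claudin-low"
  lab
}

#' Summarize correlation scores by intrinsic subtype
#'
#' Per (subtype, centroid) stratum: n, median, quartiles (type-7 quantiles),
#' minimum and maximum of the correlation scores. Strata with no tumours get
#' `n = 0` and NA statistics.
#'
#' @param scores tumours x centroids matrix from [correlationScores()].
#' @param subtypes subtype labels named by tumour id; every scored tumour
#'   must be labelled.
#' @return data.frame with one row per (subtype, centroid).
#' @export
summarizeBySubtype <- function(scores, subtypes) {
  ids <- rownames(scores)
  miss <- setdiff(ids, names(subtypes))
  if (length(miss))
    stop("tumour(s) without subtype label: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  subs <- sort(unique(as.character(subtypes[ids])))
  cents <- colnames(scores)
  rows <- expand.grid(subtype = subs, centroid = cents,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_one <- function(v) {
    if (!length(v)) return(c(n = 0, median = NA, q1 = NA, q3 = NA,
                             min = NA, max = NA))
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(n = length(v), median = qs[2L], q1 = qs[1L], q3 = qs[3L],
      min = min(v), max = max(v))
  }
  res <- t(mapply(function(s, cc) {
    stats_one(scores[subtypes[ids] == s, cc])
  }, rows$subtype, rows$centroid))
  cbind(rows, as.data.frame(res, row.names = seq_len(nrow(rows))))
}
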