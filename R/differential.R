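## Empirical-Bayes moderated two-sample t statistics, Storey q-values, and
## top-N signature selection.

.estimatePrior <- function(s2, d) {
  ## Moment matching on the scaled-F model for sample variances:
  ## log s^2 = log s0^2 + log chi^2_d/d - log chi^2_d0/d0 (independent),
  ## so E[e] and Var[e] of e = log s^2 - digamma(d/2) + log(d/2) identify
  ## (d0, s0^2) through digamma/trigamma relations.
  z <- log(s2)
  ok <- is.finite(z)
  if (sum(ok) < 2L) return(list(d0 = Inf, s0 = stats::median(s2)))
  e <- z[ok] - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigammaInverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(mean(e))
  }
  list(d0 = d0, s0 = s0)
}

.groupIdx <- function(m, group, name) {
  if (is.character(group)) {
    idx <- match(group, colnames(m))
    if (anyNA(idx))
      stop(sprintf("%s sample(s) absent from matrix: %s", name,
                   paste(group[is.na(idx)], collapse = ", ")), call. = FALSE)
  } else idx <- as.integer(group)
  if (length(idx) < 2L)
    stop(name, " must contain at least 2 samples", call. = FALSE)
  idx
}

#' Rank genes by empirical-Bayes moderated t between two groups
#'
#' Computes, per gene, the log2 fold change `mean(groupA) - mean(groupB)` and
#' a moderated t statistic whose pooled variance is shrunk towards a prior:
#' `s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)`, with the prior degrees of
#' freedom `d0` and prior variance `s0^2` estimated from the ensemble of
#' per-gene sample variances by moment matching on the scaled-F model
#' (digamma/trigamma relations). Two-sided p-values use the t distribution
#' with `d0 + d` degrees of freedom; q-values come from [estimateQvalues()].
#' A log-posterior-odds statistic (`b_stat`) is reported for a given prior
#' proportion of differentially expressed genes; for a shared design it is a
#' monotone function of `t_mod^2`, so ranking by `|t_mod|` and by `b_stat`
#' coincide.
#'
#' @param x genes x samples numeric matrix or `SummarizedExperiment`.
#' @param groupA,groupB disjoint sample id (or column index) vectors, each
#'   with at least 2 samples. "Upregulated" means higher in `groupA`.
#' @param prior_df override the estimated prior degrees of freedom `d0`
#'   (0 recovers the ordinary pooled t; `Inf` fully shrinks to `s0^2`).
#' @param prior_var override the estimated prior variance `s0^2`.
#' @param prior_prop assumed prior proportion of DE genes for `b_stat`.
#' @return data.frame with columns `gene_id`, `log_fold_change`, `t_mod`,
#'   `b_stat`, `p_value`, `q_value`, ranked by decreasing `|t_mod|`.
#' @export
rankDifferential <- function(x, groupA, groupB, prior_df = NULL,
                             prior_var = NULL, prior_prop = 0.01) {
  m <- .exprs(x)
  ia <- .groupIdx(m, groupA, "groupA")
  ib <- .groupIdx(m, groupB, "groupB")
  if (length(intersect(ia, ib)))
    stop("groups must be disjoint", call. = FALSE)
  a <- m[, ia, drop = FALSE]
  b <- m[, ib, drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  d <- nA + nB - 2
  lfc <- rowMeans(a) - rowMeans(b)
  s2 <- ((nA - 1) * .rowVars(a) + (nB - 1) * .rowVars(b)) / d
  vu <- 1 / nA + 1 / nB

  if (is.null(prior_df) || is.null(prior_var)) {
    est <- .estimatePrior(s2, d)
  } else est <- NULL
  d0 <- prior_df %||% est$d0
  s0 <- prior_var %||% est$s0
  if (d0 < 0) stop("prior_df must be nonnegative", call. = FALSE)

  stilde2 <- if (is.infinite(d0)) rep(s0, length(s2)) else
    if (d0 == 0) s2 else (d0 * s0 + d * s2) / (d0 + d)
  den <- sqrt(stilde2 * vu)
  t_mod <- ifelse(den > 0, lfc / den,
                  ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  q <- estimateQvalues(p)
  b <- .bStatistic(t_mod, df_total, vu, prior_prop)

  out <- data.frame(gene_id = rownames(m), log_fold_change = lfc,
                    t_mod = t_mod, b_stat = b, p_value = p, q_value = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-abs(out$t_mod)), , drop = FALSE]
}

## Log posterior odds of differential expression. The effect-variance ratio
## r = (v + v0)/v is estimated from the top prior_prop fraction of t^2 via
## E[t^2] = r * df/(df-2); shared across genes, so B is monotone in t^2.
.bStatistic <- function(t, df, vu, prior_prop) {
  t2 <- t^2
  t2f <- t2[is.finite(t2)]
  G <- length(t2)
  ntop <- max(1L, ceiling(prior_prop * G))
  scale_fac <- if (is.finite(df)) {
    if (df <= 2) return(rep(NA_real_, G))
    (df - 2) / df
  } else 1
  r <- if (length(t2f)) max(1, mean(sort(t2f, decreasing = TRUE)[
    seq_len(min(ntop, length(t2f)))]) * scale_fac) else 1
  kernel <- if (is.finite(df)) {
    (1 + df) / 2 * (log(t2 + df) - log(t2 / r + df))
  } else {
    (1 - 1 / r) * t2 / 2
  }
  ifelse(is.finite(t2),
         log(prior_prop / (1 - prior_prop)) - log(r) / 2 + kernel,
         Inf)
}

#' Storey q-values from a vector of p-values
#'
#' Estimates the null proportion as
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) * m))`, floored at
#' `pi0_floor` for stability on small gene sets, then computes
#' `q(p_(i)) = min_{j >= i} pi0 * m * p_(j) / j` on the sorted list and maps
#' back to input order. Forcing `pi0 = 1` recovers Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param lambda tuning parameter for the null-proportion estimate.
#' @param pi0 optional override of the estimated null proportion.
#' @param pi0_floor lower bound applied to the estimate (not to a supplied
#'   `pi0`).
#' @return Numeric vector of q-values, same order as `p`.
#' @examples
#' estimateQvalues(c(0.01, 0.2, 0.8), pi0 = 1)  # equals BH adjustment
#' @export
estimateQvalues <- function(p, lambda = 0.5, pi0 = NULL, pi0_floor = 0.05) {
  if (!length(p)) stop("p-value list must be nonempty", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
    pi0 <- max(pi0, pi0_floor)
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Select signature genes by the top-N up/down rule
#'
#' From a ranked differential-expression table, takes up to `n_up` genes with
#' the largest positive `t_mod` and up to `n_down` with the most negative,
#' each additionally required to pass `q_value < fdr_cap`. Fewer genes are
#' returned when the supply of qualifying genes is exhausted; an empty
#' selection is valid.
#'
#' @param results data.frame from [rankDifferential()].
#' @param spec a [SignatureSpec-class].
#' @param fdr_cap q-value threshold each selected gene must pass.
#' @return Character vector of selected gene ids.
#' @export
selectSignature <- function(results, spec = SignatureSpec(),
                            fdr_cap = 0.05) {
  stopifnot(is(spec, "SignatureSpec"))
  ok <- results$q_value < fdr_cap
  up <- results[ok & results$t_mod > 0, , drop = FALSE]
  up <- up[order(-up$t_mod), , drop = FALSE]
  down <- results[ok & results$t_mod < 0, , drop = FALSE]
  down <- down[order(down$t_mod), , drop = FALSE]
  c(utils::head(up$gene_id, spec@n_up),
    utils::head(down$gene_id, spec@n_down))
}

#' Union of signature genes over all pairwise cell-type comparisons
#'
#' Runs [rankDifferential()] + [selectSignature()] for every unordered pair
#' of the given cell-type labels and returns the union of selected genes.
#' The union is orientation-symmetric, so pair ordering does not matter.
#'
#' @param x annotated `SummarizedExperiment` (see [ExpressionExperiment()]).
#' @param types cell-type labels to compare; each needs >= 2 samples.
#' @param spec a [SignatureSpec-class] applied to every comparison.
#' @param fdr_cap q-value cap passed to [selectSignature()].
#' @param verbose log each comparison's selection size.
#' @return Character vector of signature gene ids with attribute
#'   `comparisons`: a data.frame recording each pair and its selection size.
#' @export
pairwiseSignatureUnion <- function(x, types, spec = SignatureSpec(),
                                   fdr_cap = 0.05, verbose = FALSE) {
  ct <- cellTypes(x)
  for (ty in types)
    if (sum(ct == ty) < 2L)
      stop(sprintf("cell type '%s' has fewer than 2 samples", ty),
           call. = FALSE)
  pairs <- utils::combn(types, 2L)
  genes <- character(0)
  rec <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    res <- rankDifferential(x, names(ct)[ct == a], names(ct)[ct == b])
    sel <- selectSignature(res, spec, fdr_cap)
    if (verbose)
      message(sprintf("comparison %s vs %s: %d signature genes", a, b,
                      length(sel)))
    rec[[k]] <- data.frame(typeA = a, typeB = b, n_selected = length(sel),
                           stringsAsFactors = FALSE)
    genes <- union(genes, sel)
  }
  structure(genes, comparisons = do.call(rbind, rec))
}

#' Write a differential-expression table as delimited text
#'
#' @param results data.frame from [rankDifferential()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeDETable <- function(results, path, sep = "\t") {
  utils::write.table(results, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
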