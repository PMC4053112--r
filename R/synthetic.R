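## Seeded generators for every input the pipeline consumes: a sorted-cell
## expression atlas with planted markers, tumour cohorts built as noisy
## convex mixtures of centroids, limiting-dilution assays, and qPCR plates.

#' Configuration for the synthetic sorted-cell expression atlas
#'
#' Defaults emulate the structure of the study design: ~2,000 genes, six
#' human cell types of which three are LP subtypes, five samples per type,
#' disjoint planted marker blocks. LP subtypes share a strong common marker
#' block (effect `major_effect`) and are separated from each other only by
#' weaker subtype-specific blocks (effect `lp_effect < major_effect`), so
#' the three LP subpopulations are mutually closer than to any other type.
#'
#' @param n_genes total genes.
#' @param cell_types all cell-type labels.
#' @param lp_types subset of `cell_types` forming the LP group.
#' @param samples_per_type samples per cell type.
#' @param marker_genes_per_type size of each planted marker block.
#' @param major_effect log2 elevation of type markers (non-LP types and the
#'   shared LP block).
#' @param lp_effect log2 elevation of LP-subtype-distinguishing markers;
#'   must be smaller than `major_effect`.
#' @param noise_sd per-gene independent Gaussian noise SD (log2 units).
#' @param baseline_mean baseline log2 expression.
#' @param seed RNG seed for [genCellAtlas()].
#' @return A validated config list of class `atlas_config`.
#' @export
atlasConfig <- function(n_genes = 2000,
                        cell_types = humanCellTypes(),
                        lp_types = attr(humanCellTypes(), "lp"),
                        samples_per_type = 5,
                        marker_genes_per_type = 50,
                        major_effect = 2,
                        lp_effect = 1,
                        noise_sd = 0.5,
                        baseline_mean = 7,
                        seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              cell_types = as.character(cell_types),
              lp_types = as.character(lp_types),
              samples_per_type = as.integer(samples_per_type),
              marker_genes_per_type = as.integer(marker_genes_per_type),
              major_effect = major_effect, lp_effect = lp_effect,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              seed = seed)
  if (cfg$lp_effect >= cfg$major_effect)
    stop("lp_effect must be smaller than major_effect", call. = FALSE)
  if (any(c(cfg$n_genes, cfg$samples_per_type,
            cfg$marker_genes_per_type) < 1L))
    stop("all counts must be positive", call. = FALSE)
  if (!all(cfg$lp_types %in% cfg$cell_types))
    stop("lp_types must be a subset of cell_types", call. = FALSE)
  n_blocks <- length(setdiff(cfg$cell_types, cfg$lp_types)) + 1L +
    length(cfg$lp_types)
  if (n_blocks * cfg$marker_genes_per_type > cfg$n_genes)
    stop("marker blocks exceed n_genes", call. = FALSE)
  structure(cfg, class = "atlas_config")
}

#' Generate a synthetic sorted-cell expression atlas
#'
#' Each cell type's mean vector is `baseline_mean` plus `major_effect` on
#' its marker block (the three LP subtypes share one such block, and are
#' additionally separated by subtype-specific blocks at `lp_effect`);
#' samples are the type mean plus independent Gaussian noise. Deterministic
#' under the config seed.
#'
#' @param cfg an [atlasConfig()].
#' @return List with `experiment` (annotated `SummarizedExperiment`),
#'   `markers` (named list of planted marker gene ids per type, plus
#'   `LP_shared`), and `means` (true genes x types mean matrix).
#' @export
genCellAtlas <- function(cfg = atlasConfig()) {
  stopifnot(inherits(cfg, "atlas_config"))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  types <- cfg$cell_types
  non_lp <- setdiff(types, cfg$lp_types)
  means <- matrix(cfg$baseline_mean, cfg$n_genes, length(types),
                  dimnames = list(genes, types))
  markers <- list()
  nb <- cfg$marker_genes_per_type
  block <- function(k) genes[((k - 1L) * nb + 1L):(k * nb)]
  k <- 1L
  for (ty in non_lp) {
    markers[[ty]] <- block(k)
    means[markers[[ty]], ty] <- means[markers[[ty]], ty] + cfg$major_effect
    k <- k + 1L
  }
  markers[["LP_shared"]] <- block(k)
  means[markers[["LP_shared"]], cfg$lp_types] <-
    means[markers[["LP_shared"]], cfg$lp_types] + cfg$major_effect
  k <- k + 1L
  for (ty in cfg$lp_types) {
    markers[[ty]] <- block(k)
    means[markers[[ty]], ty] <- means[markers[[ty]], ty] + cfg$lp_effect
    k <- k + 1L
  }

  m <- .withSeed(cfg$seed, {
    vals <- lapply(types, function(ty) {
      means[, ty] + matrix(stats::rnorm(cfg$n_genes * cfg$samples_per_type,
                                        sd = cfg$noise_sd),
                           cfg$n_genes, cfg$samples_per_type)
    })
    do.call(cbind, vals)
  })
  colnames(m) <- unlist(lapply(types, function(ty)
    paste0(ty, "_", seq_len(cfg$samples_per_type))))
  rownames(m) <- genes
  ann <- data.frame(sample_id = colnames(m),
                    cell_type = rep(types, each = cfg$samples_per_type),
                    cohort = "synthetic", stringsAsFactors = FALSE)
  list(experiment = ExpressionExperiment(m, ann, label_set = types),
       markers = markers, means = means)
}

#' Generate a synthetic tumour cohort as noisy centroid mixtures
#'
#' Each tumour is a convex mixture of the supplied centroids with one
#' designated dominant component of weight `dominant_weight` (the tumour's
#' true label), the remaining mass spread equally over the other centroids,
#' plus independent Gaussian noise.
#'
#' @param c a [CentroidSet-class] (or genes x centroids matrix) of the true
#'   generating centroids.
#' @param n_tumors number of tumours.
#' @param dominant_weight weight of the dominant component, in (0.5, 1].
#' @param noise_sd per-gene Gaussian noise SD (log2 units).
#' @param subtype_map optional named map from centroid label to intrinsic
#'   subtype label.
#' @param seed RNG seed.
#' @return List with `profiles` (genes x tumours matrix), `weights`
#'   (tumours x centroids), `labels` (true dominant centroid per tumour) and
#'   `subtypes` (via `subtype_map`, else NULL).
#' @export
genTumorCohort <- function(c, n_tumors = 200, dominant_weight = 0.7,
                           noise_sd = 0.5, subtype_map = NULL, seed = 1L) {
  cm <- .centroidMat(c)
  if (dominant_weight <= 0.5 || dominant_weight > 1)
    stop("dominant_weight must lie in (0.5, 1]", call. = FALSE)
  K <- ncol(cm)
  labels_all <- colnames(cm)
  .withSeed(seed, {
    dom <- sample(labels_all, n_tumors, replace = TRUE)
    w <- matrix((1 - dominant_weight) / max(1L, K - 1L), n_tumors, K,
                dimnames = list(NULL, labels_all))
    if (K == 1L) w[] <- 0
    w[cbind(seq_len(n_tumors), match(dom, labels_all))] <- dominant_weight
    profiles <- cm %*% t(w) +
      matrix(stats::rnorm(nrow(cm) * n_tumors, sd = noise_sd),
             nrow(cm), n_tumors)
    ids <- sprintf("T%03d", seq_len(n_tumors))
    colnames(profiles) <- ids
    rownames(w) <- ids
    list(profiles = profiles, weights = w,
         labels = stats::setNames(dom, ids),
         subtypes = if (!is.null(subtype_map))
           stats::setNames(unname(subtype_map[dom]), ids) else NULL)
  })
}

#' Generate a synthetic limiting-dilution assay
#'
#' Positives at dose d are binomial with success probability
#' `1 - exp(-true_f * d)` (single-hit Poisson model).
#'
#' @param true_f true repopulating-cell frequency (> 0).
#' @param doses cell doses.
#' @param reps transplants per dose.
#' @param population population label.
#' @param seed RNG seed.
#' @return An [LDAssay-class] with attribute `true_f`.
#' @export
genLDAssay <- function(true_f, doses, reps = 6, population = "synthetic",
                       seed = 1L) {
  stopifnot(true_f > 0, all(doses > 0), reps >= 1)
  pos <- .withSeed(seed,
    stats::rbinom(length(doses), reps, -expm1(-true_f * doses)))
  a <- LDAssay(doses, rep(reps, length(doses)), pos, population = population)
  attr(a, "true_f") <- true_f
  a
}

#' Generate a synthetic qPCR plate
#'
#' Target Ct for each sample equals the comparator's target Ct minus
#' `log2(true_rq)` plus noise; housekeeping Cts are constant plus noise;
#' wells are generated in triplicate. With `noise_sd = 0`, [ddct()] recovers
#' `true_rq` exactly.
#'
#' @param true_rq named positive vector of true relative quantities,
#'   including the comparator at exactly 1.
#' @param comparator comparator sample label (must be in `names(true_rq)`).
#' @param target target gene label.
#' @param housekeepers character(2) housekeeping gene labels.
#' @param hk_ct length-2 constant housekeeping Ct values.
#' @param target_ct comparator target Ct.
#' @param noise_sd per-well Gaussian Ct noise SD (cycles).
#' @param n_replicates wells per (sample, gene).
#' @param ntc include non-amplifying no-template-control wells.
#' @param seed RNG seed.
#' @return A [QPCRPlate-class].
#' @export
genQPCRPlate <- function(true_rq, comparator = names(true_rq)[1L],
                         target = "Target", housekeepers = c("HK1", "HK2"),
                         hk_ct = c(18, 20), target_ct = 24, noise_sd = 0,
                         n_replicates = 3, ntc = TRUE, seed = 1L) {
  if (is.null(names(true_rq)) || any(true_rq <= 0))
    stop("true_rq must be a named vector of positive relative quantities",
         call. = FALSE)
  if (!comparator %in% names(true_rq) ||
      abs(true_rq[[comparator]] - 1) > 1e-12)
    stop("the comparator must be present in true_rq with value 1",
         call. = FALSE)
  samples <- names(true_rq)
  genes <- c(target, housekeepers)
  true_ct <- function(s, g) {
    if (g == target) target_ct - log2(true_rq[[s]])
    else hk_ct[match(g, housekeepers)]
  }
  grid <- expand.grid(sample = samples, gene = genes,
                      rep = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  wells <- .withSeed(seed, {
    ct <- mapply(true_ct, grid$sample, grid$gene) +
      stats::rnorm(nrow(grid), sd = noise_sd)
    data.frame(sample = grid$sample, gene = grid$gene, ct = ct,
               well_type = "sample", stringsAsFactors = FALSE)
  })
  if (ntc) {
    wells <- rbind(wells, data.frame(
      sample = "NTC", gene = rep(genes, each = n_replicates), ct = NA_real_,
      well_type = "ntc", stringsAsFactors = FALSE))
  }
  QPCRPlate(wells, housekeepers = housekeepers, comparator = comparator)
}
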