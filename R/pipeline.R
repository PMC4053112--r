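## End-to-end orchestration: file-in/file-out stages composing the centroid,
## scoring, limiting-dilution and qPCR operations, each writing a
## machine-readable run manifest.

.writeManifest <- function(out_dir, stage, config, outputs) {
  manifest <- list(stage = stage,
                   config = config,
                   config_md5 = .md5OfObject(config),
                   outputs = as.list(tools::md5sum(outputs)))
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

.writeTable <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

#' Run the centroid-construction stage
#'
#' Reads an expression matrix and sample annotations, applies the
#' variability filter, builds the major and LP centroid sets, and writes
#' them (with provenance sidecars and a run manifest) to `out_dir`.
#'
#' @param expr path to the gene x sample log2 expression table.
#' @param annotation path to the sample annotation table.
#' @param out_dir output directory (created if needed).
#' @param keep_fraction variability-filter fraction.
#' @param major_spec,lp_spec [SignatureSpec-class]s for the two levels.
#' @param lp_types,luminal_type,other_types reference-group labels, as in
#'   [buildMajorCentroids()].
#' @param fdr_cap q-value cap for signature genes.
#' @param label_set allowed cell-type labels.
#' @return Invisibly, a named list of written file paths.
#' @export
runCentroidPipeline <- function(expr, annotation, out_dir,
                                keep_fraction = 0.5,
                                major_spec = SignatureSpec(250, 250),
                                lp_spec = SignatureSpec(100, 100),
                                lp_types = attr(humanCellTypes(), "lp"),
                                luminal_type = "NCL",
                                other_types = c("basal", "stromal"),
                                fdr_cap = 0.05,
                                label_set = humanCellTypes()) {
  if (!file.exists(annotation))
    stop("annotation file not found: ", annotation, call. = FALSE)
  m <- readExpressionMatrix(expr)
  ann <- readSampleAnnotation(annotation)
  se <- ExpressionExperiment(m, ann, label_set = label_set)
  se <- filterByVariability(se, keep_fraction)
  message(sprintf("variability filter kept %d of %d genes", nrow(se), nrow(m)))
  major <- buildMajorCentroids(se, major_spec, lp_types, luminal_type,
                               other_types, fdr_cap)
  lp <- buildLPCentroids(se, lp_spec, lp_types, fdr_cap)
  message(sprintf("major signature: %d genes; LP signature: %d genes",
                  length(centroidGenes(major)), length(centroidGenes(lp))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(major = file.path(out_dir, "major_centroids.tsv"),
             lp = file.path(out_dir, "lp_centroids.tsv"))
  writeCentroidSet(major, paths[["major"]])
  writeCentroidSet(lp, paths[["lp"]])
  cfg <- list(expr = expr, annotation = annotation,
              keep_fraction = keep_fraction,
              major_spec = c(major_spec@n_up, major_spec@n_down),
              lp_spec = c(lp_spec@n_up, lp_spec@n_down),
              lp_types = lp_types, luminal_type = luminal_type,
              other_types = other_types, fdr_cap = fdr_cap)
  manifest <- .writeManifest(out_dir, "centroids", cfg,
                             c(paths, paste0(paths, ".provenance.json")))
  invisible(c(as.list(paths), manifest = manifest))
}

#' Run the tumour-scoring stage
#'
#' Reads a tumour expression table and the two centroid sets, and writes
#' per-tumour level-1 correlation scores, mixture coefficients and partial
#' correlations, decision-tree assignments (with optional intrinsic
#' subtyping against a supplied SSP table), and, when subtypes are
#' available, a subtype-stratified score summary. Tumours failing the
#' overlap guard get error rows; the run continues.
#'
#' @param tumors path to the tumour gene x sample log2 expression table.
#' @param major_centroids,lp_centroids paths to centroid tables written by
#'   [runCentroidPipeline()].
#' @param out_dir output directory.
#' @param ssp optional path to an SSP centroid table (gene x subtype).
#' @param subtype_labels optional path to a two-column table
#'   (`tumor_id`, `subtype`) of precomputed intrinsic subtypes; tumours
#'   labelled `Claudin-low` keep that label.
#' @param min_overlap minimum signature overlap fraction.
#' @param luminal_type centroid label interpreted as luminal.
#' @return Invisibly, a named list of written file paths.
#' @export
runScoringPipeline <- function(tumors, major_centroids, lp_centroids,
                               out_dir, ssp = NULL, subtype_labels = NULL,
                               min_overlap = 0.5, luminal_type = "NCL") {
  tm <- readExpressionMatrix(tumors)
  major <- readCentroidSet(major_centroids)
  lp <- readCentroidSet(lp_centroids)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ids <- colnames(tm)
  one_tumor <- function(j) {
    tryCatch({
      prof <- tm[, j, drop = FALSE]
      sc <- correlationScores(prof, major, min_overlap)
      mx <- mixtureScores(prof, major, min_overlap)
      cl <- classifyDecisionTree(prof, major, lp, min_overlap, luminal_type)
      list(status = "ok", scores = sc[1L, ], coef = mx$coefficients[1L, ],
           pcor = mx$partial_correlations[1L, ], class = cl)
    }, error = function(e) list(status = paste0("error: ", conditionMessage(e))))
  }
  res <- lapply(seq_along(ids), one_tumor)
  ok <- vapply(res, function(r) identical(r$status, "ok"), logical(1L))
  labels <- centroidLabels(major)

  na_row <- stats::setNames(rep(NA_real_, length(labels)), labels)
  score_tab <- data.frame(
    tumor_id = ids,
    do.call(rbind, lapply(res, function(r) if (identical(r$status, "ok"))
      r$scores else na_row)),
    status = vapply(res, `[[`, character(1L), "status"),
    check.names = FALSE)
  mix_tab <- data.frame(
    tumor_id = ids,
    do.call(rbind, lapply(res, function(r) if (identical(r$status, "ok"))
      c(stats::setNames(r$coef, paste0("coef_", labels)),
        stats::setNames(r$pcor, paste0("pcor_", labels)))
      else stats::setNames(rep(NA_real_, 2 * length(labels)),
                           c(paste0("coef_", labels), paste0("pcor_", labels))))),
    status = vapply(res, `[[`, character(1L), "status"),
    check.names = FALSE)
  assign_tab <- do.call(rbind, lapply(seq_along(res), function(i) {
    r <- res[[i]]
    if (identical(r$status, "ok")) cbind(r$class, status = "ok")
    else data.frame(tumor_id = ids[i], level1 = NA, level2 = NA,
                    tie_flag = NA, genes_used_level1 = NA,
                    genes_used_level2 = NA, status = r$status)
  }))

  subtypes <- NULL
  if (!is.null(subtype_labels)) {
    st <- utils::read.table(subtype_labels, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    subtypes <- stats::setNames(st[[2L]], st[[1L]])
  }
  if (!is.null(ssp)) {
    ssp_set <- readCentroidSet(ssp)
    claudin <- names(subtypes)[subtypes == "Claudin-low"] %||% character(0)
    ssp_lab <- tryCatch(
      assignIntrinsicSubtype(tm[, ok, drop = FALSE], ssp_set,
                             claudin_low = claudin, min_overlap = min_overlap),
      error = function(e) NULL)
    if (!is.null(ssp_lab)) {
      assign_tab$intrinsic_subtype <- NA_character_
      assign_tab$intrinsic_subtype[match(names(ssp_lab), assign_tab$tumor_id)] <-
        unname(ssp_lab)
      if (is.null(subtypes)) subtypes <- ssp_lab
    }
  }

  paths <- c(scores = file.path(out_dir, "scores_level1.tsv"),
             mixture = file.path(out_dir, "mixture_scores.tsv"),
             assignments = file.path(out_dir, "assignments.tsv"))
  .writeTable(score_tab, paths[["scores"]])
  .writeTable(mix_tab, paths[["mixture"]])
  .writeTable(assign_tab, paths[["assignments"]])
  if (!is.null(subtypes) && any(ok)) {
    keep <- ids[ok][ids[ok] %in% names(subtypes)]
    if (length(keep)) {
      sc_ok <- correlationScores(tm[, keep, drop = FALSE], major, min_overlap)
      summ <- summarizeBySubtype(sc_ok, subtypes)
      paths <- c(paths, summary = file.path(out_dir, "subtype_summary.tsv"))
      .writeTable(summ, paths[["summary"]])
    }
  }
  cfg <- list(tumors = tumors, major_centroids = major_centroids,
              lp_centroids = lp_centroids, ssp = ssp,
              subtype_labels = subtype_labels, min_overlap = min_overlap,
              luminal_type = luminal_type)
  manifest <- .writeManifest(out_dir, "scoring", cfg, paths)
  invisible(c(as.list(paths), manifest = manifest))
}

#' Run the limiting-dilution stage
#'
#' Fits the single-hit Poisson model per population and writes a result
#' table carrying both the numeric frequency and its "1 in N" form.
#'
#' @param assays path to a table with columns `population`, `dose`,
#'   `n_tested`, `n_positive`.
#' @param out_dir output directory.
#' @param pop_sizes optional named population sizes; when given, MRU shares
#'   are added.
#' @param ci_method `"wald"` or `"lrt"`.
#' @return Invisibly, a named list of written file paths.
#' @export
runLD <- function(assays, out_dir, pop_sizes = NULL,
                  ci_method = c("wald", "lrt")) {
  ci_method <- match.arg(ci_method)
  al <- readLDAssays(assays)
  fits <- lapply(al, fitSingleHit, ci_method = ci_method)
  tab <- do.call(rbind, lapply(fits, function(r) data.frame(
    population = r@population, frequency = r@frequency,
    one_in = formatFrequency(r@frequency),
    ci_lower = r@ci_lower, ci_upper = r@ci_upper,
    one_in_lower = formatFrequency(r@ci_upper),
    one_in_upper = formatFrequency(r@ci_lower),
    log_frequency_se = r@log_frequency_se, degenerate = r@degenerate,
    stringsAsFactors = FALSE)))
  if (!is.null(pop_sizes)) {
    f <- vapply(fits, ldFrequency, numeric(1L))
    names(f) <- vapply(fits, function(r) r@population, character(1L))
    sh <- mruShare(f, pop_sizes)
    tab$mru_share <- unname(sh[tab$population])
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(results = file.path(out_dir, "ld_results.tsv"))
  .writeTable(tab, paths[["results"]])
  cfg <- list(assays = assays, ci_method = ci_method,
              pop_sizes = as.list(pop_sizes))
  manifest <- .writeManifest(out_dir, "ld", cfg, paths)
  invisible(c(as.list(paths), manifest = manifest))
}

#' Run the qPCR relative-quantification stage
#'
#' Reads a plate table, runs [ddct()] per target gene, and writes a table
#' with delta-Ct, delta-delta-Ct and RQ columns plus the NTC check result
#' when NTC wells are present.
#'
#' @param plate path to the plate table (`sample`, `gene`, `ct`,
#'   `well_type`).
#' @param out_dir output directory.
#' @param targets target gene label(s).
#' @param housekeepers character(2) housekeeping gene labels.
#' @param comparator comparator sample label.
#' @return Invisibly, a named list of written file paths.
#' @export
runQPCR <- function(plate, out_dir, targets, housekeepers, comparator) {
  p <- readQPCRPlate(plate, housekeepers, comparator)
  tabs <- lapply(targets, function(g) cbind(gene = g, ddct(p, g)))
  tab <- do.call(rbind, tabs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rq = file.path(out_dir, "qpcr_rq.tsv"))
  .writeTable(tab, paths[["rq"]])
  if (any(p@wells$well_type == "ntc")) {
    ntc <- ntcCheck(p)
    paths <- c(paths, ntc = file.path(out_dir, "qpcr_ntc.tsv"))
    .writeTable(data.frame(gene = names(ntc), pass = unname(ntc)),
                paths[["ntc"]])
  }
  cfg <- list(plate = plate, targets = targets, housekeepers = housekeepers,
              comparator = comparator)
  manifest <- .writeManifest(out_dir, "qpcr", cfg, paths)
  invisible(c(as.list(paths), manifest = manifest))
}
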