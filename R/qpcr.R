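## Delta-delta-Ct relative quantification with two-housekeeper normalization
## and no-template-control checks.

.meanCts <- function(plate, sd_cap = NULL) {
  w <- plate@wells[plate@wells$well_type == "sample", , drop = FALSE]
  agg <- stats::aggregate(ct ~ sample + gene, data = w,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(sample = agg$sample, gene = agg$gene,
                    ct = agg$ct[, "mean"], ct_sd = agg$ct[, "sd"],
                    n_reps = agg$ct[, "n"], stringsAsFactors = FALSE)
  if (!is.null(sd_cap)) {
    wide <- out[out$n_reps > 1L & is.finite(out$ct_sd) & out$ct_sd > sd_cap, ]
    if (nrow(wide))
      warning(sprintf(
        "replicate Ct spread above %.2g cycles for: %s", sd_cap,
        paste(sprintf("%s/%s (SD %.2f)", wide$sample, wide$gene, wide$ct_sd),
              collapse = ", ")), call. = FALSE)
  }
  out
}

#' Delta-delta-Ct relative quantification
#'
#' Ct values are averaged over replicates; per sample,
#' `dCt = Ct(target) - mean(Ct(hk1), Ct(hk2))` (arithmetic mean of the two
#' housekeeper Cts, i.e. the geometric mean of their expression levels),
#' `ddCt = dCt(sample) - dCt(comparator)`, and the relative quantity is
#' `RQ = 2^(-ddCt)` assuming doubling per cycle. The comparator sample has
#' RQ exactly 1.
#'
#' @param p a [QPCRPlate-class].
#' @param target target gene label, measured in every sample.
#' @param sd_cap replicate standard-deviation (cycles) above which a warning
#'   is emitted.
#' @return data.frame with columns `sample`, `delta_ct`, `delta_delta_ct`,
#'   `rq`.
#' @export
ddct <- function(p, target, sd_cap = 0.5) {
  stopifnot(is(p, "QPCRPlate"))
  cts <- .meanCts(p, sd_cap)
  samples <- unique(cts$sample)
  get_ct <- function(s, g) {
    v <- cts$ct[cts$sample == s & cts$gene == g]
    if (!length(v))
      stop(sprintf("gene '%s' not measured for sample '%s'", g, s),
           call. = FALSE)
    v
  }
  dct <- vapply(samples, function(s) {
    hk <- mean(c(get_ct(s, p@housekeepers[1L]), get_ct(s, p@housekeepers[2L])))
    get_ct(s, target) - hk
  }, numeric(1L))
  ddc <- dct - dct[[p@comparator]]
  data.frame(sample = samples, delta_ct = unname(dct),
             delta_delta_ct = unname(ddc), rq = unname(2^(-ddc)),
             stringsAsFactors = FALSE)
}

#' No-template-control check
#'
#' For every gene with NTC wells, fails if any amplifying NTC Ct comes
#' within `margin` cycles of the minimum sample Ct for that gene. An NTC
#' that did not amplify (NA Ct) passes.
#'
#' @param p a [QPCRPlate-class] with NTC wells.
#' @param margin required separation in cycles between NTC and the earliest
#'   sample Ct.
#' @return Named logical vector (`TRUE` = pass), one entry per checked gene.
#' @export
ntcCheck <- function(p, margin = 5) {
  stopifnot(is(p, "QPCRPlate"))
  ntc <- p@wells[p@wells$well_type == "ntc", , drop = FALSE]
  if (!nrow(ntc)) stop("plate has no NTC wells", call. = FALSE)
  sw <- p@wells[p@wells$well_type == "sample", , drop = FALSE]
  genes <- unique(ntc$gene)
  vapply(stats::setNames(genes, genes), function(g) {
    nct <- ntc$ct[ntc$gene == g]
    nct <- nct[is.finite(nct)]
    if (!length(nct)) return(TRUE)  # no amplification
    min_sample <- min(sw$ct[sw$gene == g])
    min(nct) - min_sample >= margin
  }, logical(1L))
}

#' Read a qPCR plate from delimited text
#'
#' Expects columns `sample`, `gene`, `ct`, and optionally `well_type`
#' (`"sample"`/`"ntc"`); NTC wells may have empty/NA Ct for no
#' amplification.
#'
#' @param path input path.
#' @param housekeepers character(2) housekeeping gene labels.
#' @param comparator comparator sample label.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return A [QPCRPlate-class].
#' @export
readQPCRPlate <- function(path, housekeepers, comparator, sep = NULL) {
  if (!file.exists(path)) stop("plate file not found: ", path, call. = FALSE)
  sep <- .sepForPath(path, sep)
  w <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  QPCRPlate(w, housekeepers = housekeepers, comparator = comparator)
}
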