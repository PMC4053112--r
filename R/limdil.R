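## Single-hit Poisson limiting-dilution analysis of repopulating-unit
## frequencies, and the distribution of MRUs across cell populations.

.ldLogLik <- function(logf, dose, n_tested, n_positive) {
  p <- -expm1(-exp(logf) * dose)
  ll <- sum(stats::dbinom(n_positive, n_tested, p, log = TRUE))
  ## far from the MLE the likelihood underflows to 0; keep the objective
  ## finite so interval search stays well-defined
  if (!is.finite(ll)) -1e12 else ll
}

#' Fit the single-hit Poisson model to a limiting-dilution assay
#'
#' Under the single-hit model, `P(positive | dose d) = 1 - exp(-f * d)` with
#' `f` the repopulating-cell frequency. The maximum-likelihood fit is a
#' binomial GLM with complementary log-log link and offset `log(dose)`, whose
#' intercept is `log f`; the 95 percent interval is Wald on the log-frequency
#' scale, `exp(log f +/- 1.96 * SE)`, with a likelihood-ratio interval as an
#' option. Degenerate tables yield bounds rather than failures: an
#' all-negative assay returns frequency 0 with an exact one-sided 95 percent
#' upper bound, an all-positive assay a lower bound only.
#'
#' @param a an [LDAssay-class].
#' @param ci_method `"wald"` (default) or `"lrt"`.
#' @param conf_level confidence level for the interval.
#' @return An [LDResult-class].
#' @examples
#' fitSingleHit(LDAssay(1000, 6, 3))  # closed form: -log(3/6)/1000
#' @export
fitSingleHit <- function(a, ci_method = c("wald", "lrt"), conf_level = 0.95) {
  stopifnot(is(a, "LDAssay"))
  ci_method <- match.arg(ci_method)
  d <- a@data
  alpha <- 1 - conf_level
  npos <- sum(d$n_positive)
  ntot <- sum(d$n_tested)

  if (npos == 0L) {
    ## exact one-sided bound: P(all negative | f) = exp(-f * sum(n * d))
    upper <- -log(alpha) / sum(d$n_tested * d$dose)
    return(new("LDResult", population = a@population, frequency = 0,
               ci_lower = 0, ci_upper = upper, log_frequency_se = NA_real_,
               degenerate = "all_negative"))
  }
  if (npos == ntot) {
    pr_all_pos <- function(f)
      sum(d$n_tested * log(-expm1(-f * d$dose))) - log(alpha)
    lower <- stats::uniroot(pr_all_pos, lower = 1e-12 / max(d$dose),
                            upper = 1e3 / min(d$dose), tol = 1e-14)$root
    return(new("LDResult", population = a@population, frequency = Inf,
               ci_lower = lower, ci_upper = Inf, log_frequency_se = NA_real_,
               degenerate = "all_positive"))
  }

  ## saturating doses legitimately push fitted p to 1; muffle that warning
  fit <- withCallingHandlers(
    stats::glm(
      cbind(n_positive, n_tested - n_positive) ~ 1 + offset(log(dose)),
      family = stats::binomial(link = "cloglog"), data = d,
      control = stats::glm.control(epsilon = 1e-12, maxit = 200L)),
    warning = function(w) {
      if (grepl("numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  logf <- unname(stats::coef(fit)[1L])
  se <- sqrt(stats::vcov(fit)[1L, 1L])
  z <- stats::qnorm(1 - alpha / 2)
  if (ci_method == "wald") {
    ci <- exp(logf + c(-1, 1) * z * se)
  } else {
    ll_max <- .ldLogLik(logf, d$dose, d$n_tested, d$n_positive)
    crit <- stats::qchisq(conf_level, df = 1L) / 2
    drop_fun <- function(lf)
      ll_max - .ldLogLik(lf, d$dose, d$n_tested, d$n_positive) - crit
    lo <- stats::uniroot(drop_fun, lower = logf - 20, upper = logf,
                         tol = 1e-10)$root
    hi <- stats::uniroot(drop_fun, lower = logf, upper = logf + 20,
                         tol = 1e-10)$root
    ci <- exp(c(lo, hi))
  }
  new("LDResult", population = a@population, frequency = exp(logf),
      ci_lower = ci[1L], ci_upper = ci[2L], log_frequency_se = se,
      degenerate = "none")
}

#' Distribution of repopulating units across cell populations
#'
#' Given per-population frequencies and population sizes, the share of all
#' MRUs residing in population i is `f_i * n_i / sum_j f_j * n_j`; shares
#' sum to 1.
#'
#' @param results named numeric vector of frequencies, or a named list of
#'   [LDResult-class] objects.
#' @param pop_sizes named numeric vector of population cell counts; names
#'   must match `results`.
#' @return Named numeric vector of shares summing to 1.
#' @examples
#' mruShare(c(basal = 1e-2, luminal = 1e-5), c(basal = 1e4, luminal = 3e4))
#' @export
mruShare <- function(results, pop_sizes) {
  f <- if (is.list(results))
    vapply(results, ldFrequency, numeric(1L)) else results
  if (is.null(names(f)) || is.null(names(pop_sizes)))
    stop("frequencies and population sizes must be named", call. = FALSE)
  pop_sizes <- pop_sizes[names(f)]
  if (anyNA(pop_sizes) || any(pop_sizes <= 0))
    stop("every population needs a positive size", call. = FALSE)
  if (any(!is.finite(f)) || any(f < 0))
    stop("frequencies must be finite and nonnegative", call. = FALSE)
  total <- sum(f * pop_sizes)
  if (total == 0) stop("all frequencies are zero", call. = FALSE)
  f * pop_sizes / total
}

#' Format a frequency as "1 in N"
#'
#' @param f numeric frequency (repopulating units per cell).
#' @return Character vector like `"1 in 30,000"`; `"0"` for zero and
#'   `"1 in 1"`-style saturation for infinite frequency.
#' @export
formatFrequency <- function(f) {
  vapply(f, function(x) {
    if (!is.finite(x)) return(if (is.infinite(x) && x > 0) "1 in 1" else NA_character_)
    if (x <= 0) return("0")
    sprintf("1 in %s", format(round(1 / x), big.mark = ",", scientific = FALSE))
  }, character(1L))
}

#' Read limiting-dilution assay tables from delimited text
#'
#' Expects columns `population`, `dose`, `n_tested`, `n_positive`; one
#' [LDAssay-class] is built per population.
#'
#' @param path input path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return Named list of [LDAssay-class] objects.
#' @export
readLDAssays <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("assay file not found: ", path, call. = FALSE)
  sep <- .sepForPath(path, sep)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("population", "dose", "n_tested", "n_positive")
  if (!all(need %in% names(d)))
    stop("assay table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (col in c("dose", "n_tested", "n_positive")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(d[[col]]))))
    if (length(bad))
      stop(sprintf("malformed '%s' value in row %d", col, bad[1L]),
           call. = FALSE)
  }
  split_d <- split(d, d$population)
  lapply(split_d, function(g)
    LDAssay(g$dose, g$n_tested, g$n_positive, population = g$population[1L]))
}
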