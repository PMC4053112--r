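`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate expr under a temporary RNG seed, restoring global RNG state after.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

.assertScalarFraction <- function(x, name, lower_open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (lower_open && x <= 0) || (!lower_open && x < 0) || x > 1) {
    stop(sprintf("'%s' must be a single number in %s0, 1]", name,
                 if (lower_open) "(" else "["), call. = FALSE)
  }
  invisible(x)
}

## Solve trigamma(y) = x by Newton iteration (monotone decreasing target).
.trigammaInverse <- function(x) {
  stopifnot(is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(60)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

.md5OfObject <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  ## deparse gives a stable text form independent of serialization version
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}
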