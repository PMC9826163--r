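# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulation calls do not
#' perturb the caller's random stream. With `seed = NULL` the expression
#' uses (and advances) the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# centred moving average with shrinking windows at the edges;
# width in samples (coerced to an odd integer >= 1)
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < 3L) return(x)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# rolling quantile over a centred window (in samples); edge windows shrink
rolling_quantile <- function(x, width, prob) {
  width <- max(1L, as.integer(width))
  n <- length(x)
  if (width >= n) stop_domain("rolling window (", width,
                              " samples) must be shorter than the series (", n, ")")
  h <- width %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    out[i] <- stats::quantile(x[lo:hi], probs = prob, names = FALSE, type = 7)
  }
  out
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is_scalar_num(x)) stop_domain("'", name, "' must be a finite numeric scalar")
  ok <- if (strict) x > lower else x >= lower
  if (!ok) stop_domain("'", name, "' must be ", if (strict) "> " else ">= ",
                       lower, " (got ", format(x), ")")
  invisible(x)
}
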