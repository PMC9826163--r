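#' Paired or unpaired two-sided t comparison
#'
#' Thin, contract-checked wrapper around [stats::t.test()]. Degenerate
#' input with zero variance in both samples and equal means returns
#' `t = 0, p = 1` rather than an error.
#'
#' @param x,y Numeric samples; equal length required for `mode = "paired"`.
#' @param mode `"paired"` or `"unpaired"`.
#' @return A list with `statistic`, `p_value`, `df`, `mean_difference`,
#'   `mode`.
#' @export
compare_means <- function(x, y, mode = c("paired", "unpaired")) {
  mode <- match.arg(mode)
  if (mode == "paired" && length(x) != length(y))
    stop_domain("paired comparison requires equal lengths")
  if (length(x) < 2 || length(y) < 2)
    stop_domain("need >= 2 observations per sample")
  degenerate <- if (mode == "paired") stats::sd(x - y) == 0
                else stats::sd(x) == 0 && stats::sd(y) == 0
  if (degenerate) {
    d <- mean(x) - mean(y)
    if (d == 0)
      return(list(statistic = 0, p_value = 1, df = NA_real_,
                  mean_difference = 0, mode = mode))
    return(list(statistic = sign(d) * Inf, p_value = 0, df = NA_real_,
                mean_difference = d, mode = mode))
  }
  tt <- stats::t.test(x, y, paired = (mode == "paired"), var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_difference = if (mode == "paired") mean(x - y) else mean(x) - mean(y),
       mode = mode)
}

#' One-way ANOVA with Dunnett's post hoc comparisons against a control
#'
#' Fits a one-way ANOVA and compares every non-control group with the
#' control using Dunnett's procedure (multivariate-t critical values via
#' the multcomp machinery).
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2), or a
#'   data frame with `response` and `group` columns.
#' @param control_index Index (or level name) of the control group.
#' @return A list: `F_statistic`, `F_p_value`, and `comparisons`, a data
#'   frame with `group`, `estimate` (difference vs control), `p_adjusted`
#'   (Dunnett) and `p_unadjusted`.
#' @export
anova_dunnett <- function(groups, control_index = 1L) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("response", "group") %in% names(groups)))
    df <- data.frame(response = groups$response,
                     group = as.character(groups$group))
  } else {
    if (length(groups) < 2) stop_domain("need >= 2 groups")
    nm <- names(groups) %||% paste0("g", seq_along(groups))
    nm[nm == ""] <- paste0("g", which(nm == ""))
    df <- data.frame(response = unlist(groups, use.names = FALSE),
                     group = rep(nm, lengths(groups)))
    if (is.numeric(control_index)) control_index <- nm[control_index]
  }
  tab <- table(df$group)
  if (length(tab) < 2) stop_domain("need >= 2 groups")
  if (any(tab < 2)) stop_domain("every group needs n >= 2")
  if (!control_index %in% names(tab))
    stop_domain("control group '", control_index, "' not found")
  df$group <- stats::relevel(factor(df$group), ref = control_index)

  fit <- stats::aov(response ~ group, data = df)
  an <- summary(fit)[[1]]
  Fst <- an["group", "F value"]
  Fp <- an["group", "Pr(>F)"]

  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  adj <- summary(glht_fit)  # single-step multivariate-t adjustment
  raw <- summary(glht_fit, test = multcomp::adjusted("none"))
  comparisons <- data.frame(
    group = sub(" - .*$", "", names(adj$test$coefficients)),
    estimate = as.numeric(adj$test$coefficients),
    p_adjusted = as.numeric(adj$test$pvalues),
    p_unadjusted = as.numeric(raw$test$pvalues))
  list(F_statistic = unname(Fst), F_p_value = unname(Fp),
       comparisons = comparisons,
       method = "one-way ANOVA + Dunnett (single-step multivariate t)")
}

#' Combined-versus-sum synergy test
#'
#' Tests super-additivity of a drug combination on one endpoint: for each
#' subject the excess is `combined - (A + B)`; the combined responses are
#' compared with the per-subject sums by a two-sided paired t test, and
#' synergy is declared when the mean excess is positive and p < 0.05
#' (direction-aware).
#'
#' @param individual_A,individual_B,combined Numeric responses per
#'   subject, in the endpoint's native units.
#' @param ids Subject/pairing identifiers (equal length; no missing).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `synergy_result`: `excess` (per subject),
#'   `mean_excess`, `combined_mean`, `sum_mean`, `statistic`, `p_value`,
#'   `n`, `synergy` (logical).
#' @export
synergy_test <- function(individual_A, individual_B, combined,
                         ids = seq_along(combined), alpha = 0.05) {
  n <- length(combined)
  if (length(individual_A) != n || length(individual_B) != n ||
      length(ids) != n)
    stop_domain("A, B, combined and ids must have equal length")
  if (anyNA(ids) || anyNA(individual_A) || anyNA(individual_B) || anyNA(combined))
    stop_domain("missing pairing or response values")
  if (anyDuplicated(ids)) stop_domain("duplicated subject ids")
  if (n < 2) stop_domain("need >= 2 paired subjects")
  sums <- individual_A + individual_B
  excess <- combined - sums
  cmp <- compare_means(combined, sums, mode = "paired")
  structure(list(excess = stats::setNames(excess, ids),
                 mean_excess = mean(excess),
                 combined_mean = mean(combined), sum_mean = mean(sums),
                 statistic = cmp$statistic, p_value = cmp$p_value, n = n,
                 synergy = mean(excess) > 0 && cmp$p_value < alpha),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf(
    "Combined %.3g vs sum %.3g (excess %+.3g, n = %d): t = %.3g, p = %.3g -> %s\n",
    x$combined_mean, x$sum_mean, x$mean_excess, x$n, x$statistic, x$p_value,
    if (x$synergy) "synergy (super-additive)" else "no synergy declared"))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' @param rater1,rater2 Paired ratings (equal length >= 2).
#' @return An object of class `agreement_result`: `bias` (mean
#'   difference rater1 - rater2), `sd_differences`, `limits`
#'   (`bias +/- 1.96 sd`), and `points` — plot-ready `(mean, difference)`
#'   pairs.
#' @export
bland_altman <- function(rater1, rater2) {
  if (length(rater1) != length(rater2)) stop_domain("length mismatch")
  if (length(rater1) < 2) stop_domain("need >= 2 paired ratings")
  d <- rater1 - rater2
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_differences = s,
                 limits = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
                 points = data.frame(mean = (rater1 + rater2) / 2,
                                     difference = d)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3g, 95%% limits [%.3g, %.3g] (n = %d)\n",
              x$bias, x$limits[1], x$limits[2], nrow(x$points)))
  invisible(x)
}

#' Simulate a paired synergy cohort
#'
#' Generates per-subject responses to two agents and their combination:
#' `combined = (A + B) * interaction + noise`, so `interaction = 1` is the
#' additive null and `interaction > 1` super-additive.
#'
#' @param n Number of subjects.
#' @param mean_A,mean_B True mean individual responses.
#' @param interaction Multiplicative interaction on the combined response.
#' @param sd Between-measurement SD.
#' @param seed Optional seed.
#' @return A data frame with `id`, `A`, `B`, `combined`.
#' @export
simulate_synergy_cohort <- function(n = 5, mean_A = 4, mean_B = 3,
                                    interaction = 1, sd = 1, seed = NULL) {
  with_seed(seed, {
    A <- stats::rnorm(n, mean_A, sd)
    B <- stats::rnorm(n, mean_B, sd)
    combined <- (A + B) * interaction + stats::rnorm(n, 0, sd)
    data.frame(id = seq_len(n), A = A, B = B, combined = combined)
  })
}
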