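#' Build a concentration-response curve from windowed summaries
#'
#' Turns per-concentration [window_summary()] objects (each computed
#' against the same pre-drug reference window) into a
#' [concentration_response()] dataset for one endpoint. Tone responses
#' are the windowed tone changes A (mN), optionally normalised to percent
#' of the carbachol maximum; amplitude and frequency responses are
#' changes of the mean event amplitude / of the frequency versus the
#' reference summary, absolute or percent.
#'
#' @param summaries Named list of `window_summary` objects; names are the
#'   bath concentrations in M (coercible by `as.numeric`).
#' @param reference The pre-drug `window_summary` (needed for amplitude /
#'   frequency endpoints).
#' @param endpoint `"tone"`, `"amplitude"` or `"frequency"`.
#' @param carbachol_max Optional carbachol maximum (mN); when supplied,
#'   tone responses are percent of it.
#' @param percent For amplitude/frequency: report percent change rather
#'   than absolute change.
#' @param replicate Replicate id stored on the dataset.
#' @return A [concentration_response()].
#' @export
crc_from_windows <- function(summaries, reference = NULL,
                             endpoint = c("tone", "amplitude", "frequency"),
                             carbachol_max = NULL, percent = FALSE,
                             replicate = 1L) {
  endpoint <- match.arg(endpoint)
  if (length(summaries) < 3) stop_domain("need summaries at >= 3 concentrations")
  concs <- suppressWarnings(as.numeric(names(summaries)))
  if (any(is.na(concs))) stop_domain("summary names must be concentrations (M)")
  ord <- order(concs)
  concs <- concs[ord]; summaries <- summaries[ord]
  if (endpoint != "tone" && is.null(reference))
    stop_domain("reference window summary required for endpoint '", endpoint, "'")

  resp <- vapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    switch(endpoint,
      tone = {
        a <- s$tone_change_mN
        if (!is.null(carbachol_max)) percent_of_carbachol(a, carbachol_max) else a
      },
      amplitude = {
        d <- s$mean_features[["C_mN"]] - reference$mean_features[["C_mN"]]
        if (percent) 100 * d / reference$mean_features[["C_mN"]] else d
      },
      frequency = {
        d <- s$frequency_cpm - reference$frequency_cpm
        if (percent) 100 * d / reference$frequency_cpm else d
      })
  }, numeric(1))
  concentration_response(concs, resp, replicate = replicate,
                         endpoint = endpoint)
}

#' Fit the Hill equation to a concentration-response curve
#'
#' Least-squares fit of `response = Emax * c^n / (c^n + EC50^n)` (basal
#' effect fixed at 0) by bounded Levenberg-Marquardt, started from a
#' fixed log-spaced grid of EC50 values spanning the tested
#' concentrations; the start with the lowest residual sum of squares
#' wins, ties broken toward the lowest EC50, so the fit is deterministic
#' for given data.
#'
#' @param crc A [concentration_response()] (or data frame with `conc_M`
#'   and `response` columns). Replicates are fitted jointly.
#' @param slope_bounds Bounds for the Hill slope (default `c(0.3, 5)`).
#' @param fix_slope Optional fixed Hill slope (e.g. 1).
#' @param ascending_limb_only For biphasic (rise-then-fall) curves, fit
#'   only concentrations up to the empirical maximum of the
#'   per-concentration mean response (with a warning).
#' @return An object of class `hill_fit`: `pEC50`, `EC50`, `Emax`,
#'   `hill_slope`, `se` (named vector), `converged`, `residuals`,
#'   `fitted`, `data`, `sse`.
#' @export
fit_hill <- function(crc, slope_bounds = c(0.3, 5), fix_slope = NULL,
                     ascending_limb_only = FALSE) {
  df <- as.data.frame(crc)[, c("conc_M", "response")]
  df <- df[stats::complete.cases(df), ]
  if (length(unique(df$conc_M)) < 4)
    stop_domain("need >= 4 distinct concentrations to fit the Hill equation")

  if (ascending_limb_only) {
    mu <- tapply(df$response, df$conc_M, mean)
    # follow the initial response direction: for a rise-then-fall curve the
    # excitatory limb ends at the signed maximum, not at |response| max
    dir_idx <- which(abs(mu) >= 0.1 * max(abs(mu)))[1]
    dir <- sign(mu[dir_idx])
    if (dir == 0) dir <- 1
    cmax <- as.numeric(names(mu))[which.max(dir * mu)]
    if (cmax < max(df$conc_M))
      warning("biphasic curve: fitting ascending limb up to ",
              format(cmax), " M only", call. = FALSE)
    df <- df[df$conc_M <= cmax, ]
    if (length(unique(df$conc_M)) < 4)
      stop_domain("ascending limb has < 4 concentrations")
  }

  non_converged <- structure(
    list(pEC50 = NA_real_, EC50 = NA_real_, Emax = NA_real_,
         hill_slope = NA_real_, se = c(pEC50 = NA_real_, Emax = NA_real_,
                                       hill_slope = NA_real_),
         converged = FALSE, residuals = rep(NA_real_, nrow(df)),
         fitted = rep(NA_real_, nrow(df)), data = df, sse = NA_real_),
    class = "hill_fit")
  if (stats::sd(df$response) == 0) return(non_converged)

  emax0 <- df$response[which.max(abs(df$response))]
  grid <- 10^seq(log10(min(df$conc_M)), log10(max(df$conc_M)), length.out = 13)
  lower <- c(log10(min(df$conc_M)) - 4,
             if (is.null(fix_slope)) slope_bounds[1])
  upper <- c(log10(max(df$conc_M)) + 4,
             if (is.null(fix_slope)) slope_bounds[2])

  model_fun <- function(logEC50, n, conc) {
    cn <- exp(n * log(conc))
    en <- exp(n * log(10) * logEC50)
    cn / (cn + en)
  }

  best <- NULL
  for (ec0 in grid) {
    start <- if (is.null(fix_slope)) list(logEC50 = log10(ec0), n = 1)
             else list(logEC50 = log10(ec0))
    fml <- if (is.null(fix_slope))
      response ~ Emax * model_fun(logEC50, n, conc_M)
    else
      stats::as.formula(sprintf(
        "response ~ Emax * model_fun(logEC50, %.17g, conc_M)", fix_slope))
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = df,
                        start = c(start, list(Emax = emax0)),
                        lower = c(lower, -Inf), upper = c(upper, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 &&
         stats::coef(fit)[["logEC50"]] < best$logEC50)) {
      best <- list(fit = fit, sse = sse, logEC50 = stats::coef(fit)[["logEC50"]])
    }
  }
  if (is.null(best)) return(non_converged)

  cf <- stats::coef(best$fit)
  se_raw <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                     error = function(e) NULL)
  n_hat <- if (is.null(fix_slope)) cf[["n"]] else fix_slope
  se <- c(pEC50 = unname(se_raw["logEC50"]) %||% NA_real_,
          Emax = unname(se_raw["Emax"]) %||% NA_real_,
          hill_slope = if (is.null(fix_slope)) unname(se_raw["n"]) %||% NA_real_
                       else 0)
  structure(
    list(pEC50 = -cf[["logEC50"]], EC50 = 10^cf[["logEC50"]],
         Emax = cf[["Emax"]], hill_slope = n_hat, se = se,
         converged = TRUE, residuals = as.numeric(stats::residuals(best$fit)),
         fitted = as.numeric(stats::fitted(best$fit)), data = df,
         sse = best$sse),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Hill fit: did not converge (constant or degenerate responses)\n")
  } else {
    cat(sprintf("Hill fit: pEC50 = %.2f, Emax = %.3g, slope = %.2f (SSE %.3g)\n",
                x$pEC50, x$Emax, x$hill_slope, x$sse))
  }
  invisible(x)
}

#' Threshold concentration interval of a response curve
#'
#' Scans the per-concentration mean responses for the first crossing of a
#' criterion (e.g. twice the residual SD of the pre-drug endpoint) and
#' returns the bracketing interval `(last sub-threshold conc,
#' first supra-threshold conc]` as the threshold, matching how organ-bath
#' thresholds are reported as decade intervals.
#'
#' @param crc A [concentration_response()].
#' @param criterion Threshold response level (endpoint units).
#' @return A list: `lower`, `upper` (M; `NA` with `status` `"below range"`
#'   when all responses exceed the criterion, `"above range"` when none
#'   do), `status` `"within range"` otherwise, and `ambiguous = TRUE` when
#'   the responses re-cross the criterion after the first crossing.
#' @export
threshold_concentration <- function(crc, criterion) {
  assert_scalar(criterion, "criterion")
  df <- as.data.frame(crc)
  mu <- tapply(df$response, df$conc_M, mean)
  concs <- as.numeric(names(mu))
  above <- abs(mu) >= abs(criterion)
  if (all(above))
    return(list(lower = NA_real_, upper = concs[1], status = "below range",
                ambiguous = FALSE))
  if (!any(above))
    return(list(lower = concs[length(concs)], upper = NA_real_,
                status = "above range", ambiguous = FALSE))
  first <- which(above)[1]
  if (first == 1)
    return(list(lower = NA_real_, upper = concs[1], status = "below range",
                ambiguous = FALSE))
  ambiguous <- any(!above[first:length(above)])
  list(lower = concs[first - 1], upper = concs[first],
       status = "within range", ambiguous = ambiguous)
}

#' Invert a Hill fit at a fraction of Emax
#'
#' Returns the concentration producing `fraction` of the fitted maximal
#' effect — e.g. `fraction = 0.75` gives the EC75 used to pick
#' combination concentrations for synergy experiments.
#'
#' @param fit A converged [fit_hill()] result (or [hill_params()]).
#' @param fraction Fraction of Emax in (0, 1).
#' @return Concentration (M).
#' @export
ec_fraction <- function(fit, fraction = 0.75) {
  assert_scalar(fraction, "fraction", 0, strict = TRUE)
  if (fraction >= 1) stop_domain("fraction must be < 1")
  ec50 <- if (inherits(fit, "hill_params")) fit$EC50 else fit$EC50
  n <- if (inherits(fit, "hill_params")) fit$hill_slope else fit$hill_slope
  if (!is.finite(ec50)) stop_domain("fit did not converge")
  ec50 * (fraction / (1 - fraction))^(1 / n)
}
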