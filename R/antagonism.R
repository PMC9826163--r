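#' Agonist dose ratio under an antagonist
#'
#' @param EC50_with_antagonist Agonist EC50 in the presence of the
#'   antagonist (M); > 0.
#' @param EC50_control Control agonist EC50 (M); > 0.
#' @return The concentration ratio `CR = EC50_with / EC50_control`.
#' @export
dose_ratio <- function(EC50_with_antagonist, EC50_control) {
  assert_scalar(EC50_with_antagonist, "EC50_with_antagonist", 0, strict = TRUE)
  assert_scalar(EC50_control, "EC50_control", 0, strict = TRUE)
  EC50_with_antagonist / EC50_control
}

#' Gaddum-Schild pA2 from a single antagonist concentration
#'
#' \deqn{pA_2 = \log_{10}(CR - 1) - \log_{10}[B]}
#' The antagonist concentration that would double the agonist EC50,
#' estimated from one dose ratio; equals pKB for a competitive
#' antagonist obeying the Schild relation with unit slope.
#'
#' @param CR Dose ratio; must exceed 1 (a rightward shift).
#' @param antagonist_conc Antagonist concentration \[B\] (M); > 0.
#' @return pA2 (-log10 M).
#' @export
gaddum_schild_pa2 <- function(CR, antagonist_conc) {
  assert_scalar(antagonist_conc, "antagonist_conc", 0, strict = TRUE)
  if (!is_scalar_num(CR) || CR <= 1)
    stop_domain("no rightward shift: dose ratio must be > 1 (got ",
                format(CR), ")")
  log10(CR - 1) - log10(antagonist_conc)
}

#' Schild regression over multiple antagonist concentrations
#'
#' Ordinary least squares of `log10(CR - 1)` on `log10([B])`. When the
#' 95% confidence interval of the slope includes 1 (competitive
#' behaviour), the regression is refitted with the slope constrained to 1
#' and the constrained intercept is reported as pKB; otherwise the
#' free-slope x-intercept is reported as pA2 with a slope warning.
#' Points with `CR <= 1` are excluded with a warning.
#'
#' @param antagonist_conc Antagonist concentrations (M).
#' @param CR Dose ratios (one per concentration; replicate CRs at the
#'   same concentration are allowed as separate points).
#' @return An object of class `schild_result`: `slope`, `slope_se`,
#'   `slope_ci`, `slope_unity` (logical: CI contains 1), `pKB`
#'   (slope-constrained intercept; `NA` when slope differs from 1),
#'   `pA2` (free-slope x-intercept), `n_used`, `excluded` (indices of
#'   dropped points), `data`.
#' @export
schild_regression <- function(antagonist_conc, CR) {
  if (length(antagonist_conc) != length(CR))
    stop_domain("antagonist_conc and CR must have equal length")
  if (any(antagonist_conc <= 0)) stop_domain("antagonist concentrations must be > 0")
  usable <- CR > 1
  excluded <- which(!usable)
  if (length(excluded))
    warning(length(excluded), " point(s) with CR <= 1 excluded from the Schild plot",
            call. = FALSE)
  B <- antagonist_conc[usable]
  cr <- CR[usable]
  if (length(unique(B)) < 2)
    stop_domain("need >= 2 distinct antagonist concentrations with CR > 1")
  x <- log10(B)
  y <- log10(cr - 1)
  fit <- stats::lm(y ~ x)
  # exact competitive data fits perfectly; silence the lm summary note
  cf <- suppressWarnings(summary(fit)$coefficients)
  slope <- cf["x", "Estimate"]
  slope_se <- cf["x", "Std. Error"]
  df_res <- fit$df.residual
  ci <- if (df_res > 0) slope + c(-1, 1) * stats::qt(0.975, df_res) * slope_se
        else c(-Inf, Inf)
  unity <- ci[1] <= 1 && 1 <= ci[2]
  # y = 0 (CR = 2) at log10 B = -a/b, so pA2 = -log10 B = a/b
  pA2_free <- cf["(Intercept)", "Estimate"] / slope
  pKB <- if (unity) mean(y - x) else NA_real_
  if (!unity)
    warning("Schild slope differs from unity (95% CI [",
            sprintf("%.2f, %.2f", ci[1], ci[2]),
            "]); reporting free-slope pA2, not pKB", call. = FALSE)
  structure(list(slope = slope, slope_se = slope_se, slope_ci = ci,
                 slope_unity = unity, pKB = pKB, pA2 = pA2_free,
                 n_used = length(cr), excluded = excluded,
                 data = data.frame(B_M = B, CR = cr)),
            class = "schild_result")
}

#' @export
print.schild_result <- function(x, ...) {
  cat(sprintf("Schild regression (n = %d): slope %.3f +/- %.3f", x$n_used,
              x$slope, x$slope_se))
  if (x$slope_unity) {
    cat(sprintf("; slope ~ 1, pKB = %.3f\n", x$pKB))
  } else {
    cat(sprintf("; slope != 1, pA2 = %.3f\n", x$pA2))
  }
  invisible(x)
}

#' Full antagonist-potency pipeline from fitted curves
#'
#' Averages replicate fitted pEC50s on the log scale per antagonist
#' concentration (0 = control), forms dose ratios against the control,
#' and runs [schild_regression()] (>= 2 antagonist concentrations) or
#' [gaddum_schild_pa2()] (single concentration).
#'
#' @param fits A data frame with columns `B_M` (antagonist concentration,
#'   0 for control) and `pEC50` (per fitted curve).
#' @return For >= 2 antagonist concentrations a `schild_result`; for one,
#'   a list with `CR` and `pA2`.
#' @export
antagonist_potency <- function(fits) {
  stopifnot(all(c("B_M", "pEC50") %in% names(fits)))
  if (!any(fits$B_M == 0)) stop_domain("control curves (B_M = 0) required")
  mean_pec50 <- tapply(fits$pEC50, fits$B_M, mean)
  Bs <- as.numeric(names(mean_pec50))
  ctrl <- mean_pec50[Bs == 0]
  anta <- Bs[Bs > 0]
  if (!length(anta)) stop_domain("no antagonist curves supplied")
  CR <- 10^(ctrl - mean_pec50[match(anta, Bs)])  # EC50_B / EC50_ctrl
  if (length(anta) >= 2) {
    schild_regression(anta, as.numeric(CR))
  } else {
    list(CR = as.numeric(CR), pA2 = gaddum_schild_pa2(as.numeric(CR), anta))
  }
}
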