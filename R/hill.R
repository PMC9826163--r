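#' Hill (sigmoid Emax) parameter set
#'
#' Parameters of the Hill concentration-effect model
#' \deqn{E(c) = E_{max} \, c^n / (c^n + EC_{50}^n)}
#' used both as the generating model of the synthetic pharmacodynamics and
#' as the regression model fitted to concentration-response curves.
#'
#' @param EC50 Agonist concentration producing half-maximal effect (M); > 0.
#' @param Emax Maximal effect, in the endpoint's own units (mN, % of the
#'   carbachol maximum, or c.p.m. change). May be negative for inhibitory
#'   effects.
#' @param hill_slope Hill coefficient (dimensionless); > 0.
#' @return An object of class `hill_params`.
#' @examples
#' avp_tone <- hill_params(EC50 = 3.16e-10, Emax = 7.1)
#' hill_response(1e-7, avp_tone)
#' @export
hill_params <- function(EC50, Emax, hill_slope = 1) {
  assert_scalar(EC50, "EC50", 0, strict = TRUE)
  if (!is_scalar_num(Emax)) stop_domain("'Emax' must be a finite numeric scalar")
  assert_scalar(hill_slope, "hill_slope", 0, strict = TRUE)
  structure(list(EC50 = EC50, Emax = Emax, hill_slope = hill_slope),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill model: EC50 = %.3g M (pEC50 %.2f), Emax = %.3g, slope = %.2f\n",
              x$EC50, -log10(x$EC50), x$Emax, x$hill_slope))
  invisible(x)
}

#' Hill concentration-effect response
#'
#' @param conc Agonist concentration(s), M; must be >= 0.
#' @param params A [hill_params()] object.
#' @return Response in `Emax` units; 0 at `conc = 0`, `Emax/2` at
#'   `conc = EC50`, monotone in `conc`.
#' @export
hill_response <- function(conc, params) {
  stopifnot(inherits(params, "hill_params"))
  if (!is.numeric(conc) || any(!is.finite(conc)))
    stop_domain("'conc' must be finite numeric")
  if (any(conc < 0)) stop_domain("'conc' must be >= 0")
  n <- params$hill_slope
  cn <- conc^n
  params$Emax * cn / (cn + params$EC50^n)
}

#' Competitive antagonist model
#'
#' A surmountable antagonist characterised by its equilibrium dissociation
#' constant \eqn{K_B}; by the Schild relation it shifts an agonist's EC50
#' rightward by the dose ratio \eqn{1 + [B]/K_B} without changing Emax.
#'
#' @param KB Dissociation constant (M); > 0.
#' @return An object of class `antagonist_model`.
#' @export
antagonist_model <- function(KB) {
  assert_scalar(KB, "KB", 0, strict = TRUE)
  structure(list(KB = KB, mode = "competitive"), class = "antagonist_model")
}

#' Schild shift of an agonist EC50 by a competitive antagonist
#'
#' @param EC50 Control agonist EC50 (M); > 0.
#' @param antagonist_conc Bath antagonist concentration \[B\] (M); >= 0.
#' @param model An [antagonist_model()].
#' @return Shifted EC50, `EC50 * (1 + antagonist_conc / KB)`.
#' @export
competitive_ec50_shift <- function(EC50, antagonist_conc, model) {
  stopifnot(inherits(model, "antagonist_model"))
  assert_scalar(EC50, "EC50", 0, strict = TRUE)
  assert_scalar(antagonist_conc, "antagonist_conc", 0)
  EC50 * (1 + antagonist_conc / model$KB)
}

#' Biphasic (excitatory then inhibitory) agonist model
#'
#' Sum of two Hill terms of opposite sign, emulating an adrenaline-like
#' response: alpha-mediated tone increase at low concentrations overtaken
#' by beta-mediated relaxation at high concentrations.
#'
#' @param excitatory,inhibitory [hill_params()] for the two components;
#'   the inhibitory component carries a negative `Emax`.
#' @return An object of class `biphasic_model`.
#' @export
biphasic_model <- function(excitatory, inhibitory) {
  stopifnot(inherits(excitatory, "hill_params"), inherits(inhibitory, "hill_params"))
  structure(list(excitatory = excitatory, inhibitory = inhibitory),
            class = "biphasic_model")
}

#' Net tone change under a biphasic model
#'
#' @param conc Concentration(s), M; >= 0.
#' @param model A [biphasic_model()].
#' @return Signed net effect (excitatory Hill + inhibitory Hill); 0 at
#'   `conc = 0`.
#' @export
biphasic_tone_effect <- function(conc, model) {
  stopifnot(inherits(model, "biphasic_model"))
  hill_response(conc, model$excitatory) + hill_response(conc, model$inhibitory)
}
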