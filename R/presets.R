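#' Contraction waveform shape parameters
#'
#' Geometry of a single phasic contraction and of the rhythm that repeats
#' it: amplitude C (mN), time to peak E (s), decay time F (s) — so total
#' contraction time D = E + F — the inter-onset interval of the myogenic
#' rhythm, and the resting baseline tone.
#'
#' @param amplitude_C Peak tension above baseline (mN); >= 0.
#' @param time_to_peak_E Rise time E (s); > 0.
#' @param decay_time_F Decay time F (s); > 0.
#' @param inter_onset_interval Time between successive contraction onsets
#'   (s); must be >= `time_to_peak_E` so that a contraction peaks before
#'   the next one begins.
#' @param baseline_tone Resting tone (mN); >= 0.
#' @return An object of class `contraction_shape`.
#' @export
contraction_shape <- function(amplitude_C, time_to_peak_E, decay_time_F,
                              inter_onset_interval, baseline_tone = 20) {
  assert_scalar(amplitude_C, "amplitude_C", 0)
  assert_scalar(time_to_peak_E, "time_to_peak_E", 0, strict = TRUE)
  assert_scalar(decay_time_F, "decay_time_F", 0, strict = TRUE)
  assert_scalar(inter_onset_interval, "inter_onset_interval", 0, strict = TRUE)
  assert_scalar(baseline_tone, "baseline_tone", 0)
  if (inter_onset_interval < time_to_peak_E)
    stop_domain("inter_onset_interval must be >= time_to_peak_E")
  structure(list(amplitude_C = amplitude_C,
                 time_to_peak_E = time_to_peak_E,
                 decay_time_F = decay_time_F,
                 inter_onset_interval = inter_onset_interval,
                 baseline_tone = baseline_tone),
            class = "contraction_shape")
}

#' Measurement-noise parameters
#'
#' @param additive_sd SD of additive white Gaussian force noise (mN); >= 0.
#' @param drift_rate Linear baseline drift (mN per minute); may be negative.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(additive_sd = 0, drift_rate = 0) {
  assert_scalar(additive_sd, "additive_sd", 0)
  if (!is_scalar_num(drift_rate)) stop_domain("'drift_rate' must be a finite scalar")
  structure(list(additive_sd = additive_sd, drift_rate = drift_rate),
            class = "noise_params")
}

#' Agonist pharmacodynamic model for trace simulation
#'
#' Concentration-dependent targets for the three endpoints an agonist acts
#' on in the bath — baseline tone (mN change), contraction amplitude and
#' contraction frequency (both fractional change) — together with the
#' kinetics of the response: a first-order onset time constant that
#' shortens log-linearly with concentration (responses plateau over
#' roughly 2-10 min), and a transient fade above a threshold concentration
#' (high agonist concentrations give shorter-lived responses).
#'
#' @param tone [hill_params()]; `Emax` in mN of tone change.
#' @param amplitude_scale [hill_params()]; `Emax` as fractional change of
#'   contraction amplitude (0.5 = +50%).
#' @param frequency_scale [hill_params()]; `Emax` as fractional change of
#'   contraction frequency.
#' @param onset_tau_slow,onset_tau_fast First-order onset time constants
#'   (s) at threshold and at saturating concentrations; interpolated
#'   log-linearly in concentration between them.
#' @param transient_threshold Concentration (M) above which the response
#'   fades; `Inf` disables transience.
#' @param transient_half_life Half-life (s) of the fading response.
#' @return An object of class `agonist_pd_model`.
#' @export
agonist_pd_model <- function(tone,
                             amplitude_scale = hill_params(1e-9, 0),
                             frequency_scale = hill_params(1e-9, 0),
                             onset_tau_slow = 200,
                             onset_tau_fast = 30,
                             transient_threshold = Inf,
                             transient_half_life = 300) {
  stopifnot(inherits(tone, "hill_params"),
            inherits(amplitude_scale, "hill_params"),
            inherits(frequency_scale, "hill_params"))
  assert_scalar(onset_tau_slow, "onset_tau_slow", 0, strict = TRUE)
  assert_scalar(onset_tau_fast, "onset_tau_fast", 0, strict = TRUE)
  assert_scalar(transient_half_life, "transient_half_life", 0, strict = TRUE)
  if (!(is_scalar_num(transient_threshold) || identical(transient_threshold, Inf)))
    stop_domain("'transient_threshold' must be a positive scalar or Inf")
  structure(list(tone = tone, amplitude_scale = amplitude_scale,
                 frequency_scale = frequency_scale,
                 onset_tau_slow = onset_tau_slow, onset_tau_fast = onset_tau_fast,
                 transient_threshold = transient_threshold,
                 transient_half_life = transient_half_life),
            class = "agonist_pd_model")
}

# onset time constant at a given concentration: log-linear between the
# slow value at EC50/10 and the fast value at 100*EC50 (clamped)
onset_tau_at <- function(pd, conc) {
  lo <- pd$tone$EC50 / 10
  hi <- pd$tone$EC50 * 100
  if (conc <= lo) return(pd$onset_tau_slow)
  if (conc >= hi) return(pd$onset_tau_fast)
  f <- (log10(conc) - log10(lo)) / (log10(hi) - log10(lo))
  pd$onset_tau_slow + f * (pd$onset_tau_fast - pd$onset_tau_slow)
}

#' Electrical field stimulation schedule
#'
#' @param pulse_frequency Stimulation frequency within a train (Hz).
#' @param pulse_width Pulse width (ms).
#' @param train_duration Duration of each stimulation train (s).
#' @param train_period Time between train starts (s); must exceed
#'   `train_duration`.
#' @param evoked_amplitude Amplitude of the evoked contraction (mN).
#' @return An object of class `efs_schedule`. Defaults follow the common
#'   organ-bath protocol of 5 Hz, 0.5 ms pulses for 10 s every minute.
#' @export
efs_schedule <- function(pulse_frequency = 5, pulse_width = 0.5,
                         train_duration = 10, train_period = 60,
                         evoked_amplitude = 10) {
  assert_scalar(pulse_frequency, "pulse_frequency", 0, strict = TRUE)
  assert_scalar(pulse_width, "pulse_width", 0, strict = TRUE)
  assert_scalar(train_duration, "train_duration", 0, strict = TRUE)
  assert_scalar(train_period, "train_period", 0, strict = TRUE)
  assert_scalar(evoked_amplitude, "evoked_amplitude", 0)
  if (train_duration >= train_period)
    stop_domain("train_duration must be < train_period")
  structure(list(pulse_frequency = pulse_frequency, pulse_width = pulse_width,
                 train_duration = train_duration, train_period = train_period,
                 evoked_amplitude = evoked_amplitude),
            class = "efs_schedule")
}

#' Named parameter presets
#'
#' Bundles reproducing the study conditions of the human gastric
#' organ-bath experiments:
#' \describe{
#'   \item{`proximal-default`}{Proximal (fundus/corpus) myogenic rhythm:
#'     slow symmetric contractions, C = 1.1 mN, E = F = 11.75 s
#'     (D = 23.5 s), back-to-back at 23.5 s intervals (2.6 c.p.m.) on a
#'     20 mN resting tone; noise SD 0.05 mN.}
#'   \item{`distal-default`}{Distal (antral) rhythm: ~5x larger,
#'     fast-rising slow-decaying contractions, C = 5.0 mN, E = 4.3 s,
#'     F = 17.2 s, interval 22.2 s (2.7 c.p.m.); noise SD 0.10 mN.}
#'   \item{`AVP-tone-proximal`}{Vasopressin-like tone pharmacodynamics on
#'     proximal muscle: EC50 3.16e-10 M (pEC50 9.5), Emax 7.1 % of the
#'     carbachol maximum, slope 1.}
#'   \item{`SR49059-vs-OT`}{Competitive V1A antagonist vs oxytocin,
#'     KB = 3.16e-10 M (pKB 9.5).}
#'   \item{`atropine-proximal`}{Muscarinic blockade: smooth step of
#'     baseline tone from 20.0 to 18.4 mN (first-order, tau 60 s), no
#'     effect on the myogenic rhythm itself.}
#' }
#'
#' @param name Preset name.
#' @return The preset object (class depends on the preset).
#' @examples
#' preset("proximal-default")
#' @export
preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop_domain("unknown preset '", name, "'; available: ",
                paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' @rdname preset
#' @export
preset_registry <- function() {
  list(
    "proximal-default" = list(
      shape = contraction_shape(amplitude_C = 1.1, time_to_peak_E = 11.75,
                                decay_time_F = 11.75,
                                inter_onset_interval = 23.5,
                                baseline_tone = 20),
      noise = noise_params(additive_sd = 0.05),
      region = "proximal"),
    "distal-default" = list(
      shape = contraction_shape(amplitude_C = 5.0, time_to_peak_E = 4.3,
                                decay_time_F = 17.2,
                                inter_onset_interval = 22.2,
                                baseline_tone = 20),
      noise = noise_params(additive_sd = 0.10),
      region = "distal"),
    "AVP-tone-proximal" = hill_params(EC50 = 3.16e-10, Emax = 7.1, hill_slope = 1),
    "SR49059-vs-OT" = antagonist_model(KB = 3.16e-10),
    "atropine-proximal" = agonist_pd_model(
      tone = hill_params(EC50 = 1e-12, Emax = -1.6, hill_slope = 1),
      onset_tau_slow = 60, onset_tau_fast = 60)
  )
}

#' Serialize presets to / from JSON-compatible config files
#'
#' @param x A preset object (`contraction_shape`, `noise_params`,
#'   `hill_params`, `antagonist_model`, `agonist_pd_model` or
#'   `efs_schedule`).
#' @param path File path.
#' @return `write_preset` invisibly returns `path`; `read_preset` the
#'   reconstructed object.
#' @export
write_preset <- function(x, path) {
  cls <- class(x)[1]
  payload <- list(class = cls, fields = unclass_recursive(x))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else x
}

#' @rdname write_preset
#' @export
read_preset <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- payload$fields
  switch(payload$class,
    contraction_shape = do.call(contraction_shape, f),
    noise_params = do.call(noise_params, f),
    hill_params = do.call(hill_params, f),
    antagonist_model = antagonist_model(KB = f$KB),
    efs_schedule = do.call(efs_schedule, f),
    agonist_pd_model = agonist_pd_model(
      tone = do.call(hill_params, f$tone),
      amplitude_scale = do.call(hill_params, f$amplitude_scale),
      frequency_scale = do.call(hill_params, f$frequency_scale),
      onset_tau_slow = f$onset_tau_slow, onset_tau_fast = f$onset_tau_fast,
      transient_threshold = as.numeric(f$transient_threshold %||% Inf),
      transient_half_life = f$transient_half_life),
    stop_domain("unknown preset class '", payload$class, "'"))
}
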