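#' Single-contraction waveform kernel
#'
#' Asymmetric raised-cosine contraction: a half-cosine rise from 0 to the
#' amplitude C over the time-to-peak E, then a half-cosine decay back to 0
#' over the decay time F. Continuous, peaks at exactly C at `t = E`, and
#' has closed-form phase areas C.E/2 (development) and C.F/2 (decay).
#'
#' @param t Time(s) since contraction onset (s). Values outside
#'   `[0, E+F]` return 0.
#' @param shape A [contraction_shape()].
#' @return Tension above baseline (mN), vectorized over `t`.
#' @export
contraction_kernel <- function(t, shape) {
  stopifnot(inherits(shape, "contraction_shape"))
  C <- shape$amplitude_C
  E <- shape$time_to_peak_E
  F_ <- shape$decay_time_F
  out <- numeric(length(t))
  rise <- t >= 0 & t <= E
  out[rise] <- C / 2 * (1 - cos(pi * t[rise] / E))
  dec <- t > E & t <= E + F_
  out[dec] <- C / 2 * (1 + cos(pi * (t[dec] - E) / F_))
  out
}

# per-substance envelope relaxation: first-order approach of the effect
# toward its (possibly fading) concentration-dependent target
relax_envelope <- function(t, additions, pd, endpoint) {
  n <- length(t)
  dt <- t[2] - t[1]
  hp <- pd[[endpoint]]
  target <- numeric(n)
  tau <- rep(pd$onset_tau_slow, n)
  if (nrow(additions)) {
    for (j in seq_len(nrow(additions))) {
      conc <- additions$conc_M[j]
      from <- additions$time_s[j]
      upto <- if (j < nrow(additions)) additions$time_s[j + 1] else Inf
      act <- t >= from & t < upto
      tgt <- hill_response(conc, hp)
      if (is.finite(pd$transient_threshold) && conc > pd$transient_threshold)
        tgt <- tgt * exp(-log(2) * (t[act] - from) / pd$transient_half_life)
      target[act] <- tgt
      tau[act] <- onset_tau_at(pd, conc)
    }
  }
  env <- numeric(n)
  alpha <- 1 - exp(-dt / tau)
  for (i in 2:n) env[i] <- env[i - 1] + (target[i] - env[i - 1]) * alpha[i]
  env
}

#' Simulate a spontaneous-contraction force trace with known ground truth
#'
#' Builds `baseline tone + treatment tone envelope + linear drift +
#' contraction-kernel train + white Gaussian noise` on a uniform grid.
#' Contraction onsets follow the shape's inter-onset interval, locally
#' rescaled by the frequency envelope; kernel amplitudes are scaled by the
#' amplitude envelope at onset. After each scheduled agonist addition the
#' tone/amplitude/frequency envelopes relax toward their Hill-model
#' targets with a concentration-dependent first-order time constant, and
#' fade with the model's transient half-life above its transience
#' threshold. Only contractions that complete within the trace are
#' generated.
#'
#' @param preset Either a preset name (`"proximal-default"`,
#'   `"distal-default"`) or a [contraction_shape()].
#' @param duration Trace length (s); > 0.
#' @param fs Sampling rate (Hz); default 10.
#' @param noise A [noise_params()]; defaults to the preset's noise when a
#'   preset name is given, else noise-free.
#' @param schedule Optional [treatment_schedule()] of agonist additions.
#' @param pd_models Named list of [agonist_pd_model()]s keyed by
#'   `schedule$substance`.
#' @param seed Optional integer seed; identical seed and parameters give a
#'   bitwise-identical trace.
#' @return A list with `trace` (a [force_trace()]) and `truth`, the
#'   ground-truth list: `event_onsets` (s, complete events only),
#'   `tone` / `amplitude_mult` / `frequency_mult` envelope series on the
#'   sample grid.
#' @export
simulate_trace <- function(preset, duration, fs = 10, noise = NULL,
                           schedule = NULL, pd_models = NULL, seed = NULL) {
  if (is.character(preset)) {
    p <- preset(preset)
    shape <- p$shape
    noise <- noise %||% p$noise
    region <- p$region
  } else {
    shape <- preset
    region <- NA_character_
  }
  stopifnot(inherits(shape, "contraction_shape"))
  noise <- noise %||% noise_params()
  assert_scalar(duration, "duration", 0, strict = TRUE)
  assert_scalar(fs, "fs", 0, strict = TRUE)
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "treatment_schedule"))
    if (any(schedule$time_s < 0 | schedule$time_s >= duration))
      stop_domain("schedule times must lie within [0, duration)")
    if (is.null(pd_models) ||
        !all(unique(schedule$substance) %in% names(pd_models)))
      stop_domain("pd_models must name every scheduled substance")
  }

  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1L) / fs
  E <- shape$time_to_peak_E
  F_ <- shape$decay_time_F

  tone_env <- numeric(n)
  amp_env <- rep(1, n)
  freq_env <- rep(1, n)
  if (!is.null(schedule) && nrow(schedule)) {
    for (s in unique(schedule$substance)) {
      add_s <- schedule[schedule$substance == s, , drop = FALSE]
      pd <- pd_models[[s]]
      stopifnot(inherits(pd, "agonist_pd_model"))
      tone_env <- tone_env + relax_envelope(t, add_s, pd, "tone")
      amp_env <- amp_env + relax_envelope(t, add_s, pd, "amplitude_scale")
      freq_env <- freq_env + relax_envelope(t, add_s, pd, "frequency_scale")
    }
  }
  if (any(freq_env <= 0)) stop_domain("frequency envelope became non-positive")

  # contraction onsets: interval divided by the local frequency multiplier
  onsets <- numeric(0)
  o <- 0
  while (o + E + F_ <= duration) {
    onsets <- c(onsets, o)
    f_loc <- freq_env[min(n, 1L + as.integer(floor(o * fs)))]
    step <- shape$inter_onset_interval / f_loc
    if (step < E)
      stop_domain("frequency scaling makes the inter-onset interval (",
                  format(step), " s) shorter than the rise time E (", E,
                  " s): kernels would overlap before peaking")
    o <- o + step
  }

  kern <- numeric(n)
  for (o in onsets) {
    i0 <- 1L + as.integer(ceiling(o * fs - 1e-9))
    i1 <- min(n, 1L + as.integer(floor((o + E + F_) * fs + 1e-9)))
    if (i1 >= i0) {
      a <- amp_env[min(n, 1L + as.integer(floor(o * fs)))]
      kern[i0:i1] <- kern[i0:i1] + a * contraction_kernel(t[i0:i1] - o, shape)
    }
  }

  eps <- with_seed(seed, stats::rnorm(n, 0, noise$additive_sd))
  force <- shape$baseline_tone + tone_env + noise$drift_rate * t / 60 + kern + eps

  trace <- force_trace(t, force, fs = fs,
                       metadata = list(region = region,
                                       schedule = schedule,
                                       seed = seed))
  truth <- list(event_onsets = onsets,
                tone = shape$baseline_tone + tone_env,
                amplitude_mult = amp_env,
                frequency_mult = freq_env)
  list(trace = trace, truth = truth)
}

#' Concentration-response dataset container
#'
#' @param conc_M Concentrations (M), one per row; strictly positive.
#' @param response Responses in endpoint units.
#' @param replicate Replicate/tissue id per row.
#' @param endpoint One of `"tone"`, `"amplitude"`, `"frequency"`,
#'   `"EFS-inhibition"`.
#' @return A data frame of class `concentration_response`.
#' @export
concentration_response <- function(conc_M, response, replicate = 1L,
                                   endpoint = "tone") {
  if (!length(conc_M)) stop_domain("empty concentration vector")
  if (any(conc_M <= 0)) stop_domain("concentrations must be > 0")
  df <- data.frame(conc_M = conc_M, response = response,
                   replicate = rep_len(replicate, length(conc_M)))
  for (r in unique(df$replicate)) {
    cc <- df$conc_M[df$replicate == r]
    if (is.unsorted(cc, strictly = TRUE))
      stop_domain("concentrations must be strictly increasing within replicate ", r)
  }
  attr(df, "endpoint") <- endpoint
  class(df) <- c("concentration_response", "data.frame")
  df
}

#' Simulate replicate concentration-response data from a Hill model
#'
#' Responses are the closed-form Hill values at each concentration —
#' with the EC50 Schild-shifted when a competitive antagonist is present —
#' perturbed by multiplicative Gaussian noise of coefficient of variation
#' `noise_cv`.
#'
#' @param model A [hill_params()] (or an [agonist_pd_model()], whose tone
#'   component is used).
#' @param concs Ascending agonist concentrations (M).
#' @param n_reps Number of replicates; >= 1.
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @param antagonist Optional `list(conc =, model =)` with an
#'   [antagonist_model()].
#' @param endpoint Endpoint label stored on the dataset.
#' @param seed Optional integer seed.
#' @return A [concentration_response()] data frame.
#' @export
simulate_crc_dataset <- function(model, concs, n_reps = 1L, noise_cv = 0,
                                 antagonist = NULL, endpoint = "tone",
                                 seed = NULL) {
  if (inherits(model, "agonist_pd_model")) model <- model$tone
  stopifnot(inherits(model, "hill_params"))
  if (!length(concs)) stop_domain("empty concentration vector")
  if (any(concs <= 0)) stop_domain("concentrations must be > 0")
  if (is.unsorted(concs, strictly = TRUE))
    stop_domain("concentrations must be strictly ascending")
  if (n_reps < 1) stop_domain("n_reps must be >= 1")
  assert_scalar(noise_cv, "noise_cv", 0)

  ec50 <- model$EC50
  if (!is.null(antagonist))
    ec50 <- competitive_ec50_shift(model$EC50, antagonist$conc, antagonist$model)
  gen <- hill_params(ec50, model$Emax, model$hill_slope)
  mu <- hill_response(concs, gen)

  resp <- with_seed(seed, {
    vapply(seq_len(n_reps),
           function(r) mu * (1 + stats::rnorm(length(mu), 0, noise_cv)),
           numeric(length(mu)))
  })
  concentration_response(rep(concs, times = n_reps), as.numeric(resp),
                         replicate = rep(seq_len(n_reps), each = length(concs)),
                         endpoint = endpoint)
}

#' Simulate an EFS recording
#'
#' One monophasic evoked contraction per stimulation train (raised-cosine
#' rise over the first 30% of the train, decay over the remainder), with
#' the evoked amplitude scaled by a drug-effect multiplier evaluated at
#' each train start. Only trains completing within the trace are
#' stimulated.
#'
#' @param efs An [efs_schedule()].
#' @param multiplier Drug effect on the evoked amplitude: a single number,
#'   a function of time (s), or a data frame `(time_s, multiplier)`
#'   applied as a right-continuous step function.
#' @param duration,fs,seed As in [simulate_trace()].
#' @param baseline Resting tone (mN).
#' @param noise A [noise_params()].
#' @return A list with `trace` ([force_trace()]) and `truth` listing
#'   `train_starts` (s) and the `evoked_amplitude` of each train (mN).
#' @export
simulate_efs_trace <- function(efs, multiplier = 1, duration, fs = 10,
                               baseline = 20, noise = noise_params(),
                               seed = NULL) {
  stopifnot(inherits(efs, "efs_schedule"))
  assert_scalar(duration, "duration", 0, strict = TRUE)
  mult_fun <- if (is.function(multiplier)) {
    multiplier
  } else if (is.data.frame(multiplier)) {
    stopifnot(all(c("time_s", "multiplier") %in% names(multiplier)))
    function(tt) {
      i <- findInterval(tt, multiplier$time_s)
      ifelse(i == 0, 1, multiplier$multiplier[pmax(i, 1)])
    }
  } else {
    force(multiplier)
    function(tt) rep_len(multiplier, length(tt))
  }

  starts <- seq(0, duration - efs$train_duration, by = efs$train_period)
  if (length(starts) > 1 &&
      any(diff(starts) < efs$train_duration))
    stop_domain("EFS train windows overlap")

  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1L) / fs
  evoked_shape <- contraction_shape(
    amplitude_C = 1,
    time_to_peak_E = 0.3 * efs$train_duration,
    decay_time_F = 0.7 * efs$train_duration,
    inter_onset_interval = efs$train_period, baseline_tone = 0)
  amps <- efs$evoked_amplitude * mult_fun(starts)
  kern <- numeric(n)
  for (k in seq_along(starts)) {
    i0 <- 1L + as.integer(ceiling(starts[k] * fs - 1e-9))
    i1 <- min(n, 1L + as.integer(floor((starts[k] + efs$train_duration) * fs + 1e-9)))
    kern[i0:i1] <- kern[i0:i1] +
      amps[k] * contraction_kernel(t[i0:i1] - starts[k], evoked_shape)
  }
  eps <- with_seed(seed, stats::rnorm(n, 0, noise$additive_sd))
  force <- baseline + noise$drift_rate * t / 60 + kern + eps
  trace <- force_trace(t, force, fs = fs,
                       metadata = list(protocol = "EFS", seed = seed))
  list(trace = trace,
       truth = list(train_starts = starts, evoked_amplitude = amps))
}
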