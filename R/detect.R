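#' Detection configuration
#'
#' Tunable parameters of the contraction-detection pipeline. Detection
#' runs on a lightly smoothed copy of the trace (centred moving average)
#' against a rolling lower-envelope baseline.
#'
#' @param baseline_window Rolling window for the baseline estimate (s).
#' @param baseline_prob Percentile used for the lower envelope (0-1).
#' @param smooth_window Moving-average width applied before peak search (s).
#' @param prominence_threshold Minimum peak prominence (mN); when `NULL`
#'   it is set per trace to `max(prominence_floor, 5 x noise SD)`, the
#'   noise SD being estimated from detrended first differences.
#' @param prominence_floor Lower bound on the automatic threshold (mN).
#' @param min_separation Minimum time between retained peaks (s).
#' @param onset_fraction Fraction of a peak's prominence (of its height
#'   above baseline) below which the trace must descend at the flanking
#'   troughs for them to delimit the event; in (0, 0.5].
#' @param window_length Default analysis window for summaries (s).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(baseline_window = 60, baseline_prob = 0.08,
                             smooth_window = 1.0,
                             prominence_threshold = NULL,
                             prominence_floor = 0.2,
                             min_separation = 5,
                             onset_fraction = 0.10,
                             window_length = 300) {
  assert_scalar(baseline_window, "baseline_window", 0, strict = TRUE)
  assert_scalar(baseline_prob, "baseline_prob", 0, strict = TRUE)
  assert_scalar(smooth_window, "smooth_window", 0, strict = TRUE)
  if (!is.null(prominence_threshold))
    assert_scalar(prominence_threshold, "prominence_threshold", 0, strict = TRUE)
  assert_scalar(prominence_floor, "prominence_floor", 0, strict = TRUE)
  assert_scalar(min_separation, "min_separation", 0, strict = TRUE)
  assert_scalar(onset_fraction, "onset_fraction", 0, strict = TRUE)
  if (onset_fraction > 0.5) stop_domain("onset_fraction must be in (0, 0.5]")
  assert_scalar(window_length, "window_length", 0, strict = TRUE)
  structure(list(baseline_window = baseline_window,
                 baseline_prob = baseline_prob,
                 smooth_window = smooth_window,
                 prominence_threshold = prominence_threshold,
                 prominence_floor = prominence_floor,
                 min_separation = min_separation,
                 onset_fraction = onset_fraction,
                 window_length = window_length),
            class = "detection_config")
}

smoothed_force <- function(trace, config) {
  moving_average(trace$force, round(config$smooth_window * trace$fs))
}

# noise SD from detrended first differences (robust to the slow
# contraction waveform, which contributes little sample-to-sample change)
estimate_noise_sd <- function(trace) {
  d <- diff(trace$force)
  stats::mad(d) / sqrt(2)
}

#' Rolling lower-envelope baseline tone
#'
#' Estimates the instantaneous baseline muscle tone as a rolling low
#' percentile (default 8th over 60 s) of the force, then smooths it;
#' the percentile sits below the 10th so the smoothed envelope stays a
#' lower envelope (under at least 90 percent of samples) on noisy data.
#' Phasic contractions occupy the upper part of the force distribution,
#' so the low percentile tracks the tone between contractions and follows
#' slow drift.
#'
#' @param trace A [force_trace()].
#' @param config A [detection_config()].
#' @return Numeric baseline series (mN) on the trace's sample grid.
#' @export
estimate_baseline <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "force_trace"))
  w <- as.integer(round(config$baseline_window * trace$fs))
  if (w >= length(trace$force))
    stop_domain("baseline window (", config$baseline_window,
                " s) must be shorter than the trace")
  env <- rolling_quantile(trace$force, w, config$baseline_prob)
  moving_average(env, round(10 * trace$fs))
}

# peak prominence: height above the higher of the two minima separating
# the peak from the nearest higher peak (or the record edge) on each side
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    lo_l <- {
      i <- p
      left <- which(x[seq_len(p - 1)] > x[p])
      lim <- if (length(left)) max(left) else 1L
      min(x[lim:p])
    }
    lo_r <- {
      right <- which(x[(p + 1):length(x)] > x[p])
      lim <- if (length(right)) p + min(right) else length(x)
      min(x[p:lim])
    }
    x[p] - max(lo_l, lo_r)
  }, numeric(1))
}

#' Detect spontaneous contractions
#'
#' Finds local maxima of the smoothed force with prominence at least the
#' (per-trace) threshold and at least `min_separation` apart (the more
#' prominent peak wins a conflict). Each event's onset and offset are the
#' flanking troughs: the minimum of the smoothed force between the peak
#' and its neighbouring peaks (or the record edge), ties resolved nearest
#' the peak, required to descend below
#' `baseline + onset_fraction x prominence`.
#'
#' @param trace A [force_trace()].
#' @param config A [detection_config()].
#' @return A data frame of class `contraction_events` with columns
#'   `onset_s`, `peak_s`, `offset_s`, `baseline_mN` (the event's local
#'   baseline: mean smoothed force at its flanking troughs) and
#'   `prominence_mN`; zero rows when nothing is detected.
#' @export
detect_contractions <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "force_trace"))
  x <- smoothed_force(trace, config)
  base <- estimate_baseline(trace, config)
  thr <- config$prominence_threshold %||%
    max(config$prominence_floor, 5 * estimate_noise_sd(trace))

  n <- length(x)
  empty <- structure(
    data.frame(onset_s = numeric(0), peak_s = numeric(0),
               offset_s = numeric(0), baseline_mN = numeric(0),
               prominence_mN = numeric(0)),
    class = c("contraction_events", "data.frame"),
    prominence_threshold = thr)
  if (n < 3) return(empty)

  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(empty)
  prom <- peak_prominence(x, cand)
  keep <- prom >= thr
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)

  # enforce minimum separation, keeping the more prominent peak
  min_sep <- config$min_separation * trace$fs
  ord <- order(prom, decreasing = TRUE)
  sel <- logical(length(cand))
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - taken) >= min_sep)) {
      sel[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  peaks <- sort(cand[sel])
  prom <- prom[sel][order(cand[sel])]

  # flanking troughs between adjacent peaks; the smoothed argmin locates
  # the trough region, then the boundary is refined on the raw force
  # within one smoothing window so that a flat inter-contraction gap
  # yields the sample nearest the peak (the true waveform edge)
  h_ref <- max(1L, as.integer(round(config$smooth_window * trace$fs)))
  y <- trace$force
  refine <- function(i_m, lim_lo, lim_hi, side) {
    lo <- max(lim_lo, i_m - h_ref)
    hi <- min(lim_hi, i_m + h_ref)
    seg <- y[lo:hi]
    cand <- which(seg <= min(seg) + 1e-9)
    lo - 1L + if (side == "left") max(cand) else min(cand)
  }
  bounds_lo <- integer(length(peaks))
  bounds_hi <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    lo_lim <- if (k == 1) 1L else peaks[k - 1]
    hi_lim <- if (k == length(peaks)) n else peaks[k + 1]
    seg_l <- x[lo_lim:peaks[k]]
    i_m <- lo_lim - 1L + max(which(seg_l == min(seg_l)))
    bounds_lo[k] <- refine(i_m, lo_lim, peaks[k] - 1L, "left")
    seg_r <- x[peaks[k]:hi_lim]
    i_m <- peaks[k] - 1L + min(which(seg_r == min(seg_r)))
    bounds_hi[k] <- refine(i_m, peaks[k] + 1L, hi_lim, "right")
  }

  t <- trace$time
  # local baseline of an event: mean smoothed force at its two troughs
  ev <- data.frame(onset_s = t[bounds_lo], peak_s = t[peaks],
                   offset_s = t[bounds_hi],
                   baseline_mN = (x[bounds_lo] + x[bounds_hi]) / 2,
                   prominence_mN = prom)
  # troughs must descend below the onset-fraction level of the peak height
  depth_ok <- x[bounds_lo] <= base[peaks] + config$onset_fraction * prom &
    x[bounds_hi] <= base[peaks] + config$onset_fraction * prom
  ev <- ev[depth_ok & ev$onset_s < ev$peak_s & ev$peak_s < ev$offset_s, ,
           drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("contraction_events", "data.frame"),
            prominence_threshold = thr)
}

#' Motility features of detected contractions
#'
#' Computes, per event, the eight standard motility parameters: amplitude
#' C (peak force minus local baseline, mN), total contraction time
#' D = E + F (s), time to peak E and decay time F (s), development and
#' decay areas G and H (trapezoidal area above the local baseline over
#' onset-to-peak and peak-to-offset, mN.s), total area AUC = G + H, and
#' the development/decay rates C/E and C/F (mN/s).
#'
#' @param trace A [force_trace()].
#' @param events A `contraction_events` data frame from
#'   [detect_contractions()], or any data frame with `onset_s`, `peak_s`,
#'   `offset_s` columns.
#' @param config A [detection_config()] (smoothing and baseline must match
#'   detection).
#' @return The events with feature columns `C_mN`, `D_s`, `E_s`, `F_s`,
#'   `G`, `H`, `AUC_total`, `rate_dev`, `rate_decay` appended. Area
#'   columns are mN.s (the attribute `area_units` records this).
#' @export
extract_features <- function(trace, events, config = detection_config()) {
  stopifnot(inherits(trace, "force_trace"))
  if (nrow(events) == 0L) {
    for (col in c("C_mN", "D_s", "E_s", "F_s", "G", "H", "AUC_total",
                  "rate_dev", "rate_decay")) events[[col]] <- numeric(0)
    attr(events, "area_units") <- "mN.s"
    return(events)
  }
  if (any(!(events$onset_s < events$peak_s & events$peak_s < events$offset_s)))
    stop_domain("degenerate event: need onset < peak < offset")
  x <- smoothed_force(trace, config)
  t <- trace$time
  idx_of <- function(tt) pmin(length(t), pmax(1L, round((tt - t[1]) * trace$fs) + 1L))

  i_on <- idx_of(events$onset_s)
  i_pk <- idx_of(events$peak_s)
  i_off <- idx_of(events$offset_s)
  # local baseline: mean smoothed force at the event's flanking troughs
  b_loc <- if ("baseline_mN" %in% names(events)) events$baseline_mN
           else (x[i_on] + x[i_off]) / 2
  C <- x[i_pk] - b_loc
  E <- events$peak_s - events$onset_s
  F_ <- events$offset_s - events$peak_s
  area <- function(i0, i1, b) {
    y <- pmax(0, x[i0:i1] - b)
    sum((y[-1] + y[-length(y)]) / 2) / trace$fs
  }
  G <- mapply(area, i_on, i_pk, b_loc)
  H <- mapply(area, i_pk, i_off, b_loc)
  events$C_mN <- C
  events$D_s <- E + F_
  events$E_s <- E
  events$F_s <- F_
  events$G <- G
  events$H <- H
  events$AUC_total <- G + H
  events$rate_dev <- C / E
  events$rate_decay <- C / F_
  attr(events, "area_units") <- "mN.s"
  events
}

#' Windowed before/after summary of tone, frequency and features
#'
#' Summarises a time window of a trace relative to a reference window:
#' the tone change A (mean baseline tone in the window minus the mean in
#' the reference window, mN), the contraction frequency (events whose
#' peak lies in the window, per minute), and the mean motility features
#' over events lying completely inside the window.
#'
#' @param trace A [force_trace()].
#' @param window `c(start, end)` of the analysis window (s).
#' @param reference_window `c(start, end)` of the reference (pre-drug)
#'   window; must not start after `window`.
#' @param config A [detection_config()].
#' @param events Optional precomputed feature table (from
#'   [extract_features()]); detected on the fly when omitted.
#' @return A list of class `window_summary`: `mean_tone_mN` (absolute
#'   mean baseline tone in the window), `tone_change_mN`,
#'   `frequency_cpm`, `n_events`, `mean_features` (named numeric),
#'   `window`, `reference_window`, and `short_window` flag (window
#'   shorter than the median inter-onset interval).
#' @export
window_summary <- function(trace, window, reference_window = window,
                           config = detection_config(), events = NULL) {
  stopifnot(inherits(trace, "force_trace"), length(window) == 2,
            length(reference_window) == 2)
  t0 <- trace$time[1]; t1 <- trace$time[length(trace$time)]
  if (window[1] < t0 - 1e-9 || window[2] > t1 + 1 / trace$fs + 1e-9 ||
      reference_window[1] < t0 - 1e-9 || reference_window[2] > t1 + 1 / trace$fs + 1e-9)
    stop_domain("windows must lie within the trace")
  if (reference_window[1] > window[1])
    stop_domain("reference window must precede (or equal) the analysis window")

  base <- estimate_baseline(trace, config)
  in_win <- function(w) trace$time >= w[1] & trace$time < w[2]
  A <- mean(base[in_win(window)]) - mean(base[in_win(reference_window)])

  if (is.null(events)) {
    events <- extract_features(trace, detect_contractions(trace, config), config)
  }
  pk_in <- events$peak_s >= window[1] & events$peak_s < window[2]
  minutes <- (window[2] - window[1]) / 60
  freq <- sum(pk_in) / minutes

  complete <- pk_in & events$onset_s >= window[1] & events$offset_s <= window[2]
  feat_cols <- c("C_mN", "D_s", "E_s", "F_s", "G", "H", "AUC_total",
                 "rate_dev", "rate_decay")
  mean_features <- if (any(complete) && all(feat_cols %in% names(events))) {
    colMeans(events[complete, feat_cols, drop = FALSE])
  } else {
    stats::setNames(rep(NA_real_, length(feat_cols)), feat_cols)
  }

  med_ioi <- if (nrow(events) > 1) stats::median(diff(events$onset_s)) else Inf
  structure(list(mean_tone_mN = mean(base[in_win(window)]),
                 tone_change_mN = A, frequency_cpm = freq,
                 n_events = sum(pk_in), mean_features = mean_features,
                 window = window, reference_window = reference_window,
                 short_window = (window[2] - window[1]) < med_ioi),
            class = "window_summary")
}

#' @export
print.window_summary <- function(x, ...) {
  cat(sprintf("Window [%g, %g) s: tone change A = %+.2f mN, %.2f c.p.m. (%d events)\n",
              x$window[1], x$window[2], x$tone_change_mN, x$frequency_cpm,
              x$n_events))
  invisible(x)
}

#' Express a tone change as percent of the carbachol maximum
#'
#' Agonist-induced tone changes are normalised to the tissue's maximal
#' contractile capacity, probed with 1 mM carbachol at the end of an
#' experiment.
#'
#' @param delta_tone Tone change (mN).
#' @param carbachol_max Carbachol-evoked maximal tone increase (mN); > 0.
#' @return `100 * delta_tone / carbachol_max` (percent).
#' @export
percent_of_carbachol <- function(delta_tone, carbachol_max) {
  assert_scalar(carbachol_max, "carbachol_max", 0, strict = TRUE)
  100 * delta_tone / carbachol_max
}

#' EFS-evoked contraction amplitudes and percent change
#'
#' Per stimulation train, the evoked amplitude is the maximum force inside
#' the train window minus the baseline immediately before the train (mean
#' force over the 3 s preceding the train start). Percent change is
#' relative to the mean amplitude of the trains inside `pre_drug_window`.
#'
#' @param trace A [force_trace()].
#' @param efs The [efs_schedule()] used during the recording.
#' @param pre_drug_window `c(start, end)` (s) delimiting the pre-drug
#'   reference trains (train starts falling inside it).
#' @return A data frame with `train_start_s`, `amplitude_mN` and
#'   `percent_change` columns.
#' @export
efs_responses <- function(trace, efs, pre_drug_window) {
  stopifnot(inherits(trace, "force_trace"), inherits(efs, "efs_schedule"))
  t <- trace$time
  dur_tr <- t[length(t)] - t[1] + 1 / trace$fs
  starts <- seq(0, t[length(t)] - efs$train_duration, by = efs$train_period)
  if (!length(starts)) stop_domain("no complete EFS trains within the trace")
  amp <- vapply(starts, function(s0) {
    w <- t >= s0 & t <= s0 + efs$train_duration
    pre <- t >= max(t[1], s0 - 3) & t < s0
    b <- if (any(pre)) mean(trace$force[pre]) else trace$force[which(w)[1]]
    max(trace$force[w]) - b
  }, numeric(1))
  ref_idx <- starts >= pre_drug_window[1] & starts < pre_drug_window[2]
  if (!any(ref_idx)) stop_domain("no EFS trains within the pre-drug window")
  ref <- mean(amp[ref_idx])
  data.frame(train_start_s = starts, amplitude_mN = amp,
             percent_change = 100 * (amp - ref) / ref)
}
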