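#' Radar-plot table: treated waveform relative to baseline
#'
#' Assembles the normalised data behind the radar plots that compare a
#' treated contraction waveform with its baseline: for each motility
#' parameter (tone, frequency and the eight per-contraction features)
#' the treated value divided by the baseline value, with the baseline
#' series identically 1. Parameters whose baseline value is zero are
#' flagged rather than divided.
#'
#' @param baseline,treated [window_summary()] objects for the pre- and
#'   post-treatment windows of the same tissue.
#' @return A data frame of class `radar_table` with columns `parameter`,
#'   `baseline` (all 1), `treated` (ratio; `NA` when flagged) and
#'   `flagged` (baseline parameter was 0 or unavailable).
#' @export
assemble_radar <- function(baseline, treated) {
  stopifnot(inherits(baseline, "window_summary"),
            inherits(treated, "window_summary"))
  vals <- function(s) c(tone_mN = s$mean_tone_mN,
                        frequency_cpm = s$frequency_cpm,
                        s$mean_features)
  b <- vals(baseline)
  tr <- vals(treated)
  if (!identical(names(b), names(tr)))
    stop_domain("summaries carry different parameter sets")
  flag <- !is.finite(b) | b == 0 | !is.finite(tr)
  ratio <- ifelse(flag, NA_real_, tr / b)
  structure(data.frame(parameter = names(b),
                       baseline = ifelse(flag, NA_real_, 1),
                       treated = ratio, flagged = flag,
                       row.names = NULL),
            class = c("radar_table", "data.frame"))
}

#' Run configuration for the end-to-end pipeline
#'
#' @param preset Preset name or [contraction_shape()] for simulation, or
#'   `NULL` when `input_trace` is given.
#' @param input_trace Optional path to an existing trace CSV.
#' @param duration,fs Simulation length (s) and sampling rate (Hz).
#' @param schedule Optional [treatment_schedule()].
#' @param pd_models Named list of [agonist_pd_model()]s for the schedule.
#' @param detection A [detection_config()].
#' @param windows Optional named list of `c(start, end)` windows;
#'   `windows$reference` is the pre-drug reference, every other entry is
#'   summarised against it.
#' @param seed Integer seed recorded in every report.
#' @param outdir Output directory (created if needed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(preset = NULL, input_trace = NULL, duration = 1200,
                       fs = 10, schedule = NULL, pd_models = NULL,
                       detection = detection_config(), windows = NULL,
                       seed = 1L, outdir = tempfile("gastromot-run-")) {
  if (is.null(preset) && is.null(input_trace))
    stop_domain("run_config: either 'preset' or 'input_trace' must be given")
  if (!is.null(input_trace) && !file.exists(input_trace))
    stop_domain("run_config: input_trace '", input_trace, "' does not exist")
  structure(list(preset = preset, input_trace = input_trace,
                 duration = duration, fs = fs, schedule = schedule,
                 pd_models = pd_models, detection = detection,
                 windows = windows, seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_domain("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the simulate / analyze / summarise pipeline
#'
#' Executes the configured stages — simulate (or read) a trace, detect
#' contractions and extract features, summarise windows against the
#' reference, assemble radar tables — and writes the event table,
#' window summaries and a JSON run report (with seed and configuration
#' hash) under `config$outdir`.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with `trace`, `truth` (when simulated),
#'   `events`, `summaries`, `radar`, and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  trace <- if (!is.null(config$input_trace)) {
    stage("read", read_trace(config$input_trace))
  } else {
    sim <- stage("simulate",
                 simulate_trace(config$preset, duration = config$duration,
                                fs = config$fs, schedule = config$schedule,
                                pd_models = config$pd_models,
                                seed = config$seed))
    truth <- sim$truth
    sim$trace
  }

  events <- stage("analyze", {
    ev <- detect_contractions(trace, config$detection)
    extract_features(trace, ev, config$detection)
  })
  paths <- list(events = file.path(config$outdir, "events.csv"))
  write_events(events, paths$events)

  summaries <- NULL
  radar <- NULL
  if (!is.null(config$windows)) {
    summaries <- stage("summarise", {
      ref <- config$windows$reference
      if (is.null(ref)) stop("windows$reference is missing")
      others <- config$windows[setdiff(names(config$windows), "reference")]
      s <- lapply(others, function(w)
        window_summary(trace, w, ref, config$detection, events = events))
      s$reference <- window_summary(trace, ref, ref, config$detection,
                                    events = events)
      s
    })
    if (length(summaries) > 1) {
      radar <- stage("radar", {
        others <- setdiff(names(summaries), "reference")
        lapply(stats::setNames(others, others), function(nm)
          assemble_radar(summaries$reference, summaries[[nm]]))
      })
      paths$radar <- file.path(config$outdir, "radar.csv")
      flat <- do.call(rbind, lapply(names(radar), function(nm)
        cbind(condition = nm, radar[[nm]])))
      utils::write.csv(flat, paths$radar, row.names = FALSE)
    }
  }

  paths$report <- file.path(config$outdir, "report.json")
  cfg_for_hash <- config[setdiff(names(config), "outdir")]
  report <- list(
    package = "gastromot",
    package_version = as.character(utils::packageVersion("gastromot")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = sum(utf8ToInt(paste(utils::capture.output(utils::str(cfg_for_hash)),
                                      collapse = ""))),
    n_events = nrow(events),
    summaries = if (!is.null(summaries))
      lapply(summaries, function(s)
        list(tone_change_mN = s$tone_change_mN,
             frequency_cpm = s$frequency_cpm, n_events = s$n_events)))
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(trace = trace, truth = truth, events = events,
                 summaries = summaries, radar = radar, paths = paths))
}
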