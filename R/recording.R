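#' Construct a single-channel EEG recording
#'
#' Container for one uniformly sampled microvolt time series with named event
#' markers (e.g. `LOR`, `ROR`, `emergence_start`), a group label and an
#' optional `truth` record of generating parameters (kept by the synthetic
#' generator so recovery tests can compare estimates against it).
#'
#' @param samples Numeric vector of microvolt values.
#' @param sample_rate_hz Samples per second.
#' @param events Named numeric vector or list of event times in seconds from
#'   record start. May be empty.
#' @param group Group label (character scalar) or `NA`.
#' @param subject_id Identifier (character scalar).
#' @param truth Optional list of generating parameters.
#'
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 10 * seq(0, 2, by = 0.01)), 100,
#'                      events = c(LOR = 1), subject_id = "s1")
#' duration(rec)
#' @export
eeg_recording <- function(samples, sample_rate_hz, events = numeric(),
                          group = NA_character_, subject_id = "subject",
                          truth = NULL) {
  check_samples(samples)
  check_number(sample_rate_hz, "sample_rate_hz", lower = 1e-9)
  events <- unlist(events) %||% numeric()
  if (length(events) && is.null(names(events))) {
    abort("`events` must be named (e.g. LOR, ROR, emergence_start).")
  }
  dur <- length(samples) / sample_rate_hz
  if (length(events) && (any(events < 0) || any(events > dur))) {
    abort("All event times must lie within [0, duration].")
  }
  if (all(c("ROR", "emergence_start") %in% names(events)) &&
      events[["ROR"]] <= events[["emergence_start"]]) {
    abort("`ROR` must come after `emergence_start`.")
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz,
                 events = events,
                 group = group,
                 subject_id = subject_id,
                 truth = truth),
            class = "eeg_recording")
}

#' Duration of a recording in seconds
#' @param rec An [eeg_recording()].
#' @return Numeric scalar, seconds.
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  length(rec$samples) / rec$sample_rate_hz
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s%s: %.1f s @ %g Hz",
              x$subject_id,
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              duration(x), x$sample_rate_hz))
  if (length(x$events)) {
    cat(sprintf("\n  events: %s",
                paste(sprintf("%s=%g s", names(x$events), x$events),
                      collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @export
as_tibble.eeg_recording <- function(x, ...) {
  tibble(time_s = (seq_along(x$samples) - 1) / x$sample_rate_hz,
         eeg_uv = x$samples)
}

#' Write / read a recording as plain-text CSV
#'
#' `write_recording()` writes two CSV files: `<path>` with columns
#' `time_s, eeg_uv` and `<path minus .csv>_events.csv` with columns
#' `event, time_s`. `read_recording()` reads them back, validating that the
#' time stamps are uniform and that all required events are present.
#'
#' @param rec An [eeg_recording()].
#' @param path CSV file path for the samples.
#' @param events_path Events CSV path; defaults to `<path>_events.csv`.
#' @param required_events Character vector of event names that must be
#'   present (default none).
#' @param sample_rate_hz Expected sampling rate; if supplied and the file's
#'   rate differs by more than 10^-6 relative, reading fails (no silent
#'   resampling).
#' @param group,subject_id Metadata attached to the recording read back.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an [eeg_recording()].
#' @export
write_recording <- function(rec, path, events_path = default_events_path(path)) {
  stopifnot(inherits(rec, "eeg_recording"))
  readr::write_csv(as_tibble(rec), path, progress = FALSE)
  ev <- tibble(event = names(rec$events) %||% character(),
               time_s = as.numeric(rec$events))
  readr::write_csv(ev, events_path, progress = FALSE)
  invisible(path)
}

default_events_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_events.csv")
}

#' @rdname write_recording
#' @export
read_recording <- function(path, events_path = default_events_path(path),
                           required_events = character(),
                           sample_rate_hz = NULL,
                           group = NA_character_, subject_id = NULL) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "eeg_uv") %in% names(dat))) {
    abort("Recording CSV must have columns `time_s` and `eeg_uv`.")
  }
  dt <- diff(dat$time_s)
  if (length(dt) < 1L) abort("Recording CSV holds fewer than two samples.")
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
    abort("Recording CSV time stamps are not uniformly spaced.")
  }
  fs <- 1 / dt[1]
  if (!is.null(sample_rate_hz) &&
      abs(fs - sample_rate_hz) > 1e-6 * sample_rate_hz) {
    abort(sprintf(
      "Sample rate in file (%g Hz) does not match the expected %g Hz; %s",
      fs, sample_rate_hz, "resampling is not performed implicitly."))
  }
  events <- numeric()
  if (file.exists(events_path)) {
    ev <- readr::read_csv(events_path, show_col_types = FALSE,
                          progress = FALSE)
    if (nrow(ev)) events <- setNames(ev$time_s, ev$event)
  }
  missing_ev <- setdiff(required_events, names(events))
  if (length(missing_ev)) {
    abort(paste0("Recording is missing required event(s): ",
                 paste(missing_ev, collapse = ", ")))
  }
  eeg_recording(dat$eeg_uv, fs, events = events, group = group,
                subject_id = subject_id %||%
                  sub("\\.csv$", "", basename(path)))
}
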