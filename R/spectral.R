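# Windowed spectral analysis: Welch PSD, density spectral arrays, band power.

# Internal Welch estimator returning bare numeric vectors. Hamming-tapered
# sub-windows with 50% overlap, per-sub-window mean removal; one-sided
# density scaling (uV^2/Hz).
welch_psd <- function(x, fs, subwindow_s = 2, overlap = 0.5) {
  nper <- round(subwindow_s * fs)
  n <- length(x)
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  k <- seq_len(nper) - 1L
  w <- 0.54 - 0.46 * cos(2 * pi * k / (nper - 1))
  u <- fs * sum(w^2)
  nfreq <- nper %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nfreq)]
    acc <- acc + (Mod(X)^2) / u
  }
  pxx <- acc / length(starts)
  # one-sided: double everything except DC and (for even nper) Nyquist
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  list(freq_hz = k[seq_len(nfreq)] * fs / nper, power = pxx * dbl)
}

#' Welch power spectral density of one EEG segment
#'
#' One-sided PSD via Welch averaging: 2 s Hamming sub-windows with 50%
#' overlap, per-sub-window mean removal (0.5 Hz resolution at 100 Hz).
#'
#' @param segment Numeric vector of microvolt samples.
#' @param sample_rate_hz Samples per second.
#' @param subwindow_s Welch sub-window length in seconds (default 2).
#' @param overlap Fractional sub-window overlap (default 0.5).
#' @return A tibble with columns `freq_hz` and `power_uv2_hz`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 0.01))
#' p <- psd(x, 100)
#' p$freq_hz[which.max(p$power_uv2_hz)]
#' @export
psd <- function(segment, sample_rate_hz, subwindow_s = 2, overlap = 0.5) {
  check_samples(segment, "segment")
  check_number(sample_rate_hz, "sample_rate_hz", lower = 1e-9)
  if (length(segment) < 2 * sample_rate_hz) {
    abort("`segment` must hold at least 2 s of samples.")
  }
  est <- welch_psd(segment, sample_rate_hz, subwindow_s, overlap)
  tibble(freq_hz = est$freq_hz, power_uv2_hz = est$power)
}

#' Density spectral array (sliding-window PSD)
#'
#' Computes one Welch PSD per analysis window on a regular grid of window
#' starts (`0, hop_s, 2 hop_s, ...`). A window `[t, t + window_s)` is indexed
#' by its start `t`, so "the value 15 s before an event" is the window
#' starting 15 s before the event and containing only pre-event signal.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Analysis window length in seconds (default 10).
#' @param hop_s Window shift in seconds (default 1).
#' @param normalized If `TRUE`, each window's PSD is divided by its own
#'   integral over `norm_band` so rows integrate to 1 over that band.
#' @param norm_band Reporting band used for normalization (default 6-30 Hz,
#'   the recorder's reliable range).
#' @return A long tibble of class `eeg_dsa` with columns `time_s`, `freq_hz`,
#'   `power` and attributes `window_s`, `hop_s`, `normalized`, `events`,
#'   `group`, `subject_id`.
#' @examples
#' rec <- eeg_recording(rnorm(6000), 100, subject_id = "s1")
#' d <- dsa(rec)
#' length(unique(d$time_s))  # 51 windows for a 60 s record
#' @export
dsa <- function(rec, window_s = 10, hop_s = 1, normalized = FALSE,
                norm_band = c(6, 30)) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate_hz
  dur <- duration(rec)
  if (window_s > dur) {
    abort(sprintf("Window (%g s) is longer than the record (%g s).",
                  window_s, dur))
  }
  starts <- seq(0, dur - window_s, by = hop_s)
  nwin <- round(window_s * fs)
  first <- welch_psd(rec$samples[seq_len(nwin)], fs)
  freqs <- first$freq_hz
  mat <- matrix(0, nrow = length(starts), ncol = length(freqs))
  mat[1, ] <- first$power
  for (i in seq_along(starts)[-1]) {
    i0 <- round(starts[i] * fs)
    mat[i, ] <- welch_psd(rec$samples[(i0 + 1):(i0 + nwin)], fs)$power
  }
  if (normalized) {
    sel <- freqs >= norm_band[1] & freqs <= norm_band[2]
    fsub <- freqs[sel]
    for (i in seq_len(nrow(mat))) {
      tot <- trapz_int(fsub, mat[i, sel])
      if (tot > 0) mat[i, ] <- mat[i, ] / tot
    }
  }
  out <- tibble(time_s = rep(starts, times = length(freqs)),
                freq_hz = rep(freqs, each = length(starts)),
                power = as.vector(mat))
  structure(out, class = c("eeg_dsa", class(out)),
            window_s = window_s, hop_s = hop_s, normalized = normalized,
            norm_band = norm_band, sample_rate_hz = fs,
            events = rec$events, group = rec$group,
            subject_id = rec$subject_id)
}

dsa_meta <- function(spec) {
  list(window_s = attr(spec, "window_s") %||% 10,
       hop_s = attr(spec, "hop_s") %||% 1,
       events = attr(spec, "events") %||% numeric(),
       normalized = isTRUE(attr(spec, "normalized")))
}

#' Band-power trend from a spectrogram
#'
#' Trapezoidal integration of each spectrogram row over a frequency band.
#' Conventional band edges used throughout the package: alpha 8-12 Hz,
#' beta 13-30 Hz, reporting band 6-30 Hz.
#'
#' @param spec An `eeg_dsa` tibble from [dsa()].
#' @param band Length-2 numeric `(low, high)` in Hz.
#' @return A tibble with columns `time_s`, `power_uv2` and attribute `band`.
#' @examples
#' rec <- eeg_recording(rnorm(3000), 100)
#' bp <- band_power(dsa(rec), c(8, 12))
#' head(bp)
#' @export
band_power <- function(spec, band) {
  if (length(band) != 2L || band[2] <= band[1]) {
    abort("`band` must be an increasing (low, high) pair.")
  }
  fr <- sort(unique(spec$freq_hz))
  if (band[1] < min(fr) || band[2] > max(fr)) {
    abort(sprintf("Band %g-%g Hz is outside the frequency support %g-%g Hz.",
                  band[1], band[2], min(fr), max(fr)))
  }
  sel <- spec$freq_hz >= band[1] & spec$freq_hz <= band[2]
  sub <- spec[sel, , drop = FALSE]
  out <- sub |>
    dplyr::arrange(.data$time_s, .data$freq_hz) |>
    dplyr::summarise(power_uv2 = trapz_int(.data$freq_hz, .data$power),
                     .by = "time_s")
  structure(out, band = band, hop_s = attr(spec, "hop_s"),
            window_s = attr(spec, "window_s"), events = attr(spec, "events"))
}

#' Extract the value nearest an event-relative time point
#'
#' Returns the spectrogram row or trend value whose window timestamp is
#' nearest to `event_time_s + offset_s`. Requests outside the covered grid
#' raise an error rather than being clamped.
#'
#' @param x An `eeg_dsa` spectrogram or a trend tibble with a `time_s`
#'   column (e.g. from [band_power()], [peen_trend()], [index_trend()]).
#' @param event_time_s Event time in seconds from record start.
#' @param offset_s Offset relative to the event (e.g. -15 or +30).
#' @param col Optional column name; if supplied, the scalar value of that
#'   column is returned instead of the full row.
#' @return For a spectrogram: a tibble `freq_hz`, `power` for the selected
#'   window. For a trend: a one-row tibble (or a scalar if `col` is given).
#' @export
extract_window_at <- function(x, event_time_s, offset_s, col = NULL) {
  times <- sort(unique(x$time_s))
  target <- event_time_s + offset_s
  hop <- if (length(times) > 1) min(diff(times)) else 1
  if (target < times[1] - hop / 2 - 1e-9 ||
      target > times[length(times)] + hop / 2 + 1e-9) {
    abort(sprintf(
      "Requested time %g s (event %g %+g s) is outside the covered grid [%g, %g] s.",
      target, event_time_s, offset_s, times[1], times[length(times)]))
  }
  tsel <- times[which.min(abs(times - target))]
  row <- x[x$time_s == tsel, , drop = FALSE]
  if (inherits(x, "eeg_dsa")) {
    return(tibble(freq_hz = row$freq_hz, power = row$power))
  }
  row <- as_tibble(as.data.frame(row))
  if (!is.null(col)) return(row[[col]])
  row
}

#' Write / read a spectrogram as long-format CSV
#' @param spec An `eeg_dsa` tibble.
#' @param path CSV path.
#' @return `write_dsa_csv()` returns `path` invisibly; `read_dsa_csv()`
#'   returns an `eeg_dsa` tibble (grid metadata re-derived from the time
#'   stamps).
#' @export
write_dsa_csv <- function(spec, path) {
  readr::write_csv(as_tibble(as.data.frame(spec)), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_dsa_csv
#' @param window_s,hop_s,normalized Grid metadata to re-attach on read.
#' @export
read_dsa_csv <- function(path, window_s = 10, hop_s = 1, normalized = FALSE) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  structure(out, class = c("eeg_dsa", class(out)), window_s = window_s,
            hop_s = hop_s, normalized = normalized)
}

#' Convert power to decibels for display
#' @param power Power values in uV^2/Hz.
#' @return `10 * log10(power)` relative to 1 uV^2/Hz.
#' @export
power_db <- function(power) 10 * log10(power)
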