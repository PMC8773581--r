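# Transparent depth-of-anaesthesia index: spectral log-energy ratios,
# burst suppression ratio, and a monotone logistic 0-100 composite. This is
# an open proxy built from the same stated inputs as the commercial index
# (alpha-ratio, beta-ratio, their difference, BS%); no claim of numerical
# equivalence with the proprietary ANFIS mapping is made.

# Band edges of the log energy ratios. The commercial definitions are
# proprietary; these follow the published sub-parameter family:
#   alpha_ratio = log(E[30-42] / E[6-12])
#   beta_ratio  = log(E[30-42] / E[11-21])
INDEX_BANDS <- list(high = c(30, 42), alpha = c(6, 12), beta = c(11, 21))

# Energy floor preventing -Inf ratios on suppressed windows.
ENERGY_FLOOR_UV2 <- 1e-6

# Composite mapping constants: calibrated once on the synthetic generator so
# that awake-like spectra map >= 85 and deep alpha-dominant spectra <= 50,
# then frozen. Never refit at analysis time.
INDEX_WEIGHTS <- c(intercept = 3.0, alpha_ratio = 1.2, beta_ratio = 1.0,
                   beta_over_alpha = 0.3)

#' Burst suppression ratio of a segment
#'
#' Percentage of time the rectified, smoothed amplitude envelope stays below
#' `amp_threshold_uv` for at least `min_suppress_s` contiguous seconds.
#'
#' @param segment Numeric microvolt samples (at least 5 s).
#' @param sample_rate_hz Samples per second.
#' @param amp_threshold_uv Suppression amplitude threshold in microvolts
#'   (default 5).
#' @param min_suppress_s Minimum suppression run length in seconds
#'   (default 2).
#' @param smooth_s Envelope smoothing window in seconds (default 0.25).
#' @return Percent of the segment suppressed, in `[0, 100]`.
#' @examples
#' burst_suppression_ratio(rep(0, 1000), 100)   # 100
#' @export
burst_suppression_ratio <- function(segment, sample_rate_hz,
                                    amp_threshold_uv = 5,
                                    min_suppress_s = 2,
                                    smooth_s = 0.25) {
  check_samples(segment, "segment")
  check_number(amp_threshold_uv, "amp_threshold_uv", lower = 1e-12)
  if (length(segment) < 5 * sample_rate_hz) {
    abort("`segment` must hold at least 5 s of samples.")
  }
  env <- smooth_envelope(abs(segment), sample_rate_hz * smooth_s)
  below <- env < amp_threshold_uv
  r <- rle(below)
  min_run <- min_suppress_s * sample_rate_hz
  keep <- r$values & r$lengths >= min_run
  100 * sum(r$lengths[keep]) / length(segment)
}

#' Spectral sub-parameters of one PSD window
#'
#' Computes the alpha-ratio `log(E[30-42]/E[6-12])`, beta-ratio
#' `log(E[30-42]/E[11-21])` and their difference from trapezoid band
#' energies, with energies floored at a small positive constant so suppressed
#' windows stay finite. The difference of the two log ratios equals the log
#' of the energy-ratio quotient, avoiding a division of signed logs.
#'
#' @param psd_tbl A tibble `freq_hz`, `power_uv2_hz` (or `power`) covering
#'   6-42 Hz, e.g. from [psd()].
#' @param bsr_percent Burst suppression percentage of the same window
#'   (default 0).
#' @param window_time_s Optional timestamp carried through.
#' @return One-row tibble: `alpha_ratio`, `beta_ratio`, `beta_over_alpha`,
#'   `bsr_percent`, `window_time_s`.
#' @export
sub_params <- function(psd_tbl, bsr_percent = 0, window_time_s = NA_real_) {
  pw <- psd_tbl[["power_uv2_hz"]] %||% psd_tbl[["power"]]
  fr <- psd_tbl$freq_hz
  if (min(fr) > 6 || max(fr) < 42) {
    abort("PSD must cover 6-42 Hz to form the index sub-parameters.")
  }
  check_number(bsr_percent, "bsr_percent", lower = 0, upper = 100)
  energy <- function(band) {
    sel <- fr >= band[1] & fr <= band[2]
    max(trapz_int(fr[sel], pw[sel]), ENERGY_FLOOR_UV2)
  }
  e_high <- energy(INDEX_BANDS$high)
  a <- log(e_high / energy(INDEX_BANDS$alpha))
  b <- log(e_high / energy(INDEX_BANDS$beta))
  tibble(alpha_ratio = a, beta_ratio = b, beta_over_alpha = b - a,
         bsr_percent = bsr_percent, window_time_s = window_time_s)
}

#' Composite 0-100 depth index
#'
#' Logistic map of a weighted sum of the spectral sub-parameters, scaled to
#' `[0, 100]` and pulled linearly towards 0 in proportion to BS%. The map is
#' monotone nondecreasing in each spectral ratio (positive weights) and
#' non-increasing in BS%; full suppression forces 0.
#'
#' @param params A tibble from [sub_params()] (one or more rows).
#' @param weights Named numeric mapping constants; the frozen defaults were
#'   calibrated once on the synthetic generator.
#' @return Numeric vector of index values in `[0, 100]`.
#' @examples
#' p <- tibble::tibble(alpha_ratio = 0, beta_ratio = 0, beta_over_alpha = 0,
#'                     bsr_percent = 0)
#' composite_index(p)
#' @export
composite_index <- function(params, weights = INDEX_WEIGHTS) {
  s <- weights[["intercept"]] +
    weights[["alpha_ratio"]] * params$alpha_ratio +
    weights[["beta_ratio"]] * params$beta_ratio +
    weights[["beta_over_alpha"]] * params$beta_over_alpha
  idx <- 100 / (1 + exp(-s))
  idx <- idx * (1 - params$bsr_percent / 100)
  pmin(100, pmax(0, idx))
}

#' Sliding-window depth-index trend
#'
#' Applies [sub_params()] and [composite_index()] (plus
#' [burst_suppression_ratio()]) on the same 10 s / 1 s window grid as
#' [dsa()]. Windows containing non-finite samples are flagged
#' `quality = FALSE` and yield `NA` values.
#'
#' @param rec An [eeg_recording()].
#' @param window_s,hop_s Window grid (defaults 10 and 1 s).
#' @param amp_threshold_uv,min_suppress_s Burst-suppression detection
#'   settings (see [burst_suppression_ratio()]).
#' @param weights Composite mapping constants.
#' @param smooth_windows Optional moving-average length (in windows) applied
#'   to the index trend to emulate a monitor's display delay; default `0`
#'   (off).
#' @return A tibble `time_s`, `csi_like`, `bsr_percent`, `alpha_ratio`,
#'   `beta_ratio`, `quality` with the recording's events as an attribute.
#' @export
index_trend <- function(rec, window_s = 10, hop_s = 1,
                        amp_threshold_uv = 5, min_suppress_s = 2,
                        weights = INDEX_WEIGHTS, smooth_windows = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate_hz
  dur <- length(rec$samples) / fs
  if (window_s > dur) abort("Window is longer than the record.")
  starts <- seq(0, dur - window_s, by = hop_s)
  nwin <- round(window_s * fs)
  rows <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    i0 <- round(starts[i] * fs)
    seg <- rec$samples[(i0 + 1):(i0 + nwin)]
    if (anyNA(seg) || any(!is.finite(seg))) {
      rows[[i]] <- tibble(alpha_ratio = NA_real_, beta_ratio = NA_real_,
                          beta_over_alpha = NA_real_, bsr_percent = NA_real_,
                          window_time_s = starts[i])
      next
    }
    bsr <- burst_suppression_ratio(seg, fs, amp_threshold_uv, min_suppress_s)
    est <- welch_psd(seg, fs)
    rows[[i]] <- sub_params(tibble(freq_hz = est$freq_hz, power = est$power),
                            bsr_percent = bsr, window_time_s = starts[i])
  }
  par <- dplyr::bind_rows(rows)
  quality <- !is.na(par$alpha_ratio)
  idx <- rep(NA_real_, nrow(par))
  idx[quality] <- composite_index(par[quality, , drop = FALSE], weights)
  if (smooth_windows > 1) {
    idx <- smooth_envelope(idx, smooth_windows)
  }
  structure(tibble(time_s = par$window_time_s, csi_like = idx,
                   bsr_percent = par$bsr_percent,
                   alpha_ratio = par$alpha_ratio,
                   beta_ratio = par$beta_ratio,
                   quality = quality),
            window_s = window_s, hop_s = hop_s, events = rec$events,
            group = rec$group, subject_id = rec$subject_id)
}
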