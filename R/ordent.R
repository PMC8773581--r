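# Ordinal-pattern (Bandt-Pompe permutation) entropy.

# Vectorised pattern ids for all windows of length m at lag tau.
# Rank of sample j within its window = number of samples strictly smaller,
# plus the number of equal samples occurring earlier (temporal-order tie
# policy, the original Bandt-Pompe convention). The id is the base-m rank
# code sum(rank_j * m^(j-1)), injective over permutations.
pattern_ids <- function(x, m, tau) {
  n <- length(x)
  nwin <- n - (m - 1) * tau
  if (nwin < 1L) abort("Segment too short for the requested m and tau.")
  cols <- lapply(seq_len(m) - 1L, function(j) x[(1 + j * tau):(nwin + j * tau)])
  ids <- integer(nwin)
  for (j in seq_len(m)) {
    rj <- integer(nwin)
    for (k in seq_len(m)) {
      if (k == j) next
      if (k < j) rj <- rj + (cols[[k]] <= cols[[j]])
      else rj <- rj + (cols[[k]] < cols[[j]])
    }
    ids <- ids + rj * m^(j - 1)
  }
  ids
}

#' Ordinal pattern of one window
#'
#' Returns the permutation that sorts the window ascending; equal samples are
#' ranked by temporal order (the earlier sample ranks lower).
#'
#' @param window Numeric vector of exactly `m` finite samples.
#' @return Integer vector: position `i` gives the index (1-based, temporal)
#'   of the `i`-th smallest sample.
#' @examples
#' ordinal_pattern(c(9, 10, 6))  # the third sample is lowest
#' @export
ordinal_pattern <- function(window) {
  check_samples(window, "window")
  order(window, seq_along(window))
}

#' Permutation entropy of a segment
#'
#' Shannon entropy, in bits, of the relative frequencies of the `m!` ordinal
#' patterns over all `N - (m - 1) tau` windows. No normalization: the range
#' is `[0, log2(m!)]` (about 2.585 bits for `m = 3`).
#'
#' @param segment Numeric vector of finite samples.
#' @param m Embedding dimension (default 3).
#' @param tau Time lag in samples (default 1).
#' @return Entropy in bits.
#' @examples
#' permutation_entropy(1:100)            # strictly monotone -> 0 bits
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3))
#' @export
permutation_entropy <- function(segment, m = 3, tau = 1) {
  check_samples(segment, "segment")
  check_number(m, "m", lower = 2)
  check_number(tau, "tau", lower = 1)
  if (length(segment) < (m - 1) * tau + 2) {
    abort("`segment` must hold at least (m - 1) * tau + 2 samples.")
  }
  ids <- pattern_ids(segment, as.integer(m), as.integer(tau))
  p <- tabulate(ids + 1L)
  p <- p[p > 0] / length(ids)
  -sum(p * log2(p))
}

#' Sliding-window permutation entropy trend
#'
#' Low-pass filters the recording once (zero-phase 4th-order Butterworth at
#' `lowpass_hz`), then computes [permutation_entropy()] on the same
#' window-start grid as [dsa()].
#'
#' @param rec An [eeg_recording()].
#' @param m,tau Embedding dimension and lag (defaults 3 and 1).
#' @param lowpass_hz Pre-filter cutoff in Hz (default 30). Must not exceed
#'   the Nyquist frequency.
#' @param window_s,hop_s Window length and shift in seconds (defaults 10, 1).
#' @return A tibble `time_s`, `peen_bits` with the recording's events kept
#'   as an attribute.
#' @examples
#' rec <- eeg_recording(rnorm(3000), 100)
#' head(peen_trend(rec))
#' @export
peen_trend <- function(rec, m = 3, tau = 1, lowpass_hz = 30,
                       window_s = 10, hop_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate_hz
  if (lowpass_hz > fs / 2) {
    abort("`lowpass_hz` must not exceed the Nyquist frequency.")
  }
  dur <- duration(rec)
  if (window_s > dur) abort("Window is longer than the record.")
  x <- rec$samples
  if (lowpass_hz < fs / 2) {
    bf <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  starts <- seq(0, dur - window_s, by = hop_s)
  nwin <- round(window_s * fs)
  vals <- vapply(starts, function(s) {
    i0 <- round(s * fs)
    permutation_entropy(x[(i0 + 1):(i0 + nwin)], m = m, tau = tau)
  }, numeric(1))
  structure(tibble(time_s = starts, peen_bits = vals),
            window_s = window_s, hop_s = hop_s, events = rec$events,
            group = rec$group, subject_id = rec$subject_id)
}
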