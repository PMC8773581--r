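# Synthetic EEG synthesis.
#
# Every component is coloured noise shaped in the frequency domain: white
# Gaussian noise is filtered so that its one-sided PSD equals a target shape
# integrating to a configured band power, then multiplied by a slow amplitude
# envelope. Frequency-domain shaping gives an exact closed-form PSD for the
# stationary parts, which the spectral test-suite uses as its oracle.

# Amplitude mask: 1 inside [lo, hi], raised-cosine rolloff of `edge` Hz,
# 1e-4 (-80 dB in power) outside.
band_mask <- function(f, lo, hi, edge = 1) {
  m <- rep(1e-4, length(f))
  inside <- f >= lo & f <= hi
  m[inside] <- 1
  left <- f < lo & f >= lo - edge
  m[left] <- pmax(1e-4, 0.5 * (1 + cos(pi * (lo - f[left]) / edge)))
  right <- f > hi & f <= hi + edge
  m[right] <- pmax(1e-4, 0.5 * (1 + cos(pi * (f[right] - hi) / edge)))
  m[f <= 0] <- 0
  m
}

# Unnormalized spectral shapes.
raw_shape <- function(f, kind, config) {
  lo <- config$band_limit_hz[1]
  hi <- config$band_limit_hz[2]
  switch(kind,
    background = pmax(f, 0.5)^(-config$background_exponent) *
      band_mask(f, lo, hi)^2,
    alpha = exp(-(f - 10)^2 / (2 * 0.8^2)) * band_mask(f, lo, hi)^2,
    fast = pmax(f, 0.5)^(-1) * band_mask(f, max(13, lo), hi)^2
  )
}

# Target one-sided PSD shapes; each integrates to 1 over [0, fs/2]
# (normalization computed once on an internal fine grid, independent of the
# grid the caller evaluates on).
component_shape <- function(f, kind, config) {
  grid <- seq(0, config$band_limit_hz[2] + 5, by = 0.01)
  tot <- trapz_int(grid, raw_shape(grid, kind, config))
  raw_shape(f, kind, config) / tot
}

# Closed-form one-sided PSD (uV^2/Hz) of the stationary generative mixture at
# unit envelopes; the spectral-fidelity tests integrate this analytically.
analytic_psd <- function(freqs, config, alpha_scale = 1, fast_scale = 1,
                         bg_scale = 1) {
  config$background_power_uv2 * bg_scale^2 *
    component_shape(freqs, "background", config) +
    config$alpha_power_uv2 * alpha_scale^2 *
      component_shape(freqs, "alpha", config) +
    config$beta_power_uv2 * fast_scale^2 *
      component_shape(freqs, "fast", config)
}

# Cache of spectral filter gains, keyed by component kind, grid size and the
# config fields that shape the spectrum; avoids recomputing identical masks
# for every subject of a cohort.
.shape_cache <- new.env(parent = emptyenv())

shape_filter <- function(n, fs, kind, config) {
  key <- paste(kind, n, fs, config$band_limit_hz[1], config$band_limit_hz[2],
               config$background_exponent, sep = "|")
  hit <- .shape_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- 0:(n - 1)
  f_abs <- pmin(k, n - k) * fs / n
  h <- sqrt(component_shape(f_abs, kind, config) * fs / 2)
  if (length(.shape_cache) > 64) rm(list = ls(.shape_cache),
                                    envir = .shape_cache)
  .shape_cache[[key]] <- h
  h
}

# Coloured-noise draw with one-sided PSD `power_uv2 * shape_kind(f)`.
shaped_noise <- function(n, fs, kind, power_uv2, config) {
  if (power_uv2 <= 0) return(numeric(n))
  z <- rnorm(n)
  h <- shape_filter(n, fs, kind, config) * sqrt(power_uv2)
  # white noise has one-sided PSD 2/fs; |H|^2 * 2/fs equals the target PSD
  Re(fft(fft(z) * h, inverse = TRUE)) / n
}

# 1-s moving-average smoothing used on amplitude envelopes so that piecewise
# definitions do not introduce spectral edges.
smooth_envelope <- function(env, fs) {
  w <- max(1L, round(fs))
  if (w <= 1L) return(env)
  kern <- rep(1 / w, w)
  pad <- c(rep(env[1], w), env, rep(env[length(env)], w))
  out <- stats::filter(pad, kern, sides = 2)
  as.numeric(out[(w + 1):(w + length(env))])
}

logistic_ramp <- function(t, t_mid, rise_s = 60) {
  k <- log(81) / rise_s                 # 10% -> 90% in `rise_s`
  1 / (1 + exp(-k * (t - t_mid)))
}

draw_subject_factors <- function(config) {
  # fixed draw order keeps streams comparable across configurations
  list(bg = exp(rnorm(1, 0, config$subject_sd)),
       alpha = exp(rnorm(1, 0, config$subject_sd)),
       fast = exp(rnorm(1, 0, config$subject_sd)))
}

#' Simulate one emergence recording
#'
#' Generates a single-channel emergence EEG: `1/f` background plus a waning
#' alpha oscillation plus a beta/fast activation component whose amplitude
#' ramps up logistically (60 s rise) starting at a subject-specific lead time
#' before ROR. The lead is Gamma-distributed (shape 4) with group mean
#' `config$beta_onset_mean_s[group]`. With probability `config$bsr_prob` the
#' early emergence contains burst-suppression epochs (amplitude envelope
#' reduced to 5% for 2-10 s stretches). The recording carries events
#' `emergence_start` (0 s) and `ROR` (`emergence_duration_s`), and extends
#' `post_ror_s` past ROR with awake-like signal.
#'
#' @param config A [cohort_config()].
#' @param group One of `config$group_labels`.
#' @param subject_id Identifier used in outputs and seed derivation.
#' @param seed Integer substream seed; defaults to a hash of
#'   `(config$seed, group, subject_id)` so cohorts are reproducible and
#'   subjects independent of cohort size.
#' @return An [eeg_recording()] whose `truth` records the drawn onset lead,
#'   amplitude factors and suppression epochs.
#' @examples
#' cfg <- cohort_config(emergence_duration_s = 60, post_ror_s = 10,
#'                      beta_onset_mean_s = c(propofol = 20,
#'                                            sevoflurane = 40,
#'                                            isoflurane = 40))
#' rec <- simulate_subject(cfg, "propofol", "p01")
#' rec$truth$onset_lead_s
#' @export
simulate_subject <- function(config, group, subject_id = "subject",
                             seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!group %in% config$group_labels) {
    abort(sprintf("Unknown group label '%s'; expected one of: %s.",
                  group, paste(config$group_labels, collapse = ", ")))
  }
  seed <- seed %||% derive_seed(config$seed, "emergence", group, subject_id)
  fs <- config$sample_rate_hz
  t_em <- config$emergence_duration_s
  dur <- t_em + config$post_ror_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs

  with_seed(seed, {
    fac <- draw_subject_factors(config)
    mean_lead <- config$beta_onset_mean_s[[group]]
    lead <- if (mean_lead > 0) rgamma(1, shape = 4, scale = mean_lead / 4)
            else 0
    lead <- min(lead, t_em)

    bg <- shaped_noise(n, fs, "background",
                       config$background_power_uv2 * fac$bg^2, config)
    alpha <- shaped_noise(n, fs, "alpha",
                          config$alpha_power_uv2 * fac$alpha^2, config)
    fast <- shaped_noise(n, fs, "fast",
                         config$beta_power_uv2 * fac$fast^2, config)

    # alpha wanes linearly across emergence, then drops towards an awake floor
    env_a <- ifelse(t <= t_em,
                    1 + (config$alpha_wane - 1) * t / t_em,
                    0.2)
    env_a <- smooth_envelope(env_a, fs)
    # fast activation: logistic ramp whose 10% point sits `lead` s before ROR
    env_f <- logistic_ramp(t, t_mid = t_em - lead + 30)

    x <- bg + alpha * env_a + fast * env_f

    suppression <- list()
    if (runif(1) < config$bsr_prob) {
      n_ep <- 1L + rpois(1, 2)
      sup_env <- rep(1, n)
      for (i in seq_len(n_ep)) {
        len <- runif(1, 2, 10)
        start <- runif(1, 0, max(t_em / 3 - len, 1))
        idx <- t >= start & t < start + len
        sup_env[idx] <- 0.05
        suppression[[i]] <- c(start_s = start, length_s = len)
      }
      x <- x * smooth_envelope(sup_env, fs / 2)
    }

    eeg_recording(x, fs,
                  events = c(emergence_start = 0, ROR = t_em),
                  group = group, subject_id = subject_id,
                  truth = list(onset_lead_s = lead,
                               amplitude_factors = fac,
                               suppression = suppression,
                               seed = seed))
  })
}

#' Simulate one induction recording
#'
#' Awake-like broadband EEG (fast activity on, alpha weak) transitioning over
#' about 60 s around the LOR marker into an alpha-dominant, beta-poor
#' anaesthesia signal. LOR is placed at the record midpoint.
#'
#' @inheritParams simulate_subject
#' @param group Optional group label kept as metadata (induction is
#'   propofol-like for every subject).
#' @return An [eeg_recording()] with an `LOR` event at the midpoint.
#' @export
simulate_induction <- function(config, subject_id = "subject",
                               group = NA_character_, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  dur <- config$induction_duration_s
  if (dur <= 60) {
    abort("`induction_duration_s` must exceed 60 s to span the transition.")
  }
  seed <- seed %||% derive_seed(config$seed, "induction",
                                if (is.na(group)) "" else group, subject_id)
  fs <- config$sample_rate_hz
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  t_lor <- dur / 2

  with_seed(seed, {
    fac <- draw_subject_factors(config)
    bg <- shaped_noise(n, fs, "background",
                       config$background_power_uv2 * fac$bg^2, config)
    alpha <- shaped_noise(n, fs, "alpha",
                          config$alpha_power_uv2 * fac$alpha^2, config)
    fast <- shaped_noise(n, fs, "fast",
                         config$beta_power_uv2 * fac$fast^2, config)
    up <- logistic_ramp(t, t_lor)       # 0 -> 1 across LOR
    env_a <- 0.1 + 0.9 * up             # alpha-ization after LOR
    env_f <- 1 - 0.8 * up               # fast activity fades to 20%
    x <- bg + alpha * env_a + fast * env_f
    eeg_recording(x, fs, events = c(LOR = t_lor), group = group,
                  subject_id = subject_id,
                  truth = list(amplitude_factors = fac, seed = seed))
  })
}

#' Simulate a full synthetic cohort
#'
#' One emergence recording (and optionally one induction recording) per
#' subject, `n_per_group` subjects for each group label, all derived
#' deterministically from the master seed.
#'
#' @param config A [cohort_config()].
#' @param include_induction Also simulate an induction recording per subject
#'   (default `TRUE`).
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   list-columns `emergence` (and `induction`), and the true beta-onset lead
#'   `onset_lead_s` drawn for the subject.
#' @examples
#' cfg <- cohort_config(n_per_group = 2, emergence_duration_s = 60,
#'                      post_ror_s = 10, induction_duration_s = 70,
#'                      beta_onset_mean_s = c(propofol = 10,
#'                                            sevoflurane = 30,
#'                                            isoflurane = 30))
#' cohort <- simulate_cohort(cfg)
#' nrow(cohort)
#' @export
simulate_cohort <- function(config, include_induction = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- tidyr::expand_grid(group = config$group_labels,
                             idx = seq_len(config$n_per_group))
  rows <- purrr::pmap(grid, function(group, idx) {
    sid <- sprintf("%s_%02d", substr(group, 1, 4), idx)
    em <- simulate_subject(config, group, sid)
    ind <- if (include_induction) simulate_induction(config, sid, group)
           else NULL
    tibble(subject_id = sid, group = group,
           emergence = list(em),
           induction = list(ind),
           onset_lead_s = em$truth$onset_lead_s,
           suppressed = length(em$truth$suppression) > 0)
  })
  out <- dplyr::bind_rows(rows)
  if (!include_induction) out$induction <- NULL
  out
}

#' Write a cohort to a directory of CSV files
#'
#' Writes each recording via [write_recording()] plus a `manifest.csv` with
#' subject id, group, event times and the generator's truth parameters.
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort$emergence[[i]]
    write_recording(rec, file.path(dir, paste0(rec$subject_id,
                                               "_emergence.csv")))
    if ("induction" %in% names(cohort) && !is.null(cohort$induction[[i]])) {
      write_recording(cohort$induction[[i]],
                      file.path(dir, paste0(rec$subject_id,
                                            "_induction.csv")))
    }
  }
  manifest <- cohort |>
    dplyr::mutate(
      ror_s = purrr::map_dbl(.data$emergence, ~ .x$events[["ROR"]]),
      emergence_start_s = purrr::map_dbl(.data$emergence,
                                         ~ .x$events[["emergence_start"]])) |>
    dplyr::select(!dplyr::any_of(c("emergence", "induction")))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(dir)
}
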