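#' Configuration for a synthetic emergence/induction EEG cohort
#'
#' Bundles every parameter of the synthetic cohort generator: group sizes and
#' labels, the recorder's sampling and band-limiting constraints, the spectral
#' shape of the generative mixture, and the group-specific timing of beta-band
#' activation during emergence.
#'
#' The generative model is a sum of three independent band-shaped noise
#' components: a `1/f^exponent` broadband background, a narrowband alpha
#' oscillation centred near 10 Hz (bandwidth about 2 Hz) whose amplitude wanes
#' slowly towards the return of responsiveness (ROR), and a "fast" activation
#' component spanning the beta band and the upper recorder band (13 Hz up to
#' the band limit) whose amplitude ramps up logistically starting at a
#' subject-specific lead time before ROR. The lead time is Gamma-distributed
#' per subject (shape 4) around the group mean `beta_onset_mean_s`, producing
#' the right-skewed distribution of wake-like index durations seen across
#' anaesthetic groups.
#'
#' @param n_per_group Subjects per anaesthetic group (default 15).
#' @param group_labels Character vector of group identifiers.
#' @param sample_rate_hz Sampling rate in samples/second (default 100, the
#'   rate delivered by the forehead monitor).
#' @param band_limit_hz Length-2 numeric `(low, high)` pass-band in Hz
#'   (default `c(6, 42)`, the monitor's effective band).
#' @param emergence_duration_s Seconds of pre-ROR signal (default 600: the
#'   10 min emergence window analysed).
#' @param post_ror_s Seconds of awake-like signal appended after ROR so that
#'   post-event windows exist (default 60).
#' @param induction_duration_s Seconds of induction recording around LOR
#'   (default 300; LOR is placed at the midpoint).
#' @param beta_onset_mean_s Named numeric, one entry per group label: mean
#'   lead time (s) of beta/fast activation before ROR. Defaults place the
#'   propofol-like group at 60 s and both volatile-like groups at 300 s.
#' @param alpha_power_uv2,beta_power_uv2,background_power_uv2 Band-integrated
#'   power (microvolt squared) of the alpha, fast-activation and background
#'   components at full amplitude.
#' @param background_exponent Spectral exponent of the `1/f^exponent`
#'   background (default 1).
#' @param alpha_wane Fraction of the alpha amplitude remaining at ROR
#'   (linear decline across emergence; default 0.4).
#' @param subject_sd Between-subject multiplicative (log-normal) amplitude
#'   variability (default 0.2).
#' @param bsr_prob Probability that a subject shows early burst-suppression
#'   epochs (default 0.1).
#' @param seed Master integer seed; every subject draws from a substream
#'   derived deterministically from it.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(n_per_group = 2, emergence_duration_s = 60,
#'                      beta_onset_mean_s = c(propofol = 20,
#'                                            sevoflurane = 40,
#'                                            isoflurane = 40))
#' cfg$group_labels
#' @export
cohort_config <- function(n_per_group = 15,
                          group_labels = c("propofol", "sevoflurane",
                                           "isoflurane"),
                          sample_rate_hz = 100,
                          band_limit_hz = c(6, 42),
                          emergence_duration_s = 600,
                          post_ror_s = 60,
                          induction_duration_s = 300,
                          beta_onset_mean_s = c(propofol = 60,
                                                sevoflurane = 300,
                                                isoflurane = 300),
                          alpha_power_uv2 = 100,
                          beta_power_uv2 = 40,
                          background_power_uv2 = 50,
                          background_exponent = 1,
                          alpha_wane = 0.4,
                          subject_sd = 0.2,
                          bsr_prob = 0.1,
                          seed = 1L) {
  check_number(n_per_group, "n_per_group", lower = 1)
  if (!is.character(group_labels) || length(group_labels) < 1L ||
      anyDuplicated(group_labels)) {
    abort("`group_labels` must be distinct non-empty character labels.")
  }
  check_number(sample_rate_hz, "sample_rate_hz", lower = 1)
  if (length(band_limit_hz) != 2L || band_limit_hz[1] <= 0 ||
      band_limit_hz[2] <= band_limit_hz[1]) {
    abort("`band_limit_hz` must be an increasing positive pair (low, high).")
  }
  if (sample_rate_hz < 2 * band_limit_hz[2] + 2) {
    abort(sprintf(
      "`sample_rate_hz` (%g) must be at least 2 * band high edge + 2 = %g.",
      sample_rate_hz, 2 * band_limit_hz[2] + 2))
  }
  check_number(emergence_duration_s, "emergence_duration_s", lower = 1)
  check_number(post_ror_s, "post_ror_s", lower = 0)
  check_number(induction_duration_s, "induction_duration_s", lower = 0)
  if (is.null(names(beta_onset_mean_s))) {
    if (length(beta_onset_mean_s) == 1L) {
      beta_onset_mean_s <- setNames(rep(beta_onset_mean_s,
                                        length(group_labels)), group_labels)
    } else {
      abort("`beta_onset_mean_s` must be named by group label.")
    }
  }
  missing_groups <- setdiff(group_labels, names(beta_onset_mean_s))
  if (length(missing_groups)) {
    abort(paste0("`beta_onset_mean_s` missing entries for: ",
                 paste(missing_groups, collapse = ", ")))
  }
  if (any(beta_onset_mean_s < 0) ||
      any(beta_onset_mean_s[group_labels] >= emergence_duration_s)) {
    abort("`beta_onset_mean_s` must be >= 0 and < emergence_duration_s.")
  }
  for (nm in c("alpha_power_uv2", "beta_power_uv2", "background_power_uv2")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(background_exponent, "background_exponent", lower = 0)
  check_number(alpha_wane, "alpha_wane", lower = 0, upper = 1)
  check_number(subject_sd, "subject_sd", lower = 0)
  check_number(bsr_prob, "bsr_prob", lower = 0, upper = 1)
  check_number(seed, "seed", lower = 0, upper = 2^31 - 1)

  structure(list(
    n_per_group = as.integer(n_per_group),
    group_labels = group_labels,
    sample_rate_hz = sample_rate_hz,
    band_limit_hz = as.numeric(band_limit_hz),
    emergence_duration_s = emergence_duration_s,
    post_ror_s = post_ror_s,
    induction_duration_s = induction_duration_s,
    beta_onset_mean_s = beta_onset_mean_s[group_labels],
    alpha_power_uv2 = alpha_power_uv2,
    beta_power_uv2 = beta_power_uv2,
    background_power_uv2 = background_power_uv2,
    background_exponent = background_exponent,
    alpha_wane = alpha_wane,
    subject_sd = subject_sd,
    bsr_prob = bsr_prob,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  groups: %s (n = %d each)\n",
              paste(x$group_labels, collapse = ", "), x$n_per_group))
  cat(sprintf("  fs = %g Hz, band %g-%g Hz\n", x$sample_rate_hz,
              x$band_limit_hz[1], x$band_limit_hz[2]))
  cat(sprintf("  emergence %g s (+%g s post-ROR), induction %g s\n",
              x$emergence_duration_s, x$post_ror_s, x$induction_duration_s))
  cat(sprintf("  beta onset lead means: %s\n",
              paste(sprintf("%s=%g s", names(x$beta_onset_mean_s),
                            x$beta_onset_mean_s), collapse = ", ")))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
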