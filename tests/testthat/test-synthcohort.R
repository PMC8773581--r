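# Synthetic cohort generator: determinism, spectral fidelity, and recovery
# of the generating parameters from the simulated signal.

test_that("simulation is a pure function of config, group and subject", {
  cfg <- tiny_config()
  a <- simulate_subject(cfg, "propofol", "s1")
  b <- simulate_subject(cfg, "propofol", "s1")
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$onset_lead_s, b$truth$onset_lead_s)

  other <- simulate_subject(cfg, "propofol", "s2")
  expect_false(identical(a$samples, other$samples))

  cfg2 <- tiny_config(seed = cfg$seed + 1L)
  shifted <- simulate_subject(cfg2, "propofol", "s1")
  expect_false(identical(a$samples, shifted$samples))
})

test_that("cohort has n_per_group recordings per group and is reproducible", {
  cfg <- tiny_config(n_per_group = 15)
  cohort <- simulate_cohort(cfg, include_induction = FALSE)
  expect_equal(nrow(cohort), 45)
  expect_equal(as.integer(table(cohort$group)), rep(15L, 3))

  again <- simulate_cohort(cfg, include_induction = FALSE)
  expect_identical(purrr::map(cohort$emergence, "samples"),
                   purrr::map(again$emergence, "samples"))

  bumped <- simulate_cohort(tiny_config(n_per_group = 15,
                                        seed = cfg$seed + 1L),
                            include_induction = FALSE)
  same <- purrr::map2_lgl(cohort$emergence, bumped$emergence,
                          ~ identical(.x$samples, .y$samples))
  expect_false(any(same))
})

test_that("unknown group label raises an error naming the label", {
  expect_error(simulate_subject(tiny_config(), "xenon"), "xenon")
})

test_that("zero beta power leaves no ramping beta component", {
  cfg0 <- tiny_config(beta_power_uv2 = 0, bsr_prob = 0, subject_sd = 0,
                      emergence_duration_s = 120, post_ror_s = 20,
                      n_per_group = 1,
                      beta_onset_mean_s = c(propofol = 15, sevoflurane = 40,
                                            isoflurane = 40))
  # beta-band power in a late (post-ROR, fully activated) window
  late_bp <- function(config, sid) {
    rec <- simulate_subject(config, "sevoflurane", sid)
    p <- psd(rec$samples[(125 * 100 + 1):(135 * 100)], 100)
    band_power_of_psd(p$freq_hz, p$power_uv2_hz, c(13, 30))
  }
  null_vals <- vapply(sprintf("n%02d", 1:10), function(s) late_bp(cfg0, s),
                      numeric(1))
  probe <- late_bp(cfg0, "probe")
  expect_lt(abs(probe - mean(null_vals)), 2 * stats::sd(null_vals) + 1e-9)

  # with beta power on, the same window clearly exceeds the null spread
  cfg1 <- tiny_config(bsr_prob = 0, subject_sd = 0,
                      emergence_duration_s = 120, post_ror_s = 20,
                      n_per_group = 1,
                      beta_onset_mean_s = c(propofol = 15, sevoflurane = 40,
                                            isoflurane = 40))
  probe_on <- late_bp(cfg1, "probe")
  expect_gt(probe_on, mean(null_vals) + 5 * stats::sd(null_vals))
})

test_that("beta onset leads are recoverable and preserve group ordering", {
  cfg <- cohort_config(n_per_group = 15, emergence_duration_s = 600,
                       post_ror_s = 60, subject_sd = 0.1, bsr_prob = 0,
                       beta_onset_mean_s = c(propofol = 30,
                                             sevoflurane = 150,
                                             isoflurane = 300),
                       seed = 11L)
  # estimator: the 13-30 Hz band-power trend crosses a quarter of its rise
  # (envelope 0.5, i.e. the logistic midpoint) 30 s after the ramp onset, so
  # lead = ROR + 30 - t_mid (oracle: the noiseless logistic envelope).
  estimate_lead <- function(rec) {
    sp <- dsa(rec, window_s = 10, hop_s = 2)
    bp <- band_power(sp, c(13, 30))
    v <- bp$power_uv2
    lo <- stats::median(head(v, 10))
    hi <- stats::median(tail(v, 10))
    thr <- lo + (hi - lo) / 4
    # sustained crossing: five consecutive windows above threshold, so a
    # single noisy window cannot fake the change-point
    sustained <- vapply(seq_len(length(v) - 4),
                        function(k) all(v[k:(k + 4)] >= thr), logical(1))
    i <- which(sustained)[1]
    t_mid <- bp$time_s[i] + 5
    if (i > 1) { # linear interpolation between neighbouring windows
      frac <- (v[i] - thr) / (v[i] - v[i - 1])
      if (is.finite(frac) && frac > 0 && frac < 1) t_mid <- t_mid - 2 * frac
    }
    rec$events[["ROR"]] + 30 - t_mid
  }
  res <- purrr::map(c("propofol", "isoflurane"), function(g) {
    recs <- purrr::map(seq_len(15),
                       ~ simulate_subject(cfg, g, sprintf("%s%02d", g, .x)))
    list(est = purrr::map_dbl(recs, estimate_lead),
         tru = purrr::map_dbl(recs, ~ .x$truth$onset_lead_s))
  })
  prop <- res[[1]]
  iso <- res[[2]]
  # 10-fold configured separation recovered in the medians
  expect_gt(stats::median(iso$est), 5 * stats::median(prop$est))
  # estimated means within 20% of the configured group means
  expect_lt(abs(mean(iso$est) - 300) / 300, 0.2)
  expect_lt(abs(mean(prop$est) - 30) / 30, 0.2)
  # and close to the drawn (true) leads subject by subject
  expect_lt(stats::median(abs(iso$est - iso$tru)), 20)
})

test_that("long stationary segment matches the analytic PSD within 10%", {
  cfg <- cohort_config(n_per_group = 1, emergence_duration_s = 400,
                       post_ror_s = 0, alpha_wane = 1, beta_power_uv2 = 0,
                       subject_sd = 0, bsr_prob = 0,
                       beta_onset_mean_s = c(propofol = 30,
                                             sevoflurane = 30,
                                             isoflurane = 30),
                       seed = 3L)
  rec <- simulate_subject(cfg, "propofol", "s1")
  p <- psd(rec$samples[1:(300 * 100)], 100)
  ana <- emergeEEG:::analytic_psd(p$freq_hz, cfg)
  for (band in list(c(6, 9), c(9, 11), c(11, 14), c(14, 30), c(30, 42))) {
    got <- band_power_of_psd(p$freq_hz, p$power_uv2_hz, band)
    want <- band_power_of_psd(p$freq_hz, ana, band)
    expect_lt(abs(got - want) / want, 0.10)
  }
})

test_that("power outside the band limit sits at least 20 dB below in band", {
  rec <- simulate_subject(tiny_config(emergence_duration_s = 200,
                                      post_ror_s = 0, n_per_group = 1),
                          "propofol", "s1")
  p <- psd(rec$samples, 100)
  inband <- mean(p$power_uv2_hz[p$freq_hz >= 8 & p$freq_hz <= 30])
  outband <- mean(p$power_uv2_hz[p$freq_hz >= 46])
  expect_gt(10 * log10(inband / outband), 20)
})

test_that("induction develops alpha and loses fast activity across LOR", {
  cfg <- cohort_config(n_per_group = 15, induction_duration_s = 200,
                       seed = 5L)
  t_lor <- 100
  gains <- vapply(seq_len(15), function(i) {
    rec <- simulate_induction(cfg, sprintf("s%02d", i))
    fs <- rec$sample_rate_hz
    win <- function(t0) rec$samples[(t0 * fs + 1):((t0 + 10) * fs)]
    pre <- psd(win(t_lor - 15), fs)
    post <- psd(win(t_lor + 30), fs)
    band_power_of_psd(post$freq_hz, post$power_uv2_hz, c(8, 12)) -
      band_power_of_psd(pre$freq_hz, pre$power_uv2_hz, c(8, 12))
  }, numeric(1))
  expect_gte(sum(gains > 0), 13)
})

test_that("with zero alpha and flat background only the beta band changes", {
  cfg <- cohort_config(n_per_group = 1, induction_duration_s = 200,
                       alpha_power_uv2 = 0, background_exponent = 0,
                       background_power_uv2 = 5,
                       subject_sd = 0, seed = 9L)
  rec <- simulate_induction(cfg, "s1")
  fs <- rec$sample_rate_hz
  pre <- psd(rec$samples[(60 * fs + 1):(80 * fs)], fs)
  post <- psd(rec$samples[(120 * fs + 1):(140 * fs)], fs)
  lowband_ratio <- band_power_of_psd(post$freq_hz, post$power_uv2_hz,
                                     c(6, 11)) /
    band_power_of_psd(pre$freq_hz, pre$power_uv2_hz, c(6, 11))
  beta_ratio <- band_power_of_psd(post$freq_hz, post$power_uv2_hz,
                                  c(14, 40)) /
    band_power_of_psd(pre$freq_hz, pre$power_uv2_hz, c(14, 40))
  expect_lt(abs(lowband_ratio - 1), 0.35)   # background band unchanged
  expect_lt(beta_ratio, 0.3)                # fast activity collapses
})

test_that("degenerate induction duration raises an error", {
  expect_error(cohort_config(induction_duration_s = -1))
  cfg <- tiny_config()
  cfg$induction_duration_s <- 0
  expect_error(simulate_induction(cfg, "s1"), "60 s")
})

test_that("burst suppression epochs appear with the configured probability", {
  cfg <- tiny_config(bsr_prob = 1, n_per_group = 1,
                     emergence_duration_s = 90)
  rec <- simulate_subject(cfg, "propofol", "s1")
  expect_gt(length(rec$truth$suppression), 0)
  bsr <- burst_suppression_ratio(
    rec$samples[1:(30 * rec$sample_rate_hz)], rec$sample_rate_hz)
  cfg0 <- tiny_config(bsr_prob = 0, n_per_group = 1,
                      emergence_duration_s = 90)
  rec0 <- simulate_subject(cfg0, "propofol", "s1")
  expect_equal(length(rec0$truth$suppression), 0)
})
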