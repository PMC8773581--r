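# Shared fixtures and independent oracles used across the test files.

# Small, fast cohort configuration (short records, low n).
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_per_group = 2, emergence_duration_s = 60, post_ror_s = 10,
                   induction_duration_s = 100,
                   beta_onset_mean_s = c(propofol = 15, sevoflurane = 40,
                                         isoflurane = 40),
                   seed = 7L)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

make_tone <- function(freq_hz, amp = 1, dur_s = 10, fs = 100, phase = 0) {
  amp * sin(2 * pi * freq_hz * seq(0, dur_s - 1 / fs, by = 1 / fs) + phase)
}

# Brute-force permutation entropy: explicit pattern dictionary built from
# order() with temporal tie-breaking; independent of the package's
# vectorised rank coding.
peen_oracle <- function(x, m = 3, tau = 1) {
  nwin <- length(x) - (m - 1) * tau
  pats <- vapply(seq_len(nwin), function(i) {
    w <- x[seq(i, by = tau, length.out = m)]
    paste(order(w, seq_along(w)), collapse = "-")
  }, character(1))
  p <- table(pats) / nwin
  -sum(p * log2(p))
}

# Brute-force Mann-Whitney AUC by explicit double loop.
auc_oracle <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) {
    s <- s + if (yj > xi) 1 else if (yj == xi) 0.5 else 0
  }
  s / (length(x) * length(y))
}

# Exact two-sided signed-rank p-value for tie-free differences via the
# closed-form null distribution (dsignrank); independent of the package's
# sign-assignment enumeration.
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  pv <- sum(stats::dsignrank(0:(n * (n + 1) / 2), n) *
              (0:(n * (n + 1) / 2) <= v))
  pu <- sum(stats::dsignrank(0:(n * (n + 1) / 2), n) *
              (0:(n * (n + 1) / 2) >= v))
  min(1, 2 * min(pv, pu))
}

# Band power integration helper used as an independent check.
band_power_of_psd <- function(freq, power, band) {
  sel <- freq >= band[1] & freq <= band[2]
  f <- freq[sel]
  p <- power[sel]
  sum((p[-1] + p[-length(p)]) * diff(f)) / 2
}
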