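# Between-group machinery: PSD comparison with the neighbouring-bin rule,
# AUC maps with cluster reporting, wake-duration statistic, Kruskal-Wallis
# with Dunn's post-hoc, and the Freeman-Halton exact test.

fake_dsa <- function(times, freqs = seq(6, 30, by = 0.5), window_s = 10,
                     hop_s = 1, events = numeric(), value = 1,
                     subject_id = "s1", group = "a") {
  tb <- tibble::tibble(time_s = rep(times, each = length(freqs)),
                       freq_hz = rep(freqs, times = length(times)),
                       power = value)
  structure(tb, class = c("eeg_dsa", class(tb)), window_s = window_s,
            hop_s = hop_s, normalized = FALSE, events = events,
            subject_id = subject_id, group = group)
}

# Subject-level PSD tables drawn around a base spectrum with log-normal
# subject variability; `shift` multiplies power in `shift_band`.
fake_psd_group <- function(n, freqs = seq(6, 30, by = 0.5), sd_log = 0.3,
                           shift = 1, shift_band = c(8, 12)) {
  purrr::map_dfr(seq_len(n), function(i) {
    base <- 100 / freqs
    subj <- exp(rnorm(1, 0, sd_log))
    noise <- exp(rnorm(length(freqs), 0, sd_log / 2))
    p <- base * subj * noise
    p[freqs >= shift_band[1] & freqs <= shift_band[2]] <-
      p[freqs >= shift_band[1] & freqs <= shift_band[2]] * shift
    tibble::tibble(subject_id = sprintf("x%02d", i), freq_hz = freqs,
                   power = p)
  })
}

test_that("alignment keeps exactly the fully pre-event windows", {
  spec <- fake_dsa(times = 0:640, events = c(ROR = 620))
  al <- align_to_event(spec, span_s = 600)
  rel <- sort(unique(al$rel_time_s))
  expect_length(rel, 591)
  expect_equal(rel[1], -600)
  expect_equal(rel[length(rel)], -10)

  # already aligned grid with event at 0 is the identity
  spec0 <- fake_dsa(times = seq(-600, -10), events = c(ROR = 0))
  al0 <- align_to_event(spec0, 0, span_s = 600)
  expect_equal(sort(unique(al0$rel_time_s)), seq(-600, -10))

  short <- fake_dsa(times = 0:30, events = c(ROR = 35))
  expect_error(align_to_event(short, span_s = 600), "does not cover")
})

test_that("identical groups give AUC exactly 0.5 everywhere", {
  withr::with_seed(26, {
    g <- fake_psd_group(6)
  })
  spec_a <- dplyr::mutate(g, rel_time_s = -20)
  res <- auc_map(spec_a, spec_a, n_boot = 50, seed = 1, cluster_min = 4)
  expect_true(all(res$auc == 0.5))
  expect_true(all(res$cluster <= res$sig))  # cluster mask within sig mask
})

test_that("AUC maps are antisymmetric under label swap", {
  withr::with_seed(27, {
    a <- dplyr::mutate(fake_psd_group(8), rel_time_s = -20)
    b <- dplyr::mutate(fake_psd_group(8, shift = 2), rel_time_s = -20)
  })
  m_ab <- auc_map(a, b, n_boot = 20, seed = 1)
  m_ba <- auc_map(b, a, n_boot = 20, seed = 1)
  expect_equal(m_ab$auc, 1 - m_ba$auc, tolerance = 1e-12)
})

test_that("an isolated significant bin is never retained by psd_compare", {
  withr::with_seed(28, {
    a <- fake_psd_group(15, sd_log = 0.2)
    # strong shift confined to a single 0.5 Hz bin
    b <- fake_psd_group(15, sd_log = 0.2, shift = 6,
                        shift_band = c(20, 20))
  })
  res <- psd_compare(a, b, n_boot = 400, seed = 2)
  sig_at <- res$freq_hz[res$sig]
  expect_true(20 %in% sig_at)
  expect_false(res$retained[res$freq_hz == 20])
})

test_that("a band-wide alpha shift is retained over most of the band", {
  withr::with_seed(29, {
    a <- fake_psd_group(15, sd_log = 0.3)
    b <- fake_psd_group(15, sd_log = 0.3, shift = 2.5)  # ~3 sd in log power
  })
  res <- psd_compare(a, b, n_boot = 400, seed = 3)
  alpha_bins <- res$freq_hz >= 8 & res$freq_hz <= 12
  expect_gte(mean(res$retained[alpha_bins]), 0.5)
  expect_error(psd_compare(a, dplyr::mutate(b, freq_hz = freq_hz + 0.25)),
               "frequency grids")
})

test_that("duration above threshold follows the run-to-ROR convention", {
  mk <- function(vals, times = seq(0, 590), ror = 600) {
    structure(tibble::tibble(time_s = times, csi_like = vals),
              window_s = 10, hop_s = 1, events = c(ROR = ror),
              subject_id = "s", group = "g")
  }
  # saturated: at threshold throughout a 600 s window
  expect_equal(duration_above(mk(rep(90, 591)))$duration_s, 600)
  # below threshold at ROR: 0 s with the flag set
  low_end <- c(rep(90, 580), rep(10, 11))
  r <- duration_above(mk(low_end))
  expect_equal(r$duration_s, 0)
  expect_true(r$at_ror_below)
  # wake-like island not touching ROR still counts 0 under the run reading
  island <- rep(10, 591)
  island[480:540] <- 95
  r2 <- duration_above(mk(island))
  expect_equal(r2$duration_s, 0)
  # but is counted by the total-time alternative
  r3 <- duration_above(mk(island), contiguous = FALSE)
  expect_equal(r3$duration_s, 61)
  # run ending at ROR measures back to the run start
  tailrun <- rep(10, 591)
  tailrun[472:591] <- 95  # times 471..590
  expect_equal(duration_above(mk(tailrun))$duration_s, 600 - 471)
  expect_error(duration_above(mk(rep(90, 10), times = seq(0, 90, by = 10),
                                 ror = 300)), "reach")
})

test_that("raising the threshold never lengthens a duration", {
  withr::with_seed(30, {
    vals <- 50 + cumsum(rnorm(591)) * 2
  })
  tr <- structure(tibble::tibble(time_s = seq(0, 590), csi_like = vals),
                  window_s = 10, hop_s = 1, events = c(ROR = 600))
  durs <- vapply(c(20, 40, 60, 80),
                 function(th) duration_above(tr, threshold = th)$duration_s,
                 numeric(1))
  expect_true(all(diff(durs) <= 0))
})

test_that("kruskal-dunn separates what should be separated", {
  same <- data.frame(v = rep(c(1, 2, 3, 4, 5), 3),
                     g = rep(c("a", "b", "c"), each = 5))
  r0 <- kruskal_dunn(same, "v", "g")
  expect_lt(r0$kw_chi2, 0.01)
  expect_gt(r0$kw_p, 0.99)

  sep <- data.frame(v = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                    g = rep(c("a", "b", "c"), each = 3))
  r1 <- kruskal_dunn(sep, "v", "g")
  expect_lt(r1$kw_p, 0.05)
  extreme <- r1$pairwise$p_adj[r1$pairwise$group1 == "a" &
                                 r1$pairwise$group2 == "c"]
  expect_equal(min(r1$pairwise$p_adj), extreme)

  expect_error(kruskal_dunn(data.frame(v = c(1, 2, 3), g = c("a", "a", "b")),
                            "v", "g"), "at least 2")
})

test_that("dunn p-values are calibrated under permuted null labels", {
  withr::with_seed(31, {
    pvals <- vapply(1:200, function(i) {
      d <- data.frame(v = rnorm(30), g = sample(rep(c("a", "b", "c"), 10)))
      kruskal_dunn(d, "v", "g")$kw_p
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))  # discrete ties
  expect_gt(ks$p.value, 0.01)
})

test_that("freeman-halton reduces to Fisher's exact test on 2x2 tables", {
  withr::with_seed(32, {
    for (i in 1:20) {
      t2 <- matrix(rpois(4, 6) + 1, 2)
      expect_equal(freeman_halton(t2)$p_value,
                   stats::fisher.test(t2)$p.value, tolerance = 1e-9)
    }
  })
})

test_that("enumerated table probabilities sum to one", {
  for (tab in list(rbind(c(7, 9, 11), c(8, 6, 4)),
                   rbind(c(10, 8, 10), c(5, 7, 5)),
                   rbind(c(3, 1, 4), c(2, 5, 2), c(1, 2, 3)))) {
    res <- freeman_halton(tab)
    expect_lt(abs(res$total_prob - 1), 1e-10)
  }
})

test_that("monte-carlo freeman-halton approximates the exact value", {
  tab <- rbind(c(7, 9, 11), c(8, 6, 4))
  exact <- freeman_halton(tab)$p_value
  mc <- freeman_halton(tab, monte_carlo = TRUE, n_sim = 20000, seed = 33)
  expect_lt(abs(mc$p_value - exact), 0.02)
  expect_error(freeman_halton(tab, max_tables = 10), "budget")
  expect_error(freeman_halton(rbind(c(0, 0), c(1, 2))), "positive")
  expect_error(freeman_halton(rbind(c(0.5, 1), c(1, 2))), "integer")
})
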