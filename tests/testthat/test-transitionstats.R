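# Paired transition statistics: set construction, Wilcoxon signed rank,
# dependent-samples Hedges' g, AUC and bootstrap confidence intervals.

make_trends <- function(n_subjects, times = 0:100, f = function(t, i) t) {
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    tibble::tibble(subject_id = sprintf("s%02d", i),
                   group = if (i %% 2) "a" else "b",
                   time_s = times, value = f(times, i))
  })
}

test_that("paired sets keep one pre/post pair per covered subject", {
  tr <- make_trends(6)
  ps <- build_paired_set(tr, 50, "ROR")
  expect_equal(nrow(ps), 6)
  expect_equal(ps$pre, rep(35, 6))
  expect_equal(ps$post, rep(80, 6))

  # two subjects lack the post-event window: dropped and logged
  short <- dplyr::filter(tr, !(subject_id %in% c("s01", "s02") &
                                 time_s > 60))
  expect_message(ps2 <- build_paired_set(short, 50, "ROR"), "dropped 2")
  expect_equal(nrow(ps2), 4)
  expect_equal(nrow(attr(ps2, "dropped")), 2)

  # zero offsets give identical pre and post
  ps0 <- build_paired_set(tr, 50, "ROR", pre_offset_s = 0, post_offset_s = 0)
  expect_identical(ps0$pre, ps0$post)

  expect_error(build_paired_set(dplyr::filter(tr, time_s < 20), 50, "ROR"),
               "No subject retained")
})

test_that("wilcoxon exact path matches known and enumerated values", {
  # n = 5, all differences positive: p = 2/2^5
  res <- wilcoxon_signed_rank(c(3, 4, 5, 6, 7), c(1, 2, 3, 4, 5))
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$n_effective, 5L)

  # antisymmetric differences sit at the null centre
  res2 <- wilcoxon_signed_rank(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_equal(res2$p_value, 1)

  # all-zero differences: defined p = 1 with a warning
  expect_warning(res3 <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(res3$p_value, 1)
  expect_equal(res3$n_zero_dropped, 4L)
})

test_that("wilcoxon agrees with the closed-form null on tie-free data", {
  withr::with_seed(17, {
    for (i in 1:50) {
      n <- sample(4:12, 1)
      d <- rnorm(n)
      got <- wilcoxon_signed_rank(d, rep(0, n))$p_value
      expect_equal(got, wilcoxon_oracle(d), tolerance = 1e-12)
    }
  })
})

test_that("exact and approximate wilcoxon paths agree for n = 20", {
  withr::with_seed(18, {
    for (i in 1:20) {
      pre <- rnorm(20)
      post <- rnorm(20)
      p_exact <- wilcoxon_signed_rank(pre, post, exact_max = 20)$p_value
      p_approx <- wilcoxon_signed_rank(pre, post, exact_max = 0)$p_value
      expect_lt(abs(p_exact - p_approx), 0.02)
    }
  })
})

test_that("hedges g matches the hand formula with the J correction", {
  res <- hedges_g_dependent(c(2, 4, 6), c(1, 2, 3), n_boot = 200)
  expect_equal(res$g, (1 - 3 / 7) * 2 / 1, tolerance = 1e-12)

  flat <- hedges_g_dependent(c(1, -1, 2, -2), rep(0, 4), n_boot = 200)
  expect_equal(flat$g, 0, tolerance = 1e-12)

  expect_error(hedges_g_dependent(c(1, 2, 3), c(0, 1, 2)), "zero variance")
})

test_that("sign-flipping all differences negates g and mirrors the CI", {
  pre <- withr::with_seed(19, rnorm(12, 1))
  post <- withr::with_seed(20, rnorm(12))
  a <- hedges_g_dependent(pre, post, n_boot = 2000, seed = 4)
  b <- hedges_g_dependent(post, pre, n_boot = 2000, seed = 4)
  expect_equal(b$g, -a$g, tolerance = 1e-12)
  expect_equal(b$ci, -rev(a$ci), tolerance = 1e-9)
})

test_that("auc matches brute-force pair counting and its limits", {
  expect_equal(auc_two_sample(c(1, 2, 3), c(2, 3, 4)), 7 / 9)
  expect_equal(auc_two_sample(1:5, 1:5), 0.5)
  expect_equal(auc_two_sample(1:3, 4:6), 1)
  expect_error(auc_two_sample(numeric(), 1:3), "nonempty")
  withr::with_seed(21, {
    for (i in 1:100) {
      x <- sample(1:6, sample(2:8, 1), replace = TRUE)
      y <- sample(1:6, sample(2:8, 1), replace = TRUE)
      expect_equal(auc_two_sample(x, y), auc_oracle(x, y),
                   tolerance = 1e-12)
      expect_equal(emergeEEG:::cpp_auc(x, y), auc_oracle(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("label swap reflects the AUC around 0.5", {
  withr::with_seed(22, {
    x <- rnorm(9)
    y <- rnorm(11, 0.5)
    expect_equal(auc_two_sample(x, y), 1 - auc_two_sample(y, x),
                 tolerance = 1e-12)
  })
})

test_that("bootstrap CIs are seeded, cover the estimate, collapse when flat", {
  x <- withr::with_seed(23, rnorm(20))
  ci1 <- bootstrap_ci(mean, x, n_boot = 500, seed = 5)
  ci2 <- bootstrap_ci(mean, x, n_boot = 500, seed = 5)
  expect_identical(ci1, ci2)
  expect_lt(ci1[1], ci1[2])

  flat <- bootstrap_ci(mean, rep(3, 10), n_boot = 100, seed = 5)
  expect_equal(unname(flat), c(3, 3))

  expect_error(bootstrap_ci(mean, 1:2, n_boot = 10), "3 resampling units")

  # CI contains the point estimate in nearly all simulated datasets
  hits <- withr::with_seed(24, vapply(1:100, function(i) {
    z <- rnorm(15)
    ci <- bootstrap_ci(mean, z, n_boot = 300, seed = i)
    ci[1] <= mean(z) && mean(z) <= ci[2]
  }, logical(1)))
  expect_gte(mean(hits), 0.99)
})

test_that("CI-based significance uses closed containment of 0.5", {
  expect_true(significant_by_ci(c(0.63, 0.84)))
  expect_false(significant_by_ci(c(0.28, 0.74)))
  expect_false(significant_by_ci(c(0.5, 0.84)))   # touching counts as inside
  expect_false(significant_by_ci(c(0.31, 0.5)))
})

test_that("paired transition test composes a full results row", {
  withr::with_seed(25, {
    pre <- rnorm(15, 2.35, 0.05)
    post <- pre - rnorm(15, 0.08, 0.03)  # clear decrease
  })
  tr <- purrr::map_dfr(1:15, function(i) {
    tibble::tibble(subject_id = sprintf("s%02d", i), group = "pooled",
                   time_s = c(135, 180),
                   value = c(pre[i], post[i]))
  })
  ps <- build_paired_set(tr, 150, "LOR")
  tt <- paired_transition_test(ps, n_boot = 2000, seed = 6)
  row <- tidy(tt)
  expect_equal(row$n, 15)
  expect_lt(row$p_value, 0.05)
  expect_gt(row$g, 0)          # decrease -> positive g on (pre - post)
  expect_gt(row$auc, 0.5)      # responsive (pre) side higher
  expect_true(row$auc_lo <= row$auc & row$auc <= row$auc_hi)
  expect_s3_class(glance(tt), "tbl_df")
})
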