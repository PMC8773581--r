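# Paired pre/post statistics at LOR and ROR: value extraction at -15/+30 s,
# Wilcoxon signed rank, dependent-samples Hedges' g, and AUC with bootstrap
# confidence intervals.

#' Build a paired pre/post set around a transition event
#'
#' Extracts, per subject, the trend value nearest `event + pre_offset_s` and
#' `event + post_offset_s` (window-start convention: the pre-LOR/ROR value
#' comes from a window containing only pre-event signal). Subjects whose
#' trend does not cover both offsets are dropped and recorded in the
#' `dropped` attribute.
#'
#' @param trends A tibble with columns `subject_id`, `time_s`, the value
#'   column, and optionally `group`: typically row-bound per-subject outputs
#'   of [peen_trend()], [index_trend()] or [band_power()] with a
#'   `subject_id` column.
#' @param events A tibble `subject_id`, `time_s` giving each subject's event
#'   time, or a single number if all subjects share it.
#' @param event_name Label, e.g. `"LOR"` or `"ROR"`.
#' @param pre_offset_s,post_offset_s Offsets in seconds relative to the
#'   event (defaults -15 and +30).
#' @param value_col Name of the value column; defaults to the first numeric
#'   column other than `time_s`.
#' @return A tibble of class `paired_transition_set` with columns
#'   `subject_id`, `group`, `pre`, `post`; attributes `parameter`,
#'   `event_name`, `dropped`.
#' @export
build_paired_set <- function(trends, events, event_name = "event",
                             pre_offset_s = -15, post_offset_s = 30,
                             value_col = NULL) {
  if (is.null(value_col)) {
    cand <- setdiff(names(trends)[vapply(trends, is.numeric, logical(1))],
                    c("time_s"))
    if (!length(cand)) abort("No numeric value column found in `trends`.")
    value_col <- cand[1]
  }
  if (is.numeric(events) && length(events) == 1L) {
    events <- tibble(subject_id = unique(trends$subject_id), time_s = events)
  }
  rows <- list()
  dropped <- list()
  for (sid in unique(trends$subject_id)) {
    tr <- trends[trends$subject_id == sid, , drop = FALSE]
    ev <- events$time_s[events$subject_id == sid]
    if (!length(ev)) {
      dropped[[sid]] <- "no event time"
      next
    }
    vals <- tryCatch(
      c(pre = extract_window_at(tr, ev[1], pre_offset_s, col = value_col),
        post = extract_window_at(tr, ev[1], post_offset_s, col = value_col)),
      error = function(e) NULL)
    if (is.null(vals) || anyNA(vals)) {
      dropped[[sid]] <- if (is.null(vals)) "offset outside trend coverage"
                        else "non-finite value at offset"
      next
    }
    rows[[sid]] <- tibble(subject_id = sid,
                          group = if ("group" %in% names(tr))
                            tr$group[1] else NA_character_,
                          pre = vals[["pre"]], post = vals[["post"]])
  }
  if (!length(rows)) {
    abort(sprintf("No subject retained for the %s paired set.", event_name))
  }
  if (length(dropped)) {
    inform(sprintf("%s paired set: dropped %d subject(s): %s.", event_name,
                   length(dropped),
                   paste(sprintf("%s (%s)", names(dropped),
                                 unlist(dropped)), collapse = "; ")))
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("paired_transition_set", class(out)),
            parameter = value_col, event_name = event_name,
            dropped = tibble(subject_id = names(dropped),
                             reason = unlist(dropped) %||% character()))
}

#' Wilcoxon signed rank test for paired values
#'
#' Two-sided test on `pre - post`. Zero differences are dropped (classic
#' Wilcoxon convention; the count is reported). With 15 or fewer nonzero
#' differences the null distribution is enumerated exactly over all sign
#' assignments (midranks, so ties are handled exactly); above that a normal
#' approximation with tie and continuity correction is used.
#'
#' @param pre,post Numeric vectors aligned by subject, or a
#'   `paired_transition_set` as `pre`.
#' @param exact_max Largest n for the exact enumeration path (default 15).
#' @return A list of class `wilcoxon_signed_rank`: `p_value`, `statistic`
#'   (V, sum of positive ranks), `n_effective`, `n_zero_dropped`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(3, 4, 5, 6, 7), c(1, 2, 3, 4, 5))$p_value  # 0.0625
#' @export
wilcoxon_signed_rank <- function(pre, post = NULL, exact_max = 15) {
  if (inherits(pre, "paired_transition_set")) {
    post <- pre$post
    pre <- pre$pre
  }
  stopifnot(length(pre) == length(post))
  d <- pre - post
  check_samples(d, "differences")
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n == 0L) {
    warn("All differences are zero; returning p = 1.")
    return(structure(list(p_value = 1, statistic = 0, n_effective = 0L,
                          n_zero_dropped = n_zero, method = "degenerate"),
                     class = "wilcoxon_signed_rank"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: V is the rank-sum over a uniformly random sign assignment
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(w_all <= v + 1e-9), mean(w_all >= v - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tt <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
    cc <- sign(v - mu) * 0.5
    z <- (v - mu - cc) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation (tie/continuity corrected)"
  }
  structure(list(p_value = p, statistic = v, n_effective = n,
                 n_zero_dropped = n_zero, method = method),
            class = "wilcoxon_signed_rank")
}

#' @export
print.wilcoxon_signed_rank <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank (%s): V = %g, n = %d, p = %.4g\n",
              x$method, x$statistic, x$n_effective, x$p_value))
  invisible(x)
}

#' Hedges' g for dependent samples, with bootstrap CI
#'
#' `g = J * mean(d) / sd(d)` with `d = pre - post`, the `n - 1` denominator,
#' and the small-sample correction `J = 1 - 3 / (4 (n - 1) - 1)`. A parameter
#' *decrease* therefore yields positive g. The confidence interval is a
#' bias-corrected percentile bootstrap over subjects.
#'
#' @param pre,post Numeric vectors aligned by subject, or a
#'   `paired_transition_set` as `pre`.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return A list of class `hedges_g`: `g`, `ci` (length 2), `n`, `n_boot`.
#' @examples
#' hedges_g_dependent(c(2, 4, 6), c(1, 2, 3), n_boot = 200)$g  # ~1.143
#' @export
hedges_g_dependent <- function(pre, post = NULL, n_boot = 10000,
                               level = 0.95, seed = 1L) {
  if (inherits(pre, "paired_transition_set")) {
    post <- pre$post
    pre <- pre$pre
  }
  stopifnot(length(pre) == length(post))
  d <- pre - post
  n <- length(d)
  if (n < 2 || sd(d) == 0) {
    abort("Hedges' g undefined: the differences have zero variance.")
  }
  j <- 1 - 3 / (4 * (n - 1) - 1)
  g <- j * mean(d) / sd(d)
  gb <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      db <- d[sample.int(n, n, replace = TRUE)]
      s <- sd(db)
      if (s == 0) NA_real_ else j * mean(db) / s
    }, numeric(1))
  })
  gb <- gb[is.finite(gb)]
  if (!length(gb)) {
    warn("Degenerate bootstrap; returning collapsed CI at the point value.")
    ci <- c(g, g)
  } else {
    # bias-corrected percentile
    z0 <- qnorm(pmin(pmax((sum(gb < g) + 0.5 * sum(gb == g)) / length(gb),
                          1e-6), 1 - 1e-6))
    alpha <- (1 - level) / 2
    probs <- pnorm(2 * z0 + qnorm(c(alpha, 1 - alpha)))
    ci <- unname(quantile(gb, probs, type = 7))
  }
  structure(list(g = g, ci = ci, n = n, n_boot = n_boot, level = level),
            class = "hedges_g")
}

#' @export
print.hedges_g <- function(x, ...) {
  cat(sprintf("Hedges' g (dependent): g = %.3f [%.3f, %.3f] (n = %d)\n",
              x$g, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Two-sample Mann-Whitney AUC
#'
#' `P(Y > X) + 0.5 P(Y = X)` via the rank formula (ties as midranks), which
#' is identical to brute-force pair counting.
#'
#' @param x,y Numeric samples (x: reference/negative class).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_two_sample(c(1, 2, 3), c(2, 3, 4))  # 7/9
#' @export
auc_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) abort("Both samples must be nonempty.")
  check_samples(x, "x")
  check_samples(y, "y")
  r <- rank(c(x, y))
  ny <- length(y)
  (sum(r[(length(x) + 1):(length(x) + ny)]) - ny * (ny + 1) / 2) /
    (length(x) * ny)
}

#' Percentile bootstrap confidence interval
#'
#' Seeded percentile bootstrap of an arbitrary statistic. The resampling
#' unit is the element of `data`: rows of a data frame (subjects for paired
#' statistics), or elements within each group if `data` is a list of two or
#' more vectors (subjects within group for two-group AUC).
#'
#' @param statistic Function taking resampled data (same shape as `data`).
#' @param data Vector, data frame, or list of vectors.
#' @param n_boot Number of resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Length-2 numeric `(lo, hi)`.
#' @examples
#' bootstrap_ci(mean, rnorm(20), n_boot = 500, seed = 2)
#' @export
bootstrap_ci <- function(statistic, data, n_boot = 10000, level = 0.95,
                         seed = 1L) {
  resample <- function() {
    if (is.data.frame(data)) {
      data[sample.int(nrow(data), nrow(data), replace = TRUE), , drop = FALSE]
    } else if (is.list(data)) {
      lapply(data, function(g) g[sample.int(length(g), length(g),
                                            replace = TRUE)])
    } else {
      data[sample.int(length(data), length(data), replace = TRUE)]
    }
  }
  n_units <- if (is.data.frame(data)) nrow(data)
             else if (is.list(data)) min(lengths(data))
             else length(data)
  if (n_units < 3) abort("Need at least 3 resampling units for a bootstrap.")
  stats_b <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) as.numeric(statistic(resample())),
           numeric(1))
  })
  ok <- is.finite(stats_b)
  if (!any(ok)) {
    warn("Statistic degenerate on every resample; collapsed CI returned.")
    return(c(NA_real_, NA_real_))
  }
  if (length(unique(stats_b[ok])) == 1L && sum(ok) < n_boot) {
    warn("Statistic degenerate on some resamples; CI may be collapsed.")
  }
  alpha <- (1 - level) / 2
  unname(quantile(stats_b[ok], c(alpha, 1 - alpha), type = 7))
}

#' Is an AUC significantly different from chance?
#'
#' `TRUE` iff the confidence interval excludes 0.5. Containment is closed:
#' an interval touching 0.5 at an endpoint counts as containing it (not
#' significant).
#'
#' @param ci Length-2 numeric `(lo, hi)`.
#' @return Logical flag.
#' @examples
#' significant_by_ci(c(0.63, 0.84))  # TRUE
#' significant_by_ci(c(0.28, 0.74))  # FALSE
#' @export
significant_by_ci <- function(ci) {
  stopifnot(length(ci) == 2L, ci[1] <= ci[2])
  !(ci[1] <= 0.5 && 0.5 <= ci[2])
}

#' Full paired transition analysis of one parameter at one event
#'
#' Combines the Wilcoxon signed rank test, dependent-samples Hedges' g with
#' bootstrap CI, and the responsive-vs-unresponsive AUC with bootstrap CI
#' (subjects resampled as pairs). The AUC is oriented as P(responsive-state
#' value > unresponsive-state value): the pre-event side is responsive at
#' LOR, the post-event side at ROR.
#'
#' @param pset A `paired_transition_set` from [build_paired_set()].
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param responsive `"auto"` (from the event name), `"pre"` or `"post"`.
#' @return An object of class `transition_test`; use [tidy()] for a one-row
#'   tibble mirroring a results-table row.
#' @export
paired_transition_test <- function(pset, n_boot = 10000, seed = 1L,
                                   responsive = c("auto", "pre", "post")) {
  responsive <- match.arg(responsive)
  ev <- attr(pset, "event_name") %||% "event"
  if (responsive == "auto") {
    responsive <- if (grepl("LOR", ev, ignore.case = TRUE)) "pre" else "post"
  }
  wt <- wilcoxon_signed_rank(pset)
  hg <- hedges_g_dependent(pset, n_boot = n_boot, seed = seed)
  resp <- if (responsive == "pre") pset$pre else pset$post
  unresp <- if (responsive == "pre") pset$post else pset$pre
  auc <- auc_two_sample(unresp, resp)
  auc_ci <- bootstrap_ci(
    function(df) auc_two_sample(df$unresp, df$resp),
    tibble(resp = resp, unresp = unresp),
    n_boot = n_boot, seed = seed + 1L)
  structure(list(event = ev,
                 parameter = attr(pset, "parameter") %||% "value",
                 group = if (length(unique(pset$group)) == 1L)
                   pset$group[1] else "pooled",
                 n = nrow(pset),
                 pre = pset$pre, post = pset$post,
                 wilcoxon = wt, hedges = hg,
                 auc = auc, auc_ci = auc_ci,
                 significant_auc = significant_by_ci(auc_ci),
                 responsive = responsive),
            class = "transition_test")
}

#' @export
print.transition_test <- function(x, ...) {
  cat(sprintf("<transition_test> %s / %s (%s, n = %d)\n", x$event,
              x$parameter, x$group, x$n))
  cat(sprintf("  p = %.4g, g = %.2f [%.2f, %.2f], AUC = %.2f [%.2f, %.2f]%s\n",
              x$wilcoxon$p_value, x$hedges$g, x$hedges$ci[1], x$hedges$ci[2],
              x$auc, x$auc_ci[1], x$auc_ci[2],
              if (x$significant_auc) " *" else ""))
  invisible(x)
}

#' @export
tidy.transition_test <- function(x, ...) {
  tibble(event = x$event, parameter = x$parameter, group = x$group,
         n = x$n,
         pre_median = median(x$pre), pre_q1 = unname(quantile(x$pre, 0.25)),
         pre_q3 = unname(quantile(x$pre, 0.75)),
         post_median = median(x$post),
         post_q1 = unname(quantile(x$post, 0.25)),
         post_q3 = unname(quantile(x$post, 0.75)),
         p_value = x$wilcoxon$p_value,
         g = x$hedges$g, g_lo = x$hedges$ci[1], g_hi = x$hedges$ci[2],
         auc = x$auc, auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
         significant_auc = x$significant_auc)
}

#' @export
glance.transition_test <- function(x, ...) {
  tibble(n = x$n, p_value = x$wilcoxon$p_value, g = x$hedges$g,
         auc = x$auc, significant_auc = x$significant_auc)
}
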