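# Between-group emergence analyses: per-bin PSD comparison with the
# two-neighbouring-bin rule, pixel-wise AUC maps with cluster-based
# reporting, the wake-like index duration statistic, and Kruskal-Wallis
# with Dunn's post-hoc comparisons.

resample_index_matrix <- function(n_boot, n) {
  matrix(sample.int(n, n_boot * n, replace = TRUE) - 1L, nrow = n_boot)
}

subject_value_matrix <- function(df, value_col, cell_cols) {
  wide <- tidyr::pivot_wider(df,
                             id_cols = "subject_id",
                             names_from = dplyr::all_of(cell_cols),
                             values_from = dplyr::all_of(value_col))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subject_id
  m
}

#' Per-frequency-bin PSD comparison between two groups
#'
#' For each frequency bin, computes the subject-level two-group AUC (one PSD
#' value per subject per bin), a seeded percentile-bootstrap confidence
#' interval (subjects resampled within group), and flags bins whose CI
#' excludes 0.5. A finding is *retained* only where at least two neighbouring
#' bins are jointly significant.
#'
#' @param group_a,group_b Tibbles with columns `subject_id`, `freq_hz` and a
#'   power column (`power` or `power_uv2_hz`): one PSD row per subject, all
#'   on the same frequency grid.
#' @param n_boot Bootstrap resamples per bin (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return A tibble `freq_hz`, `auc`, `ci_lo`, `ci_hi`, `sig`, `retained`.
#'   The AUC is oriented as P(group B value > group A value).
#' @export
psd_compare <- function(group_a, group_b, n_boot = 1000, seed = 1L,
                        level = 0.95) {
  val <- intersect(c("power", "power_uv2_hz"), names(group_a))[1]
  fa <- sort(unique(group_a$freq_hz))
  fb <- sort(unique(group_b$freq_hz))
  if (length(fa) != length(fb) || any(abs(fa - fb) > 1e-9)) {
    abort("The two groups are on different frequency grids.")
  }
  X <- subject_value_matrix(dplyr::arrange(group_a, .data$freq_hz), val,
                            "freq_hz")
  Y <- subject_value_matrix(dplyr::arrange(group_b, .data$freq_hz), val,
                            "freq_hz")
  if (nrow(X) < 3 || nrow(Y) < 3) abort("Need at least 3 subjects per group.")
  auc <- as.numeric(cpp_auc_matrix(X, Y))
  boot <- with_seed(seed, {
    cpp_auc_boot(X, Y, resample_index_matrix(n_boot, nrow(X)),
                 resample_index_matrix(n_boot, nrow(Y)))
  })
  alpha <- (1 - level) / 2
  ci <- apply(boot, 2, quantile, probs = c(alpha, 1 - alpha), type = 7)
  sig <- ci[1, ] > 0.5 | ci[2, ] < 0.5
  nb <- length(sig)
  neighbour <- c(sig[-1], FALSE) | c(FALSE, sig[-nb])
  tibble(freq_hz = fa, auc = auc, ci_lo = ci[1, ], ci_hi = ci[2, ],
         sig = sig, retained = sig & neighbour)
}

#' Align a spectrogram to an event
#'
#' Re-timestamps DSA rows as seconds relative to the event, keeping the
#' windows that lie fully inside `[event - span_s, event]`: with 10 s
#' windows and a 1 s hop the aligned window starts run from `-span_s` to
#' `-window_s`.
#'
#' @param spec An `eeg_dsa` tibble from [dsa()].
#' @param event_time_s Event time (seconds from record start); defaults to
#'   the recording's `ROR` event carried on the spectrogram.
#' @param span_s Length of the pre-event span (default 600 s).
#' @return A tibble `rel_time_s`, `freq_hz`, `power` of class `aligned_dsa`.
#' @export
align_to_event <- function(spec, event_time_s = NULL, span_s = 600) {
  meta <- dsa_meta(spec)
  event_time_s <- event_time_s %||% meta$events[["ROR"]]
  if (is.null(event_time_s)) abort("No event time given or carried on `spec`.")
  wanted <- seq(event_time_s - span_s, event_time_s - meta$window_s,
                by = meta$hop_s)
  have <- sort(unique(spec$time_s))
  hit <- vapply(wanted, function(t) any(abs(have - t) < 1e-6), logical(1))
  if (!all(hit)) {
    abort(sprintf(
      "Spectrogram does not cover [event - %g s, event]: %d of %d required windows missing.",
      span_s, sum(!hit), length(wanted)))
  }
  sel <- spec$time_s >= wanted[1] - 1e-9 &
    spec$time_s <= wanted[length(wanted)] + 1e-9
  out <- tibble(rel_time_s = spec$time_s[sel] - event_time_s,
                freq_hz = spec$freq_hz[sel],
                power = spec$power[sel])
  structure(out, class = c("aligned_dsa", class(out)),
            window_s = meta$window_s, hop_s = meta$hop_s,
            subject_id = attr(spec, "subject_id"),
            group = attr(spec, "group"))
}

# 4-connected component labelling of a logical matrix (iterative flood fill).
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      if (i > 1L) stack <- c(stack, p - 1L)
      if (i < nr) stack <- c(stack, p + 1L)
      if (j > 1L) stack <- c(stack, p - nr)
      if (j < nc) stack <- c(stack, p + nr)
    }
  }
  lab
}

#' Pixel-wise AUC map between two groups of aligned spectrograms
#'
#' Computes, for every time-frequency pixel, the subject-level two-group AUC
#' with a seeded bootstrap CI; pixels whose CI excludes 0.5 are significant,
#' and the cluster mask keeps significant pixels belonging to 4-connected
#' components of at least `cluster_min` pixels.
#'
#' @param group_a,group_b Tibbles with columns `subject_id`, `rel_time_s`,
#'   `freq_hz`, `power`: row-bound [align_to_event()] outputs with a
#'   `subject_id` column, all on the same grid.
#' @param n_boot Bootstrap resamples per pixel (default 500).
#' @param seed Integer seed.
#' @param cluster_min Minimum cluster size in pixels (default 8, calibrated
#'   on the null generator).
#' @param freq_band Frequency reporting band (default 6-30 Hz).
#' @param level Confidence level (default 0.95).
#' @return A tibble of class `auc_map`: `rel_time_s`, `freq_hz`, `auc`,
#'   `ci_lo`, `ci_hi`, `sig`, `cluster`. AUC is oriented as
#'   P(group B value > group A value).
#' @export
auc_map <- function(group_a, group_b, n_boot = 500, seed = 1L,
                    cluster_min = 8, freq_band = c(6, 30), level = 0.95) {
  ga <- dplyr::filter(group_a, .data$freq_hz >= freq_band[1],
                      .data$freq_hz <= freq_band[2])
  gb <- dplyr::filter(group_b, .data$freq_hz >= freq_band[1],
                      .data$freq_hz <= freq_band[2])
  key_a <- dplyr::arrange(dplyr::distinct(ga, .data$rel_time_s, .data$freq_hz),
                          .data$rel_time_s, .data$freq_hz)
  key_b <- dplyr::arrange(dplyr::distinct(gb, .data$rel_time_s, .data$freq_hz),
                          .data$rel_time_s, .data$freq_hz)
  if (nrow(key_a) != nrow(key_b) ||
      max(abs(key_a$rel_time_s - key_b$rel_time_s)) > 1e-9 ||
      max(abs(key_a$freq_hz - key_b$freq_hz)) > 1e-9) {
    abort("The two groups are on different time-frequency grids.")
  }
  ga <- dplyr::arrange(ga, .data$rel_time_s, .data$freq_hz)
  gb <- dplyr::arrange(gb, .data$rel_time_s, .data$freq_hz)
  X <- subject_value_matrix(ga, "power", c("rel_time_s", "freq_hz"))
  Y <- subject_value_matrix(gb, "power", c("rel_time_s", "freq_hz"))
  if (nrow(X) < 3 || nrow(Y) < 3) abort("Need at least 3 subjects per group.")
  grid <- dplyr::arrange(key_a, .data$rel_time_s, .data$freq_hz)
  auc <- as.numeric(cpp_auc_matrix(X, Y))
  boot <- with_seed(seed, {
    cpp_auc_boot(X, Y, resample_index_matrix(n_boot, nrow(X)),
                 resample_index_matrix(n_boot, nrow(Y)))
  })
  alpha <- (1 - level) / 2
  ci <- apply(boot, 2, quantile, probs = c(alpha, 1 - alpha), type = 7)
  sig <- ci[1, ] > 0.5 | ci[2, ] < 0.5

  times <- sort(unique(grid$rel_time_s))
  freqs <- sort(unique(grid$freq_hz))
  # grid is arranged time-major, so the mask fills a freq x time matrix
  mask <- matrix(sig, nrow = length(freqs), ncol = length(times))
  lab <- label_components(mask)
  keep <- which(tabulate(lab) >= cluster_min)
  cluster <- lab %in% keep & mask
  out <- tibble(rel_time_s = grid$rel_time_s, freq_hz = grid$freq_hz,
                auc = auc, ci_lo = ci[1, ], ci_hi = ci[2, ],
                sig = sig, cluster = as.vector(cluster))
  structure(out, class = c("auc_map", class(out)),
            cluster_min = cluster_min, n_boot = n_boot, level = level)
}

#' Duration the depth index indicated wakefulness before ROR
#'
#' Length of the maximal contiguous run of index values at or above
#' `threshold` ending at (and including) the last analysis window before
#' ROR. A subject whose index is below threshold at ROR gets a duration of
#' 0 s with `at_ror_below = TRUE`. With `contiguous = FALSE` the total
#' (possibly interrupted) time at or above threshold before ROR is returned
#' instead.
#'
#' @param trend An [index_trend()] tibble (or any trend with `time_s` and a
#'   value column).
#' @param ror_time_s ROR time in seconds from record start; defaults to the
#'   `ROR` event carried on the trend.
#' @param threshold Wake-like index threshold (default 80).
#' @param value_col Value column (default `csi_like`).
#' @param contiguous Use the contiguous-run-ending-at-ROR reading
#'   (default `TRUE`).
#' @return One-row tibble: `subject_id`, `group`, `duration_s`,
#'   `at_ror_below`.
#' @export
duration_above <- function(trend, ror_time_s = NULL, threshold = 80,
                           value_col = "csi_like", contiguous = TRUE) {
  ror_time_s <- ror_time_s %||% (attr(trend, "events") %||% numeric())[["ROR"]]
  if (is.null(ror_time_s) || is.na(ror_time_s)) {
    abort("No ROR time given or carried on the trend.")
  }
  window_s <- attr(trend, "window_s") %||% 10
  hop_s <- attr(trend, "hop_s") %||% 1
  times <- trend$time_s
  vals <- trend[[value_col]]
  pre <- times <= ror_time_s - window_s + 1e-9
  if (!any(pre) || max(times[pre]) < ror_time_s - window_s - hop_s - 1e-9) {
    abort("Trend does not reach the last pre-ROR window.")
  }
  ord <- order(times)
  times <- times[ord][pre[ord]]
  vals <- vals[ord][pre[ord]]
  above <- !is.na(vals) & vals >= threshold
  n <- length(vals)
  if (contiguous) {
    if (!above[n]) {
      dur <- 0
      at_ror_below <- TRUE
    } else {
      i <- n
      while (i > 1 && above[i - 1] &&
             abs(times[i] - times[i - 1] - hop_s) < 1e-9) {
        i <- i - 1
      }
      dur <- ror_time_s - times[i]
      at_ror_below <- FALSE
    }
  } else {
    dur <- sum(above) * hop_s
    at_ror_below <- !above[n]
    if (at_ror_below && dur == 0) dur <- 0
  }
  tibble(subject_id = attr(trend, "subject_id") %||% NA_character_,
         group = attr(trend, "group") %||% NA_character_,
         duration_s = dur, at_ror_below = at_ror_below)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis chi-square test across three or more groups,
#' followed by Dunn's z-tests on mean ranks with Holm step-down adjustment
#' over the pairwise comparisons.
#'
#' @param data A data frame, or a numeric vector of values.
#' @param values,groups Column names (if `data` is a data frame) or the
#'   grouping vector (if `data` is numeric).
#' @return A list of class `kruskal_dunn`: `kw_p`, `kw_chi2`, `df`, and a
#'   `pairwise` tibble (`group1`, `group2`, `z`, `p_raw`, `p_adj`).
#' @examples
#' kruskal_dunn(data.frame(v = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                         g = rep(c("a", "b", "c"), each = 3)), "v", "g")
#' @export
kruskal_dunn <- function(data, values = "value", groups = "group") {
  if (is.data.frame(data)) {
    x <- data[[values]]
    g <- factor(data[[groups]])
  } else {
    x <- data
    g <- factor(values)
  }
  tab <- table(g)
  if (any(tab < 2)) {
    abort("Every group needs at least 2 observations for Kruskal-Wallis.")
  }
  kw <- kruskal.test(x, g)
  r <- rank(x)
  n <- length(x)
  rbar <- tapply(r, g, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(levels(g), 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / tab[[p[1]]] + 1 / tab[[p[2]]]))
    (rbar[[p[1]]] - rbar[[p[2]]]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  structure(list(kw_p = kw$p.value,
                 kw_chi2 = unname(kw$statistic),
                 df = unname(kw$parameter),
                 pairwise = tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                                   z = z, p_raw = p_raw,
                                   p_adj = p.adjust(p_raw, "holm"))),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi2 = %.3f (df = %d), p = %.4g\n",
              x$kw_chi2, x$df, x$kw_p))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.kruskal_dunn <- function(x, ...) x$pairwise

#' @export
glance.kruskal_dunn <- function(x, ...) {
  tibble(kw_chi2 = x$kw_chi2, df = x$df, kw_p = x$kw_p)
}
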