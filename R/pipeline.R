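# Orchestration of the full study replica: cohort -> trends -> paired
# transition statistics -> emergence AUC maps -> wake-duration analysis ->
# demographics tests, with seeded determinism and CSV outputs.

#' Analysis settings for a study run
#'
#' @param window_s,hop_s Analysis window grid for trends (defaults 10, 1 s).
#' @param pre_offset_s,post_offset_s Paired-extraction offsets around LOR/ROR
#'   (defaults -15 and +30 s).
#' @param n_boot Bootstrap resamples for scalar statistics (default 10000).
#' @param map_n_boot Bootstrap resamples per map pixel (default 500).
#' @param map_hop_s Time step of the emergence AUC maps in seconds (default
#'   10: non-overlapping episodes, keeping map pixels quasi-independent).
#' @param map_span_s Pre-ROR span of the maps (default 600 s).
#' @param cluster_min Minimum cluster size in pixels (default 8).
#' @param index_threshold Wake-like index threshold (default 80).
#' @param norm_band Reporting band in Hz (default 6-30).
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(window_s = 10, hop_s = 1, pre_offset_s = -15,
                            post_offset_s = 30, n_boot = 10000,
                            map_n_boot = 500, map_hop_s = 10,
                            map_span_s = 600, cluster_min = 8,
                            index_threshold = 80, norm_band = c(6, 30)) {
  structure(as.list(environment()), class = "analysis_config")
}

#' Configuration for a full study run
#'
#' One master seed governs every stochastic stage: the cohort generator
#' inherits it, and each bootstrap stage derives its own substream from it.
#'
#' @param cohort A [cohort_config()]; its seed is overridden by `seed`.
#' @param analysis An [analysis_config()].
#' @param demographics Named list of contingency-table matrices tested with
#'   [freeman_halton()]; defaults to the study's printed sex and ASA tables.
#' @param seed Master integer seed.
#' @param output_dir Directory for CSV outputs, or `NULL` to keep results in
#'   memory only.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), analysis = analysis_config(),
                       demographics = demographics_tables(), seed = 1L,
                       output_dir = NULL) {
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, analysis = analysis,
                 demographics = demographics, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' The study's demographic contingency tables
#'
#' Sex (male/female) and ASA status (I/II) counts for the propofol,
#' sevoflurane and isoflurane groups, used as worked-example inputs to
#' [freeman_halton()].
#'
#' @return Named list of two 2 x 3 integer matrices.
#' @export
demographics_tables <- function() {
  list(
    sex = matrix(c(7, 8, 9, 6, 11, 4), nrow = 2,
                 dimnames = list(c("male", "female"),
                                 c("propofol", "sevoflurane", "isoflurane"))),
    asa = matrix(c(10, 5, 8, 7, 10, 5), nrow = 2,
                 dimnames = list(c("ASA_I", "ASA_II"),
                                 c("propofol", "sevoflurane", "isoflurane")))
  )
}

#' Write / read a run configuration as YAML
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  ser <- list(cohort = unclass(config$cohort),
              analysis = unclass(config$analysis),
              demographics = lapply(config$demographics, function(m) {
                list(counts = as.vector(m), nrow = nrow(m),
                     rownames = rownames(m), colnames = colnames(m))
              }),
              seed = config$seed,
              output_dir = config$output_dir)
  ser$cohort$beta_onset_mean_s <- as.list(config$cohort$beta_onset_mean_s)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  ser <- yaml::read_yaml(path)
  ser$cohort$beta_onset_mean_s <- unlist(ser$cohort$beta_onset_mean_s)
  cohort <- do.call(cohort_config, ser$cohort)
  analysis <- do.call(analysis_config, ser$analysis)
  demo <- lapply(ser$demographics, function(d) {
    matrix(d$counts, nrow = d$nrow,
           dimnames = list(d$rownames, d$colnames))
  })
  run_config(cohort = cohort, analysis = analysis, demographics = demo,
             seed = ser$seed, output_dir = ser$output_dir)
}

trend_with_id <- function(trend, rec) {
  dplyr::mutate(as_tibble(as.data.frame(trend)),
                subject_id = rec$subject_id, group = rec$group,
                .before = 1)
}

#' Run the full study replica on a synthetic cohort
#'
#' Pipeline: simulate cohort; compute permutation-entropy and depth-index
#' trends for induction and emergence; paired LOR statistics pooled over all
#' subjects; paired ROR statistics per group; pairwise emergence AUC maps
#' with cluster reporting; wake-like index duration analysis
#' (Kruskal-Wallis/Dunn plus pairwise AUC); Freeman-Halton demographics
#' tests. Re-running with the same configuration reproduces every table.
#'
#' @param config A [run_config()].
#' @return A list of class `emergence_study`: `paired_stats`,
#'   `map_clusters`, `maps`, `durations`, `duration_test`,
#'   `duration_pairwise`, `demographics`, `cohort_truth`, `manifest`.
#'   If `config$output_dir` is set, tables are also written as CSV together
#'   with a `manifest.csv` recording the configuration hash and seed.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  an <- config$analysis
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  cohort <- stage("simulate", simulate_cohort(config$cohort))

  ind_peen <- stage("induction trends", dplyr::bind_rows(
    purrr::map2(cohort$induction, cohort$emergence, function(ind, em) {
      trend_with_id(peen_trend(ind, window_s = an$window_s,
                               hop_s = an$hop_s), ind)
    })))
  ind_index <- stage("induction index", dplyr::bind_rows(
    purrr::map(cohort$induction, function(ind) {
      trend_with_id(index_trend(ind, window_s = an$window_s,
                                hop_s = an$hop_s), ind)
    })))
  em_peen <- stage("emergence trends", dplyr::bind_rows(
    purrr::map(cohort$emergence, function(em) {
      trend_with_id(peen_trend(em, window_s = an$window_s,
                               hop_s = an$hop_s), em)
    })))
  em_index_trends <- stage("emergence index", purrr::map(
    cohort$emergence, function(em) {
      index_trend(em, window_s = an$window_s, hop_s = an$hop_s)
    }))
  em_index <- dplyr::bind_rows(
    purrr::map2(em_index_trends, cohort$emergence, trend_with_id))

  lor_time <- config$cohort$induction_duration_s / 2
  ror_time <- config$cohort$emergence_duration_s

  paired_rows <- list()
  lor_sets <- list(
    peen_bits = build_paired_set(ind_peen, lor_time, "LOR",
                                 an$pre_offset_s, an$post_offset_s,
                                 value_col = "peen_bits"),
    csi_like = build_paired_set(ind_index, lor_time, "LOR",
                                an$pre_offset_s, an$post_offset_s,
                                value_col = "csi_like"))
  for (nm in names(lor_sets)) {
    tt <- stage(paste("LOR stats", nm),
                paired_transition_test(lor_sets[[nm]], n_boot = an$n_boot,
                                       seed = derive_seed(config$seed, "lor",
                                                          nm)))
    paired_rows[[paste0("LOR_", nm)]] <- tidy(tt)
  }
  for (grp in config$cohort$group_labels) {
    for (nm in c("peen_bits", "csi_like")) {
      trends <- if (nm == "peen_bits") em_peen else em_index
      pset <- build_paired_set(trends[trends$group == grp, , drop = FALSE],
                               ror_time, paste0("ROR-", grp),
                               an$pre_offset_s, an$post_offset_s,
                               value_col = nm)
      tt <- stage(paste("ROR stats", grp, nm),
                  paired_transition_test(pset, n_boot = an$n_boot,
                                         seed = derive_seed(config$seed,
                                                            "ror", grp, nm)))
      paired_rows[[paste0("ROR_", grp, "_", nm)]] <- tidy(tt)
    }
  }
  paired_stats <- dplyr::bind_rows(paired_rows)

  aligned <- stage("align maps", dplyr::bind_rows(
    purrr::map(cohort$emergence, function(em) {
      sp <- dsa(em, window_s = an$window_s, hop_s = an$map_hop_s)
      al <- align_to_event(sp, em$events[["ROR"]], span_s = an$map_span_s)
      dplyr::mutate(as_tibble(as.data.frame(al)),
                    subject_id = em$subject_id, group = em$group,
                    .before = 1)
    })))
  pairs <- utils::combn(config$cohort$group_labels, 2)
  maps <- list()
  cl_rows <- list()
  for (k in seq_len(ncol(pairs))) {
    g1 <- pairs[1, k]
    g2 <- pairs[2, k]
    m <- stage(paste("auc map", g1, g2),
               auc_map(aligned[aligned$group == g1, , drop = FALSE],
                       aligned[aligned$group == g2, , drop = FALSE],
                       n_boot = an$map_n_boot,
                       seed = derive_seed(config$seed, "map", g1, g2),
                       cluster_min = an$cluster_min,
                       freq_band = an$norm_band))
    key <- paste(g1, "vs", g2)
    maps[[key]] <- m
    cl_rows[[key]] <- tibble(comparison = key,
                             n_sig = sum(m$sig),
                             n_cluster_pixels = sum(m$cluster),
                             any_cluster = any(m$cluster))
  }
  map_clusters <- dplyr::bind_rows(cl_rows)

  durations <- stage("durations", dplyr::bind_rows(
    purrr::map(em_index_trends, function(tr) {
      duration_above(tr, threshold = an$index_threshold)
    })))
  duration_test <- stage("duration tests",
                         kruskal_dunn(durations, "duration_s", "group"))
  dur_pairs <- purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- durations$duration_s[durations$group == pairs[1, k]]
    b <- durations$duration_s[durations$group == pairs[2, k]]
    auc <- auc_two_sample(a, b)
    ci <- bootstrap_ci(function(d) auc_two_sample(d[[1]], d[[2]]),
                       list(a, b), n_boot = an$n_boot,
                       seed = derive_seed(config$seed, "dur",
                                          pairs[1, k], pairs[2, k]))
    tibble(group1 = pairs[1, k], group2 = pairs[2, k], auc = auc,
           ci_lo = ci[1], ci_hi = ci[2],
           significant = significant_by_ci(ci))
  })
  duration_pairwise <- dplyr::bind_rows(dur_pairs)

  demographics <- dplyr::bind_rows(purrr::imap(config$demographics,
    function(tab, nm) {
      fh <- stage(paste("demographics", nm), freeman_halton(tab))
      tibble(table = nm, p_value = fh$p_value, n_tables = fh$n_tables)
    }))

  cohort_truth <- dplyr::select(cohort, !dplyr::any_of(c("emergence",
                                                         "induction")))
  manifest <- tibble(
    config_hash = rlang::hash(list(unclass(config$cohort),
                                   unclass(config$analysis),
                                   config$demographics, config$seed)),
    seed = config$seed,
    n_subjects = nrow(cohort),
    paired_hash = rlang::hash(paired_stats),
    durations_hash = rlang::hash(durations),
    maps_hash = rlang::hash(maps))

  out <- structure(list(paired_stats = paired_stats,
                        map_clusters = map_clusters, maps = maps,
                        durations = durations,
                        duration_test = duration_test,
                        duration_pairwise = duration_pairwise,
                        demographics = demographics,
                        cohort_truth = cohort_truth,
                        manifest = manifest),
                   class = "emergence_study")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) readr::write_csv(x, file.path(config$output_dir, f),
                                          progress = FALSE)
    wr(paired_stats, "paired_stats.csv")
    wr(map_clusters, "map_clusters.csv")
    for (nm in names(maps)) {
      wr(as_tibble(as.data.frame(maps[[nm]])),
         paste0("auc_map_", gsub(" ", "_", nm), ".csv"))
    }
    wr(durations, "durations.csv")
    wr(duration_pairwise, "duration_pairwise.csv")
    wr(demographics, "demographics.csv")
    wr(cohort_truth, "cohort_truth.csv")
    wr(manifest, "manifest.csv")
  }
  out
}

#' @export
print.emergence_study <- function(x, ...) {
  cat("<emergence_study>\n")
  cat(sprintf("  %d subjects; %d paired tests; %d AUC maps\n",
              x$manifest$n_subjects, nrow(x$paired_stats), length(x$maps)))
  cat(sprintf("  duration Kruskal-Wallis p = %.4g\n", x$duration_test$kw_p))
  cat(sprintf("  config hash %s (seed %d)\n", x$manifest$config_hash,
              x$manifest$seed))
  invisible(x)
}
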