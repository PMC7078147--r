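# End-to-end pipeline: preprocessing -> classification -> cross-correlation
# -> clustering -> survival linkage. Thin orchestration over the module
# functions so scripts and tests can run (and re-run, reproducibly) the whole
# analysis with one call.

#' Run the full lesion-heterogeneity analysis
#'
#' @param records Long-format lesion records (validated; see
#'   [read_lesion_table()] / [validate_lesion_records()]).
#' @param covariates Patient covariate table.
#' @param ruleset Organ-classification ruleset (default: shipped ruleset).
#' @param k Number of CC clusters (default 3, the conventional
#'   different/undefined/similar split; the elbow diagnostic is always
#'   computed and reported).
#' @param max_lag Maximum visit-index shift searched (default 12).
#' @param seed Seed for the clustering restarts.
#' @param n_restarts K-means restarts.
#' @param threshold Median-CC dichotomization and centroid-label cutoff
#'   (default 0.35).
#' @param min_patients Rare-class merge threshold (default 30).
#' @param survival_arm Treatment arm analyzed for survival (`"cetuximab"`,
#'   `"control"` or `"all"`).
#' @param intra_classes Classes given an intra-class analysis (default: the
#'   main classes present).
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as CSV (deterministic content for a fixed input and seed).
#' @return A list with `preprocess` (report), `classified`, `class_table`,
#'   `interclass` (CC table), `intraclass` (named list of CC tables),
#'   `clustering_zero` / `clustering_max` (cluster fits), `report_zero` /
#'   `report_max` (cluster reports), `lag_hist_max`, `elbow` (diagnostic on
#'   the zero-shift CCs), `outcomes`, `km`, `logrank`, `cox_continuous`,
#'   `cox_binary`.
#' @export
run_pipeline <- function(records, covariates, ruleset = read_ruleset(),
                         k = 3, max_lag = 12, seed = 1, n_restarts = 50,
                         threshold = 0.35, min_patients = 30,
                         survival_arm = "cetuximab",
                         intra_classes = NULL, out_dir = NULL) {
  pre <- preprocess_lesions(records, covariates)
  series <- build_series(pre$records)

  classified <- classify_lesions(lesion_metadata(pre$records), ruleset)
  merged <- merge_rare_classes(classified, min_patients = min_patients)
  classified <- merged$classified

  inter_recs <- interclass_pairs(series, classified, max_lag = max_lag)
  interclass <- cc_table(inter_recs, analysis = "inter-class")

  if (is.null(intra_classes)) {
    intra_classes <- intersect(c("Liver", "Lung", "Lymph node", "Other"),
                               unique(classified$class_name))
  }
  intraclass <- lapply(intra_classes, function(cl) {
    cc_table(intraclass_pairs(series, classified, cl, max_lag = max_lag),
             analysis = paste0("intra-class:", cl))
  })
  names(intraclass) <- intra_classes

  defined_zero <- interclass$cc_zero[!is.na(interclass$cc_zero)]
  elbow <- if (length(unique(defined_zero)) >= 7) {
    choose_k_elbow(defined_zero, seed = seed)
  } else NULL

  clustering_zero <- cluster_cc_pairs(interclass, use_max_cc = FALSE, k = k,
                                      seed = seed, n_restarts = n_restarts)
  clustering_max <- cluster_cc_pairs(interclass, use_max_cc = TRUE, k = k,
                                     seed = seed, n_restarts = n_restarts)
  report_zero <- cluster_report(clustering_zero, cutoff = threshold)
  report_max <- cluster_report(clustering_max, cutoff = threshold)
  lag_hist_max <- lag_histogram(clustering_max)

  surv_cov <- if (identical(survival_arm, "all")) covariates
              else covariates[covariates$arm == survival_arm, , drop = FALSE]
  outcomes <- build_outcomes(surv_cov, interclass, series, threshold = threshold)
  with_cc <- outcomes[!is.na(outcomes$cc_group), , drop = FALSE]
  two_groups <- length(unique(with_cc$cc_group)) == 2 &&
    all(table(with_cc$cc_group) >= 2)
  km <- if (two_groups) km_estimate(outcomes, risk_times = seq(0, 150, by = 25))
        else NULL
  logrank <- if (two_groups) logrank_test(outcomes) else NULL
  cox_continuous <- cox_fit(outcomes,
                            terms = c("ecog", "ts0", "ts_ratio8", "kras",
                                      "median_cc"))
  cox_binary <- cox_fit(outcomes,
                        terms = c("ecog", "ts0", "ts_ratio8", "kras", "cc_low"),
                        threshold = threshold)

  result <- list(preprocess = pre$report, classified = classified,
                 class_table = class_summary(classified),
                 merge_report = merged$report,
                 interclass = interclass, intraclass = intraclass,
                 clustering_zero = clustering_zero,
                 clustering_max = clustering_max,
                 report_zero = report_zero, report_max = report_max,
                 lag_hist_max = lag_hist_max, elbow = elbow,
                 outcomes = outcomes, km = km, logrank = logrank,
                 cox_continuous = cox_continuous, cox_binary = cox_binary)
  if (!is.null(out_dir)) write_pipeline_results(result, out_dir)
  result
}

#' Write pipeline result tables as CSV
#'
#' Writes the CC table, the cluster reports (zero-shift and lag-maximized),
#' the lag histogram, the class summary, the outcome table and the Cox model
#' tables. Output is deterministic for a fixed input and seed.
#'
#' @param result Output of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_pipeline_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(result$class_table, "class_summary.csv")
  all_cc <- rbind(result$interclass, do.call(rbind, unname(result$intraclass)))
  w(all_cc, "cc_pairs.csv")
  w(result$report_zero$table, "clusters_zero_shift.csv")
  w(result$report_max$table, "clusters_max_cc.csv")
  w(result$lag_hist_max, "lag_histogram.csv")
  w(result$outcomes, "outcomes.csv")
  w(result$cox_continuous$table, "cox_continuous.csv")
  w(result$cox_binary$table, "cox_binary.csv")
  if (!is.null(result$km)) {
    curves <- do.call(rbind, lapply(names(result$km$groups), function(g) {
      cbind(group = g, result$km$groups[[g]]$curve)
    }))
    w(curves, "km_curves.csv")
    w(result$km$risk_table, "km_risk_table.csv")
  }
  invisible(out_dir)
}
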