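# Linking the heterogeneity metric to overall survival.
#
# The per-patient metric is the median of the zero-shift inter-class CCs
# (patients with lesions in only one class have no inter-class pair and are
# excluded from the CC-based survival analyses). The metric enters
# Kaplan-Meier / log-rank comparisons after dichotomization at a cutoff
# (default 0.35, "low" meaning equal-to-or-below), and Cox
# proportional-hazards models either continuous or dichotomized, alongside
# ECOG status, baseline tumor size, early tumor shrinkage and KRAS status.
# Fitter internals come from the survival package (Efron tie handling); the
# bespoke content is the metric derivation and the model specifications.

#' Per-patient median zero-shift cross-correlation
#'
#' @param cc_df Inter-class CC table ([cc_table()]).
#' @param patient_id Optional single patient id; when omitted, a named vector
#'   with one entry per patient appearing in `cc_df` is returned.
#' @return Median of the patient's defined zero-shift CCs, or `NA` when the
#'   patient has no defined inter-class pair. Even pair counts use the
#'   standard midpoint median.
#' @export
median_cc <- function(cc_df, patient_id = NULL) {
  defined <- cc_df[!is.na(cc_df$cc_zero), , drop = FALSE]
  one <- function(pid) {
    v <- defined$cc_zero[defined$patient_id == pid]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }
  if (!is.null(patient_id)) return(one(patient_id))
  pids <- unique(cc_df$patient_id)
  stats::setNames(vapply(pids, one, numeric(1)), pids)
}

#' Dichotomize the median CC
#'
#' @param median_cc Numeric vector of per-patient median CCs (may contain
#'   `NA`).
#' @param threshold Cutoff (default 0.35; 0.5 is a supported sensitivity
#'   setting). Values equal to the threshold go to the `low` group.
#' @return Factor with levels `low` (median CC <= threshold, more
#'   heterogeneity) and `high`; `NA` stays `NA`.
#' @export
dichotomize_cc <- function(median_cc, threshold = 0.35) {
  factor(ifelse(is.na(median_cc), NA_character_,
                ifelse(median_cc <= threshold, "low", "high")),
         levels = c("low", "high"))
}

#' Early tumor shrinkage (TS ratio)
#'
#' `(TS0 - TS8) / TS0`: the relative drop in total tumor size from baseline
#' to the week-8 landmark. Always <= 1, reaching 1 only when the week-8 size
#' is zero; negative values mean growth.
#'
#' @param ts0 Baseline total tumor size (must be positive).
#' @param ts8 Total tumor size at the landmark (`NA` gives `NA`).
#' @return `(ts0 - ts8) / ts0`, vectorized.
#' @export
ets <- function(ts0, ts8) {
  if (any(!is.na(ts0) & ts0 <= 0)) stop("ts0 must be positive", call. = FALSE)
  (ts0 - ts8) / ts0
}

#' Assemble the per-patient outcome table
#'
#' Joins survival outcomes and covariates with the derived heterogeneity
#' metric (median CC and its dichotomization) and the tumor-size covariates
#' (baseline total size `ts0` and early tumor shrinkage `ts_ratio8`).
#'
#' @param covariates Covariate table (see [read_covariate_table()]).
#' @param cc_df Inter-class CC table.
#' @param series_by_patient Output of [build_series()] (for the tumor-size
#'   landmarks).
#' @param threshold Dichotomization cutoff (default 0.35).
#' @param ts_landmark Landmark time in weeks for the shrinkage ratio
#'   (default 8).
#' @param tolerance Visit-matching window in weeks for the landmarks
#'   (default 2).
#' @return A `data.frame` with one row per patient in `covariates`:
#'   `patient_id`, `os_time`, `os_event`, `arm`, `kras`, `ecog`, `median_cc`,
#'   `cc_group`, `ts0`, `ts_ratio8`.
#' @export
build_outcomes <- function(covariates, cc_df, series_by_patient,
                           threshold = 0.35, ts_landmark = 8, tolerance = 2) {
  med <- median_cc(cc_df)
  ts0 <- total_ts(series_by_patient, 0, tolerance)
  ts8 <- total_ts(series_by_patient, ts_landmark, tolerance)
  pid <- as.character(covariates$patient_id)
  m <- unname(med[pid])
  t0 <- unname(ts0[pid])
  t8 <- unname(ts8[pid])
  ratio <- rep(NA_real_, length(pid))
  ok <- !is.na(t0) & t0 > 0
  ratio[ok] <- ets(t0[ok], t8[ok])
  data.frame(patient_id = pid,
             os_time = covariates$os_time,
             os_event = covariates$os_event,
             arm = covariates$arm,
             kras = covariates$kras,
             ecog = covariates$ecog,
             median_cc = m,
             cc_group = dichotomize_cc(m, threshold),
             ts0 = t0,
             ts_ratio8 = ratio,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier estimate by group
#'
#' Product-limit estimator per group with log-log (Greenwood-based)
#' confidence bands. The median is the earliest time with `S(t) <= 0.5`
#' (`NA` = not reached); its confidence interval comes from inverting the
#' confidence bands (earliest crossing of 0.5 by the lower/upper band).
#'
#' @param outcomes Outcome table ([build_outcomes()]).
#' @param group_field Name of the grouping column (default `"cc_group"`);
#'   rows with `NA` group are dropped.
#' @param risk_times Optional vector of times (weeks) for a number-at-risk
#'   table.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `groups` (per group: `curve` data frame with `time`,
#'   `n_risk`, `n_event`, `surv`, `lower`, `upper`; plus `n`, `events`,
#'   `median`, `median_lower`, `median_upper`) and `risk_table` (or `NULL`).
#' @export
km_estimate <- function(outcomes, group_field = "cc_group", risk_times = NULL,
                        conf_level = 0.95) {
  d <- outcomes[!is.na(outcomes[[group_field]]), , drop = FALSE]
  d$group <- factor(d[[group_field]])
  if (nrow(d) == 0) stop("no subjects with a defined group", call. = FALSE)
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ group, data = d,
                           conf.type = "log-log", conf.int = conf_level)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) {
    rep(levels(d$group)[1], length(sm$time))
  } else sub("^group=", "", as.character(sm$strata))

  first_crossing <- function(time, s) {
    i <- which(!is.na(s) & s <= 0.5)
    if (length(i) == 0) NA_real_ else time[min(i)]
  }
  groups <- list()
  for (g in unique(strata)) {
    sel <- strata == g
    curve <- data.frame(time = sm$time[sel], n_risk = sm$n.risk[sel],
                        n_event = sm$n.event[sel], surv = sm$surv[sel],
                        lower = sm$lower[sel], upper = sm$upper[sel])
    curve <- curve[order(curve$time), , drop = FALSE]
    groups[[g]] <- list(
      curve = curve,
      n = sum(d$group == g),
      events = sum(curve$n_event),
      median = first_crossing(curve$time, curve$surv),
      median_lower = first_crossing(curve$time, curve$lower),
      median_upper = first_crossing(curve$time, curve$upper)
    )
  }
  risk_table <- NULL
  if (!is.null(risk_times)) {
    smt <- summary(fit, times = risk_times, extend = TRUE)
    st <- if (is.null(smt$strata)) rep(names(groups)[1], length(smt$time))
          else sub("^group=", "", as.character(smt$strata))
    risk_table <- data.frame(group = st, time = smt$time, n_risk = smt$n.risk)
  }
  list(groups = groups, risk_table = risk_table)
}

#' Log-rank test between groups
#'
#' Standard (unweighted) log-rank: observed minus expected events under the
#' pooled-risk-set null with hypergeometric variance, chi-square reference
#' with (groups - 1) degrees of freedom.
#'
#' @inheritParams km_estimate
#' @return A list with `statistic`, `df`, `p_value`, and per-group `observed`
#'   / `expected` event counts.
#' @export
logrank_test <- function(outcomes, group_field = "cc_group") {
  d <- outcomes[!is.na(outcomes[[group_field]]), , drop = FALSE]
  d$group <- factor(as.character(d[[group_field]]))
  if (nlevels(d$group) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(os_time, os_event) ~ group, data = d)
  df <- length(sd_$n) - 1
  list(statistic = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       observed = sd_$obs, expected = sd_$exp)
}

# numeric design columns derived from the outcome table
prepare_cox_data <- function(outcomes, threshold = 0.35) {
  data.frame(
    os_time = outcomes$os_time,
    os_event = outcomes$os_event,
    ecog = ifelse(outcomes$ecog == "missing", NA_real_,
                  as.numeric(outcomes$ecog == "not_fully_active")),
    kras = ifelse(outcomes$kras == "missing", NA_real_,
                  as.numeric(outcomes$kras == "mut")),
    ts0 = outcomes$ts0,
    ts_ratio8 = outcomes$ts_ratio8,
    median_cc = outcomes$median_cc,
    cc_low = as.numeric(dichotomize_cc(outcomes$median_cc, threshold) == "low")
  )
}

#' Multivariate Cox proportional-hazards model
#'
#' Partial-likelihood fit (Efron tie handling) of overall survival on the
#' requested terms. Available terms: `ecog` (1 = not fully active), `ts0`
#' (continuous baseline total size), `ts_ratio8` (continuous early tumor
#' shrinkage), `kras` (1 = mutated), `median_cc` (continuous) or `cc_low`
#' (1 = median CC at or below the cutoff). `interaction = TRUE` adds
#' `kras x median_cc` (or `kras x cc_low`). Subjects with a missing value in
#' any included term are excluded, which reproduces the reduced analysis set
#' induced by requiring an available median CC.
#'
#' @param outcomes Outcome table ([build_outcomes()]).
#' @param terms Character vector of term names (see above).
#' @param interaction Add the KRAS-by-CC interaction term.
#' @param threshold Cutoff used to derive `cc_low`.
#' @return A list with `table` (term, coef, hr, ci bounds, se, p), `n`,
#'   `events`, `flagged` (possible separation / non-convergence messages) and
#'   `fit` (the underlying `coxph` object).
#' @export
cox_fit <- function(outcomes, terms = c("ecog", "ts0", "ts_ratio8", "kras",
                                        "median_cc"),
                    interaction = FALSE, threshold = 0.35) {
  dat <- prepare_cox_data(outcomes, threshold)
  allowed <- setdiff(names(dat), c("os_time", "os_event"))
  bad <- setdiff(terms, allowed)
  if (length(bad) > 0) {
    stop("unknown term(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  rhs <- terms
  if (interaction) {
    cc_term <- intersect(c("median_cc", "cc_low"), terms)
    if (length(cc_term) == 0) stop("interaction requires median_cc or cc_low among terms",
                                   call. = FALSE)
    if (!("kras" %in% terms)) stop("interaction requires kras among terms",
                                   call. = FALSE)
    rhs <- c(rhs, paste0("kras:", cc_term[1]))
  }
  used <- unique(c("os_time", "os_event", terms))
  dat <- dat[stats::complete.cases(dat[used]), , drop = FALSE]
  fml <- stats::as.formula(paste("survival::Surv(os_time, os_event) ~",
                                 paste(rhs, collapse = " + ")))
  flagged <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      flagged <<- c(flagged, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(is.na(stats::coef(fit)))) {
    stop("Cox model did not converge (NA coefficient); diagnostics: ",
         paste(flagged, collapse = "; "), call. = FALSE)
  }
  s <- summary(fit)
  ct <- s$coefficients
  ci <- s$conf.int
  table <- data.frame(term = rownames(ct),
                      coef = ct[, "coef"],
                      hr = ct[, "exp(coef)"],
                      hr_lower = ci[, 3],
                      hr_upper = ci[, 4],
                      se = ct[, "se(coef)"],
                      p = ct[, "Pr(>|z|)"],
                      stringsAsFactors = FALSE)
  rownames(table) <- NULL
  list(table = table, n = s$n, events = s$nevent, flagged = flagged, fit = fit)
}
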