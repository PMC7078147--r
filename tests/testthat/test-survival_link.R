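cc_row <- function(pid, cc) {
  data.frame(patient_id = pid, id_a = "Liver", id_b = "Lung", cc_zero = cc,
             cc_max = cc, best_lag = 0L, n_overlap = 4L,
             computable = !is.na(cc), analysis = "inter-class",
             stringsAsFactors = FALSE)
}

test_that("median CC takes the median of a patient's defined zero-shift CCs", {
  cc <- rbind(cc_row("P1", 0.9), cc_row("P1", 0.8), cc_row("P1", -0.2),
              cc_row("P2", 0.4), cc_row("P3", NA))
  expect_equal(median_cc(cc, "P1"), 0.8)
  expect_equal(median_cc(cc, "P2"), 0.4)
  expect_true(is.na(median_cc(cc, "P3")))   # no defined pair -> missing
  all_ <- median_cc(cc)
  expect_equal(unname(all_[c("P1", "P2")]), c(0.8, 0.4))
  # even pair count: midpoint of the two central values
  cc4 <- rbind(cc_row("P4", 0.1), cc_row("P4", 0.5))
  expect_equal(median_cc(cc4, "P4"), 0.3)
})

test_that("dichotomization puts the threshold itself in the low group", {
  expect_equal(as.character(dichotomize_cc(c(0.35, 0.36, -1, NA))),
               c("low", "high", "low", NA))
  expect_equal(as.character(dichotomize_cc(0.5, threshold = 0.5)), "low")
})

test_that("early tumor shrinkage is the relative drop from baseline", {
  expect_equal(ets(100, 70), 0.3)
  expect_equal(ets(80, 80), 0)
  expect_equal(ets(60, 0), 1)
  expect_equal(ets(50, 60), -0.2)
  expect_true(is.na(ets(100, NA)))
  expect_error(ets(0, 10), "positive")
})

test_that("product-limit estimator matches hand computation", {
  # 6 subjects: deaths at 6, 10, 15, 25; censored at 7 and 19
  out <- data.frame(patient_id = paste0("S", 1:6),
                    os_time = c(6, 7, 10, 15, 19, 25),
                    os_event = c(1L, 0L, 1L, 1L, 0L, 1L),
                    grp = "all", stringsAsFactors = FALSE)
  km <- km_estimate(out, group_field = "grp")
  g <- km$groups$all
  ev <- g$curve[g$curve$n_event > 0, ]
  # hand-derived: 5/6, then 5/6 * 3/4, * 2/3, * 0
  expect_equal(ev$surv, c(5/6, 5/8, 5/12, 0))
  expect_equal(g$median, 15)   # earliest time with S <= 0.5
  expect_equal(g$events, 4)

  oracle <- oracle_km(out$os_time, out$os_event)
  expect_equal(ev$surv, oracle$surv)

  # no censoring: the estimator is the empirical survival function
  out2 <- data.frame(patient_id = paste0("T", 1:10), os_time = 1:10,
                     os_event = 1L, grp = "all", stringsAsFactors = FALSE)
  g2 <- km_estimate(out2, group_field = "grp")$groups$all
  expect_equal(g2$curve$surv, (9:0) / 10)
  expect_equal(g2$median, 5)   # S(5) = 0.5, the earliest crossing

  # single subject with an event; then an all-censored group
  out3 <- data.frame(patient_id = "U1", os_time = 3, os_event = 1L,
                     grp = "all", stringsAsFactors = FALSE)
  g3 <- km_estimate(out3, group_field = "grp")$groups$all
  expect_equal(g3$curve$surv, 0)
  expect_equal(g3$median, 3)
  out4 <- data.frame(patient_id = c("V1", "V2"), os_time = c(5, 9),
                     os_event = 0L, grp = "all", stringsAsFactors = FALSE)
  g4 <- km_estimate(out4, group_field = "grp")$groups$all
  expect_true(all(g4$curve$surv == 1))
  expect_true(is.na(g4$median))   # median not reached
})

test_that("survival curves start at 1, never increase, and risk tables count", {
  sim <- simulate_trial(sim_config(n_patients = 120, seed = 13))
  out <- data.frame(patient_id = sim$covariates$patient_id,
                    os_time = sim$covariates$os_time,
                    os_event = sim$covariates$os_event,
                    grp = rep(c("a", "b"), length.out = 120),
                    stringsAsFactors = FALSE)
  km <- km_estimate(out, group_field = "grp", risk_times = c(0, 50, 100))
  for (g in km$groups) {
    expect_true(all(g$curve$surv <= 1))
    expect_true(all(diff(g$curve$surv) <= 1e-12))
  }
  r0 <- km$risk_table[km$risk_table$time == 0, ]
  expect_equal(sum(r0$n_risk), 120)
})

test_that("log-rank matches the explicit risk-set oracle and its invariances", {
  out <- data.frame(patient_id = paste0("S", 1:6),
                    os_time = c(6, 10, 19, 7, 15, 25),
                    os_event = c(1L, 1L, 0L, 0L, 1L, 1L),
                    grp = rep(c("A", "B"), each = 3), stringsAsFactors = FALSE)
  lr <- logrank_test(out, group_field = "grp")
  want <- oracle_logrank(out$os_time, out$os_event, out$grp)
  # hand tabulation: O_A = 2, E_A = 4/3, V = 13/18, chi2 = (2/3)^2/(13/18)
  expect_equal(want$observed, 2)
  expect_equal(want$expected, 4/3)
  expect_equal(want$variance, 13/18)
  expect_equal(lr$statistic, want$statistic)
  expect_equal(lr$statistic, (2/3)^2 / (13/18))
  expect_equal(lr$df, 1)
  expect_equal(lr$p_value, pchisq(8/13, 1, lower.tail = FALSE))

  # relabeling groups leaves the statistic unchanged
  out2 <- out
  out2$grp <- ifelse(out$grp == "A", "B", "A")
  expect_equal(logrank_test(out2, group_field = "grp")$statistic, lr$statistic)

  # two identical groups: statistic 0, p = 1
  dup <- rbind(transform(out, grp = "A"), transform(out, grp = "B"))
  lr0 <- logrank_test(dup, group_field = "grp")
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  expect_error(logrank_test(transform(out, grp = "A"), group_field = "grp"),
               "2 non-empty groups")
})

test_that("log-rank detects a strong hazard ratio in simulated two-arm data", {
  set.seed(2024)
  sig <- 0
  for (r in 1:10) {
    n <- 200
    t1 <- rexp(n, 1 / 80)
    t2 <- rexp(n, 3 / 80)     # hazard ratio 3
    cens <- runif(2 * n, 40, 160)
    out <- data.frame(patient_id = seq_len(2 * n),
                      os_time = pmin(c(t1, t2), cens),
                      os_event = as.integer(c(t1, t2) <= cens),
                      grp = rep(c("ref", "haz"), each = n),
                      stringsAsFactors = FALSE)
    sig <- sig + (logrank_test(out, group_field = "grp")$p_value < 0.05)
  }
  expect_equal(sig, 10)
})

test_that("Cox partial likelihood matches closed-form toy maxima", {
  base <- function(n) data.frame(
    patient_id = paste0("S", 1:n), arm = "cetuximab", kras = "wt",
    ecog = "fully_active", ts0 = 50, ts_ratio8 = 0.1, cc_group = NA,
    stringsAsFactors = FALSE)

  # two subjects tied at t = 1 with x = (1, 0): Efron maximum is beta = 0
  out <- cbind(base(2), os_time = c(1, 1), os_event = 1L,
               median_cc = c(1, 0))
  fit <- cox_fit(out, terms = "median_cc")
  expect_equal(fit$table$coef, 0, tolerance = 1e-8)

  # three subjects, events at 1 < 2 < 3 with x = (1, 0, 1):
  # dlogL/db = 0  at  e^(2b) = 1/2
  out3 <- cbind(base(3), os_time = c(1, 2, 3), os_event = 1L,
                median_cc = c(1, 0, 1))
  fit3 <- cox_fit(out3, terms = "median_cc")
  expect_equal(fit3$table$coef, -log(2) / 2, tolerance = 1e-6)
})

test_that("Cox recovers a known hazard ratio on clean simulated data", {
  set.seed(77)
  n <- 800
  x <- rnorm(n)
  beta <- log(0.74)
  t <- rexp(n, exp(beta * x) / 100)
  cens <- runif(n, 50, 300)
  out <- data.frame(patient_id = seq_len(n), os_time = pmin(t, cens),
                    os_event = as.integer(t <= cens), arm = "cetuximab",
                    kras = "wt", ecog = "fully_active", ts0 = 50,
                    ts_ratio8 = 0.1, median_cc = x, cc_group = NA,
                    stringsAsFactors = FALSE)
  fit <- cox_fit(out, terms = "median_cc")
  row <- fit$table[fit$table$term == "median_cc", ]
  expect_lt(abs(row$coef - beta), 3 * row$se)
  expect_equal(row$hr, exp(row$coef))
  expect_true(row$hr_lower < row$hr && row$hr < row$hr_upper)
})

test_that("model specification supports the binary metric and the interaction", {
  sim <- simulate_trial(sim_config(n_patients = 250, seed = 5))
  pre <- preprocess_lesions(validate_lesion_records(sim$records),
                            sim$covariates)
  series <- build_series(pre$records)
  cls <- merge_rare_classes(classify_lesions(lesion_metadata(pre$records)))$classified
  cc <- cc_table(interclass_pairs(series, cls, max_lag = 0))
  out <- build_outcomes(sim$covariates, cc, series)

  fit_bin <- cox_fit(out, terms = c("ecog", "ts0", "ts_ratio8", "kras",
                                    "cc_low"))
  expect_true("cc_low" %in% fit_bin$table$term)
  fit_int <- cox_fit(out, terms = c("ecog", "ts0", "ts_ratio8", "kras",
                                    "median_cc"), interaction = TRUE)
  expect_true("kras:median_cc" %in% fit_int$table$term)
  # subjects without a median CC are excluded from the reduced analysis set
  expect_equal(fit_int$n, sum(!is.na(out$median_cc) & out$kras != "missing" &
                                out$ecog != "missing" & !is.na(out$ts_ratio8) &
                                !is.na(out$ts0)))
  expect_error(cox_fit(out, terms = "nonsense"), "unknown term")
  expect_error(cox_fit(out, terms = "median_cc", interaction = TRUE),
               "requires kras")
})

test_that("outcome assembly derives the metric, groups and size covariates", {
  fx <- make_fixture("two_lesion_mirror")
  pre <- preprocess_lesions(validate_lesion_records(fx$records),
                            fx$covariates)
  series <- build_series(pre$records)
  cls <- classify_lesions(lesion_metadata(pre$records))
  # both lesions are liver: no inter-class pair, median CC missing
  cc <- cc_table(interclass_pairs(series, cls))
  out <- build_outcomes(fx$covariates, cc, series)
  expect_true(is.na(out$median_cc))
  expect_equal(out$ts0, 60)        # 50 + 10 at baseline
  expect_equal(out$ts_ratio8, 0)   # 40 + 20 at week 8

  # force an inter-class comparison: mirrored pair gives median CC -1
  cls2 <- cls
  cls2$class_name <- c("Liver", "Lung")
  cc2 <- cc_table(interclass_pairs(series, cls2))
  out2 <- build_outcomes(fx$covariates, cc2, series)
  expect_equal(out2$median_cc, -1)
  expect_equal(as.character(out2$cc_group), "low")
})
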