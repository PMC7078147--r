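# Synthetic multi-lesion mCRC-like trial generator.
#
# Emulates the structure of a metastatic colorectal cancer trial dataset:
# 1-10 target lesions per patient (at most 5 per organ), free-text organ
# locations, a baseline + periodic assessment schedule, KRAS/ECOG covariates,
# and censored overall survival whose hazard depends on the TRUE (noise-free)
# concordance of the patient's organ-class dynamics. Lesion trajectories
# follow the biexponential shrink-regrow form
#   TS(t) = B * (exp(-k_s t) + exp(k_g t) - 1),
# standard in tumor-size modeling; heterogeneity is injected by switching
# whole organ classes to growth-dominant parameters (probability `p_div`) and
# by delaying a class's response by a whole number of visits (`lag_prob`).
# A truth log records every latent quantity for recovery tests.

ORGAN_TEXT_POOL <- list(
  "Liver" = c("LIVER RIGHT LOBE", "Liver, left lobe", "hepatic segment IVb",
              "liver dome"),
  "Lung" = c("RIGHT LUNG UPPER LOBE", "left lung base", "pulmonary nodule LLL"),
  "Lymph node" = c("para-aortic lymph node", "mesenteric lymph node",
                   "iliac adenopathy", "retroperitoneal node"),
  "Other digestive organs" = c("peritoneum", "splenic lesion", "gastric wall",
                               "omental deposit"),
  "Other specified organs" = c("adrenal gland", "left kidney", "pelvic mass")
)
PRIMARY_TEXT_POOL <- c("sigmoid colon", "rectum", "ascending colon")

#' Simulation configuration
#'
#' Assembles and validates the generator settings. Defaults describe a
#' plausible single-arm (cetuximab) mCRC trial: assessments every 8 weeks to
#' week 48, liver-dominant organ involvement, lesions shrinking under
#' treatment (`k_s` = 0.05/week against regrowth `k_g` = 0.005/week) with
#' occasional growth-dominant (divergent) organ classes, KRAS-mutation
#' attenuated response, and a Weibull baseline hazard giving a median
#' survival near 70 weeks when all effects are at reference.
#'
#' @param n_patients Number of patients.
#' @param schedule Assessment times in weeks, strictly increasing, starting
#'   at baseline 0.
#' @param metric `"SLD"` (mm, longest diameters) or `"SOPD"` (mm^2, the
#'   latent diameters are squared before noise and rounding).
#' @param organ_weights Named sampling weights for the organ classes.
#' @param class_count_probs Probabilities of a patient involving 1, 2, 3, ...
#'   organ classes.
#' @param lesion_count_probs Probabilities of 1..5 lesions within one organ.
#' @param p_primary Probability of an additional primary (non-metastatic)
#'   lesion.
#' @param p_missing_organ Probability a lesion's location text is missing.
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the
#'   baseline longest diameter (mm).
#' @param k_s,k_g Shrinkage and regrowth rates (1/week) of responding
#'   classes.
#' @param k_s_div,k_g_div Rates of divergent (growth-dominant) classes.
#' @param par_cv Lognormal coefficient of variation applied to the rates at
#'   the class and at the lesion level.
#' @param noise_sd Lognormal sd of the multiplicative observation noise.
#' @param p_div Probability that an organ class follows divergent dynamics.
#' @param lag_prob Probability that a class's response is delayed.
#' @param lag_magnitude Delay, in whole visits, of a delayed class.
#' @param p_kras_mut,p_kras_missing KRAS status probabilities.
#' @param kras_ks_factor Multiplier on `k_s` for KRAS-mutated patients.
#' @param p_ecog_bad,p_ecog_missing ECOG status probabilities (bad = not
#'   fully active).
#' @param p_cetuximab Probability of the cetuximab arm (default 1: a pooled
#'   cetuximab analysis population).
#' @param control_ks_factor Multiplier on `k_s` for control-arm patients.
#' @param p_miss_visit Probability a scheduled post-baseline visit is missed
#'   (whole-patient scan missed).
#' @param p_baseline_only Probability a patient has no usable follow-up scan
#'   (exercises the baseline-only exclusion).
#' @param p_surgery Probability of a tumor surgery during follow-up.
#' @param weib_shape,weib_scale Weibull baseline hazard parameters (scale in
#'   weeks).
#' @param beta_cc Log hazard ratio per unit of the true median class
#'   concordance (default `log(0.74)`: higher concordance, i.e. less
#'   heterogeneity, lowers risk).
#' @param beta_ets,beta_ecog,beta_ts0 Log hazard ratios for true early tumor
#'   shrinkage (per unit), ECOG not fully active, and baseline size (per mm,
#'   centered at 60 mm).
#' @param cens_rate Rate (1/weeks) of the exponential random-censoring
#'   process.
#' @param horizon_os Administrative censoring time (weeks).
#' @param seed Global seed; per-patient substreams are derived from it so
#'   patient i's data do not change when `n_patients` changes.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500,
                       schedule = seq(0, 48, by = 8),
                       metric = "SLD",
                       organ_weights = c("Liver" = 0.55, "Lung" = 0.16,
                                         "Lymph node" = 0.16,
                                         "Other digestive organs" = 0.08,
                                         "Other specified organs" = 0.05),
                       class_count_probs = c(0.45, 0.40, 0.15),
                       lesion_count_probs = c(0.45, 0.30, 0.15, 0.07, 0.03),
                       p_primary = 0.08,
                       p_missing_organ = 0.02,
                       baseline_meanlog = log(25), baseline_sdlog = 0.45,
                       k_s = 0.05, k_g = 0.005,
                       k_s_div = 0.005, k_g_div = 0.02,
                       par_cv = 0.15,
                       noise_sd = 0.05,
                       p_div = 0.35,
                       lag_prob = 0.15, lag_magnitude = 1,
                       p_kras_mut = 0.40, p_kras_missing = 0.03,
                       kras_ks_factor = 0.5,
                       p_ecog_bad = 0.25, p_ecog_missing = 0.02,
                       p_cetuximab = 1.0, control_ks_factor = 0.5,
                       p_miss_visit = 0.05,
                       p_baseline_only = 0.02,
                       p_surgery = 0.04,
                       weib_shape = 1.2, weib_scale = 95,
                       beta_cc = log(0.74),
                       beta_ets = log(0.5), beta_ecog = log(1.6),
                       beta_ts0 = 0.004,
                       cens_rate = 1 / 400, horizon_os = 160,
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(p_primary, p_missing_organ, p_div, lag_prob, p_kras_mut,
             p_kras_missing, p_ecog_bad, p_ecog_missing, p_cetuximab,
             p_miss_visit, p_baseline_only, p_surgery)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(k_s, k_g, k_s_div, k_g_div, par_cv, noise_sd, cens_rate) < 0)) {
    stop("rates and dispersions must be non-negative", call. = FALSE)
  }
  if (length(schedule) < 2 || any(diff(schedule) <= 0) || schedule[1] != 0) {
    stop("schedule must start at 0 and be strictly increasing", call. = FALSE)
  }
  if (!metric %in% c("SLD", "SOPD")) stop("metric must be SLD or SOPD", call. = FALSE)
  if (n_patients < 1) stop("n_patients must be positive", call. = FALSE)
  if (lag_magnitude < 0 || lag_magnitude != round(lag_magnitude)) {
    stop("lag_magnitude must be a non-negative integer", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# latent biexponential trajectory, response delayed by `delay` weeks
biexp_ts <- function(t, B, ks, kg, delay = 0) {
  te <- pmax(0, t - delay)
  B * (exp(-ks * te) + exp(kg * te) - 1)
}

#' Simulate a multi-lesion trial
#'
#' @param config A [sim_config()].
#' @return A list with `records` (long-format lesion table with the canonical
#'   columns), `covariates` (one row per patient) and `truth`, the latent-
#'   parameter log: `truth$classes` (one row per patient x organ class:
#'   divergent flag, delay, rates, true class-sum trajectory summaries),
#'   `truth$patients` (true median class concordance `true_median_cc`, true
#'   baseline size and early shrinkage, linear predictor, event time) and
#'   `truth$config`.
#' @export
simulate_trial <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n_visits <- length(cf$schedule)
  interval <- cf$schedule[2] - cf$schedule[1]

  rec <- list(patient_id = list(), lesion_id = list(), organ_text = list(),
              lesion_type = list(), time = list(), size = list())
  np <- cf$n_patients
  cov <- list(patient_id = character(np), arm = character(np),
              kras = character(np), ecog = character(np),
              surgery_time = numeric(np), os_time = numeric(np),
              os_event = integer(np))
  truth_cls <- list(patient_id = list(), class_name = list(),
                    divergent = list(), delay_visits = list(), k_s = list(),
                    k_g = list(), n_lesions = list(), n_obs_visits = list())
  truth_pat <- list(n_classes = integer(np), true_median_cc = numeric(np),
                    ts0_true = numeric(np), ets_true = numeric(np),
                    lp = numeric(np), t_event = numeric(np))

  for (i in seq_len(cf$n_patients)) {
    pid <- sprintf("P%04d", i)
    set.seed((cf$seed * 1000003 + i) %% 2147483647L)

    # covariates
    arm <- if (stats::runif(1) < cf$p_cetuximab) "cetuximab" else "control"
    u <- stats::runif(1)
    kras <- if (u < cf$p_kras_missing) "missing"
            else if (u < cf$p_kras_missing + cf$p_kras_mut) "mut" else "wt"
    u <- stats::runif(1)
    ecog <- if (u < cf$p_ecog_missing) "missing"
            else if (u < cf$p_ecog_missing + cf$p_ecog_bad) "not_fully_active"
            else "fully_active"

    # organ involvement
    n_classes <- sample.int(length(cf$class_count_probs), 1,
                            prob = cf$class_count_probs)
    classes <- sample(names(cf$organ_weights), n_classes,
                      prob = cf$organ_weights)
    has_primary <- stats::runif(1) < cf$p_primary

    # patient-level response attenuation
    ks_pat <- cf$k_s
    if (kras == "mut") ks_pat <- ks_pat * cf$kras_ks_factor
    if (arm == "control") ks_pat <- ks_pat * cf$control_ks_factor

    # observed visit pattern (whole-patient scans)
    if (stats::runif(1) < cf$p_baseline_only) {
      obs_visits <- 1L
    } else {
      miss <- stats::runif(n_visits - 1) < cf$p_miss_visit
      obs_visits <- c(1L, which(!miss) + 1L)
    }
    surgery_time <- NA_real_
    if (stats::runif(1) < cf$p_surgery && n_visits > 3) {
      surgery_time <- cf$schedule[sample(2:(n_visits - 1), 1)] + interval / 4
    }

    # class-level dynamics
    lesion_counter <- 0L
    total_lesions <- 0L
    class_sum_traj <- list()   # noise-free class-sum on the full schedule
    for (cl in classes) {
      divergent <- stats::runif(1) < cf$p_div
      delayed <- stats::runif(1) < cf$lag_prob
      delay_wk <- if (delayed) cf$lag_magnitude * interval else 0
      if (divergent) {
        ks_cl <- cf$k_s_div * exp(stats::rnorm(1, 0, cf$par_cv))
        kg_cl <- cf$k_g_div * exp(stats::rnorm(1, 0, cf$par_cv))
      } else {
        ks_cl <- ks_pat * exp(stats::rnorm(1, 0, cf$par_cv))
        kg_cl <- cf$k_g * exp(stats::rnorm(1, 0, cf$par_cv))
      }
      n_les <- sample.int(5, 1, prob = cf$lesion_count_probs)
      n_les <- min(n_les, 10L - total_lesions - as.integer(has_primary))
      if (n_les < 1) next
      total_lesions <- total_lesions + n_les

      cls_traj <- numeric(n_visits)
      for (l in seq_len(n_les)) {
        lesion_counter <- lesion_counter + 1L
        B <- min(max(stats::rlnorm(1, cf$baseline_meanlog, cf$baseline_sdlog), 8), 120)
        ks_l <- ks_cl * exp(stats::rnorm(1, 0, cf$par_cv))
        kg_l <- kg_cl * exp(stats::rnorm(1, 0, cf$par_cv))
        latent <- biexp_ts(cf$schedule, B, ks_l, kg_l, delay_wk)
        cls_traj <- cls_traj + latent
        noise <- exp(stats::rnorm(n_visits, 0, cf$noise_sd))
        obs <- latent[obs_visits] * noise[obs_visits]
        if (cf$metric == "SOPD") obs <- obs^2
        obs <- pmax(round(obs), 0)
        organ <- if (stats::runif(1) < cf$p_missing_organ) "" else
          sample(ORGAN_TEXT_POOL[[cl]], 1)
        k <- length(rec$patient_id) + 1L
        rec$patient_id[[k]] <- rep(pid, length(obs_visits))
        rec$lesion_id[[k]] <- rep(sprintf("L%02d", lesion_counter), length(obs_visits))
        rec$organ_text[[k]] <- rep(organ, length(obs_visits))
        rec$lesion_type[[k]] <- rep(if (cl == "Lymph node") "node" else "metastatic",
                                    length(obs_visits))
        rec$time[[k]] <- cf$schedule[obs_visits]
        rec$size[[k]] <- obs
      }
      class_sum_traj[[cl]] <- cls_traj
      j <- length(truth_cls$patient_id) + 1L
      truth_cls$patient_id[[j]] <- pid
      truth_cls$class_name[[j]] <- cl
      truth_cls$divergent[[j]] <- divergent
      truth_cls$delay_visits[[j]] <- if (delayed) cf$lag_magnitude else 0L
      truth_cls$k_s[[j]] <- ks_cl
      truth_cls$k_g[[j]] <- kg_cl
      truth_cls$n_lesions[[j]] <- n_les
      truth_cls$n_obs_visits[[j]] <- length(obs_visits)
    }

    if (has_primary && total_lesions < 10L) {
      lesion_counter <- lesion_counter + 1L
      total_lesions <- total_lesions + 1L
      B <- min(max(stats::rlnorm(1, cf$baseline_meanlog, cf$baseline_sdlog), 8), 120)
      latent <- biexp_ts(cf$schedule, B, ks_pat, cf$k_g, 0)
      noise <- exp(stats::rnorm(n_visits, 0, cf$noise_sd))
      obs <- latent[obs_visits] * noise[obs_visits]
      if (cf$metric == "SOPD") obs <- obs^2
      obs <- pmax(round(obs), 0)
      k <- length(rec$patient_id) + 1L
      rec$patient_id[[k]] <- rep(pid, length(obs_visits))
      rec$lesion_id[[k]] <- rep(sprintf("L%02d", lesion_counter), length(obs_visits))
      rec$organ_text[[k]] <- rep(sample(PRIMARY_TEXT_POOL, 1), length(obs_visits))
      rec$lesion_type[[k]] <- rep("primary", length(obs_visits))
      rec$time[[k]] <- cf$schedule[obs_visits]
      rec$size[[k]] <- obs
    }

    # true class concordance: median pairwise zero-shift CC of the
    # noise-free class-sum trajectories on the full schedule
    true_mcc <- NA_real_
    if (length(class_sum_traj) >= 2) {
      ccs <- c()
      nm <- names(class_sum_traj)
      for (a in seq_len(length(nm) - 1)) {
        for (b in seq.int(a + 1, length(nm))) {
          ccs <- c(ccs, cc_at_lag(class_sum_traj[[nm[a]]],
                                  class_sum_traj[[nm[b]]], 0L))
        }
      }
      ccs <- ccs[!is.na(ccs)]
      if (length(ccs) > 0) true_mcc <- stats::median(ccs)
    }
    total_traj <- Reduce(`+`, class_sum_traj, accumulate = FALSE)
    if (is.null(total_traj)) total_traj <- numeric(n_visits)
    ts0_true <- total_traj[1]
    i8 <- which.min(abs(cf$schedule - 8))
    ets_true <- if (ts0_true > 0) (ts0_true - total_traj[i8]) / ts0_true else 0

    lp <- cf$beta_cc * (if (is.na(true_mcc)) 0 else true_mcc) +
      cf$beta_ets * (ets_true - 0.2) +
      cf$beta_ecog * as.numeric(ecog == "not_fully_active") +
      cf$beta_ts0 * (ts0_true - 60)
    # survival and censoring draw from their own per-patient substream, so
    # the outcome noise is independent of the trajectory noise by
    # construction (the position of a draw within the lesion stream depends
    # on the sampled lesion structure)
    set.seed((cf$seed * 1000003 + i + 1013904223) %% 2147483647L)
    t_event <- cf$weib_scale * (-log(stats::runif(1)) * exp(-lp))^(1 / cf$weib_shape)
    t_cens <- min(stats::rexp(1, cf$cens_rate), cf$horizon_os)
    os_time <- round(min(t_event, t_cens), 1)
    os_time <- max(os_time, 0.1)
    os_event <- as.integer(t_event <= t_cens)

    cov$patient_id[i] <- pid
    cov$arm[i] <- arm
    cov$kras[i] <- kras
    cov$ecog[i] <- ecog
    cov$surgery_time[i] <- surgery_time
    cov$os_time[i] <- os_time
    cov$os_event[i] <- os_event
    truth_pat$n_classes[i] <- length(class_sum_traj)
    truth_pat$true_median_cc[i] <- true_mcc
    truth_pat$ts0_true[i] <- ts0_true
    truth_pat$ets_true[i] <- ets_true
    truth_pat$lp[i] <- lp
    truth_pat$t_event[i] <- t_event
  }

  records <- data.frame(
    patient_id = unlist(rec$patient_id), lesion_id = unlist(rec$lesion_id),
    organ_text = unlist(rec$organ_text), lesion_type = unlist(rec$lesion_type),
    time = unlist(rec$time), size = unlist(rec$size),
    metric = cf$metric, stringsAsFactors = FALSE)
  classes_df <- data.frame(
    patient_id = unlist(truth_cls$patient_id),
    class_name = unlist(truth_cls$class_name),
    divergent = unlist(truth_cls$divergent),
    delay_visits = unlist(truth_cls$delay_visits),
    k_s = unlist(truth_cls$k_s), k_g = unlist(truth_cls$k_g),
    n_lesions = unlist(truth_cls$n_lesions),
    n_obs_visits = unlist(truth_cls$n_obs_visits),
    stringsAsFactors = FALSE)
  patients_df <- data.frame(patient_id = cov$patient_id,
                            n_classes = truth_pat$n_classes,
                            true_median_cc = truth_pat$true_median_cc,
                            ts0_true = truth_pat$ts0_true,
                            ets_true = truth_pat$ets_true,
                            lp = truth_pat$lp, t_event = truth_pat$t_event,
                            stringsAsFactors = FALSE)
  list(records = records,
       covariates = as.data.frame(cov, stringsAsFactors = FALSE),
       truth = list(classes = classes_df, patients = patients_df,
                    config = cf))
}

#' Realized divergent-pair fraction from the truth log
#'
#' Among patients with at least two simulated organ classes and at least two
#' observed visits, the fraction of unordered class pairs where exactly one
#' class follows divergent (growth-dominant) dynamics — the pairs whose
#' zero-shift CC the pipeline should place in the lowest cluster.
#'
#' @param truth The `truth` element of [simulate_trial()] output.
#' @return A single fraction in `[0, 1]` (`NaN` when no eligible pair
#'   exists).
#' @export
divergent_pair_fraction <- function(truth) {
  cl <- truth$classes[truth$classes$n_obs_visits >= 2, , drop = FALSE]
  n_pair <- 0L
  n_div <- 0L
  for (pid in unique(cl$patient_id)) {
    div <- cl$divergent[cl$patient_id == pid]
    m <- length(div)
    if (m < 2) next
    for (a in seq_len(m - 1)) {
      for (b in seq.int(a + 1, m)) {
        n_pair <- n_pair + 1L
        if (xor(div[a], div[b])) n_div <- n_div + 1L
      }
    }
  }
  n_div / n_pair
}

#' Canned hand-verifiable fixtures
#'
#' Tiny deterministic datasets used throughout the unit tests:
#' * `"two_lesion_mirror"` — one patient, two liver lesions whose sizes
#'   mirror each other (`y = c - x`), so their zero-shift CC is exactly -1.
#' * `"delayed_lung"` — one patient with a liver and a lung lesion where the
#'   lung series is the liver series shifted by one visit, so the maximum CC
#'   is exactly 1 at `|lag| = 1` while the zero-shift CC is below 1.
#' * `"three_mode_cc"` — a numeric CC sample with three modes near -0.9,
#'   0.15 and 0.9 (sd 0.05, 300 values per mode, clamped to `[-1, 1]`), the
#'   canonical elbow-selection input.
#'
#' @param name Fixture name.
#' @param seed Seed for the stochastic fixture (`"three_mode_cc"`).
#' @return For the record fixtures, a list with `records` and `covariates`;
#'   for `"three_mode_cc"`, a numeric vector.
#' @export
make_fixture <- function(name, seed = 1) {
  fixtures <- c("two_lesion_mirror", "delayed_lung", "three_mode_cc")
  if (!name %in% fixtures) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  }
  cov1 <- data.frame(patient_id = "P1", arm = "cetuximab", kras = "wt",
                     ecog = "fully_active", surgery_time = NA_real_,
                     os_time = 100, os_event = 1L, stringsAsFactors = FALSE)
  if (name == "two_lesion_mirror") {
    times <- c(0, 8, 16, 24)
    x <- c(50, 40, 30, 20)
    y <- 60 - x
    records <- data.frame(
      patient_id = "P1",
      lesion_id = rep(c("L01", "L02"), each = 4),
      organ_text = rep(c("LIVER right lobe", "liver left lobe"), each = 4),
      lesion_type = "metastatic",
      time = rep(times, 2), size = c(x, y), metric = "SLD",
      stringsAsFactors = FALSE)
    return(list(records = records, covariates = cov1))
  }
  if (name == "delayed_lung") {
    times <- seq(0, 40, by = 8)
    liver <- c(50, 40, 30, 25, 22, 21)
    lung <- c(48, liver[1:5])   # liver shifted one visit later
    records <- data.frame(
      patient_id = "P1",
      lesion_id = rep(c("L01", "L02"), each = 6),
      organ_text = rep(c("liver segment II", "right lung"), each = 6),
      lesion_type = "metastatic",
      time = rep(times, 2), size = c(liver, lung), metric = "SLD",
      stringsAsFactors = FALSE)
    return(list(records = records, covariates = cov1))
  }
  # three_mode_cc
  with_local_seed(seed, {
    v <- c(stats::rnorm(300, -0.9, 0.05), stats::rnorm(300, 0.15, 0.05),
           stats::rnorm(300, 0.9, 0.05))
    pmin(pmax(v, -1), 1)
  })
}
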