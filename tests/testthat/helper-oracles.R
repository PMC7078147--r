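# Independent oracles, written with explicit loops and first-principles
# formulas so they share no code path with the package implementation.

# Pearson correlation of x[i] vs y[i+lag] over the overlapping indices.
oracle_cc <- function(x, y, lag) {
  n <- length(x)
  xs <- c()
  ys <- c()
  for (i in seq_len(n)) {
    j <- i + lag
    if (j >= 1 && j <= n) {
      xs <- c(xs, x[i])
      ys <- c(ys, y[j])
    }
  }
  if (length(xs) < 2) return(NA_real_)
  mx <- sum(xs) / length(xs)
  my <- sum(ys) / length(ys)
  num <- 0; dx <- 0; dy <- 0
  for (k in seq_along(xs)) {
    num <- num + (xs[k] - mx) * (ys[k] - my)
    dx <- dx + (xs[k] - mx)^2
    dy <- dy + (ys[k] - my)^2
  }
  if (dx == 0 || dy == 0) return(NA_real_)
  num / sqrt(dx * dy)
}

# Exhaustive optimal 1-D k-partition: optimal clusters of scalars are
# contiguous in sorted order, so enumerate all compositions of n into k
# non-empty blocks and keep the minimum within-cluster sum of squares.
oracle_best_sse <- function(values, k) {
  vs <- sort(values)
  n <- length(vs)
  block_sse <- function(seg) sum((seg - mean(seg))^2)
  best <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  if (k == 1) return(block_sse(vs))
  for (col in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, col], n)
    sse <- 0
    for (j in seq_len(k)) sse <- sse + block_sse(vs[(b[j] + 1):b[j + 1]])
    if (sse < best) best <- sse
  }
  best
}

# Product-limit estimator from first principles.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# Two-sample log-rank O-E and hypergeometric variance by explicit risk-set
# tabulation; `group` is a two-level factor, statistics are for level 1.
oracle_logrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(observed = O, expected = E, variance = V,
       statistic = (O - E)^2 / V)
}

# small constructors --------------------------------------------------------

make_series <- function(times, sizes, pid = "P1", id = "L1") {
  list(patient_id = pid, series_id = id, times = times, sizes = sizes,
       organ_text = "", lesion_type = "metastatic")
}

make_records <- function(pid, lid, organ, type, times, sizes, metric = "SLD") {
  data.frame(patient_id = pid, lesion_id = lid, organ_text = organ,
             lesion_type = type, time = times, size = sizes, metric = metric,
             stringsAsFactors = FALSE)
}

make_covariates <- function(pids, surgery_time = NA_real_, os_time = 100,
                            os_event = 1L, arm = "cetuximab", kras = "wt",
                            ecog = "fully_active") {
  data.frame(patient_id = pids, arm = arm, kras = kras, ecog = ecog,
             surgery_time = surgery_time, os_time = os_time,
             os_event = os_event, stringsAsFactors = FALSE)
}
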