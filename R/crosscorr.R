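# Lagged cross-correlation of lesion-size time courses.
#
# The similarity of two within-patient size trajectories is the Pearson
# product-moment correlation of the two series restricted to their common
# assessment visits, evaluated at integer shifts of the visit index
# (statistical normalized cross-correlation). Each lagged CC is mean-centered
# and scaled by the overlap-segment standard deviations, so every defined
# value lies in [-1, 1]: 1 means the two lesions move together, -1 means
# opposite dynamics, values near 0 an undefined relationship.

#' Align two lesion series on their common assessment visits
#'
#' Within-patient lesions share protocol assessment visits; alignment pairs
#' the visits present in both series, matching times within `time_tolerance`
#' weeks (default 0, exact match), preserving visit order.
#'
#' @param a,b Lesion series (lists with `times` and `sizes`, as produced by
#'   [build_series()]).
#' @param time_tolerance Maximum time difference (weeks) for two visits to be
#'   considered the same assessment.
#' @return A list with `times` (from `a`), `x`, `y` (the paired size vectors)
#'   and `n` (number of common visits). Pairs with fewer than 2 common visits
#'   are non-computable: `n < 2` and `x`/`y` empty or length 1.
#' @export
align_series <- function(a, b, time_tolerance = 0) {
  ia <- integer(0); ib <- integer(0)
  used_b <- rep(FALSE, length(b$times))
  for (i in seq_along(a$times)) {
    d <- abs(b$times - a$times[i])
    d[used_b] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && is.finite(d[j]) && d[j] <= time_tolerance) {
      ia <- c(ia, i); ib <- c(ib, j); used_b[j] <- TRUE
    }
  }
  list(times = a$times[ia], x = a$sizes[ia], y = b$sizes[ib], n = length(ia))
}

#' Cross-correlation of two equal-length size vectors at one lag
#'
#' Pairs `x[i]` with `y[i + lag]` over the indices where both exist, then
#' computes the Pearson correlation of the overlapping segments (centered by
#' the overlap means, scaled by the overlap standard deviations). Undefined
#' (`NA`) when the overlap is shorter than 2 points or either overlap segment
#' is flat (zero variance).
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @param lag Integer visit-index shift, `|lag| <= n - 2`.
#' @return A number in `[-1, 1]`, or `NA` when undefined.
#' @export
cc_at_lag <- function(x, y, lag) {
  n <- length(x)
  stopifnot(length(y) == n, lag == round(lag))
  i <- seq.int(max(1L, 1L - lag), min(n, n - lag))
  if (length(i) < 2) return(NA_real_)
  xs <- x[i]
  ys <- y[i + lag]
  xc <- xs - mean(xs)
  yc <- ys - mean(ys)
  sx2 <- sum(xc^2)
  sy2 <- sum(yc^2)
  if (sx2 == 0 || sy2 == 0) return(NA_real_)
  r <- sum(xc * yc) / sqrt(sx2 * sy2)
  # guard against floating-point excursion beyond the mathematical range
  max(-1, min(1, r))
}

#' Full lag profile of a lesion pair
#'
#' Evaluates [cc_at_lag()] for every lag in `[-L, L]` with
#' `L = min(max_lag, n - 2)` where `n` is the number of common visits, so the
#' overlap always keeps at least 2 points. A two-assessment pair allows no
#' shift: only lag 0 is evaluated and its CC is -1 or 1 (or undefined when a
#' segment is flat). `best_lag` attains the maximum defined CC; ties are
#' broken by the smallest `|lag|`, then by the negative lag.
#'
#' @param a,b Lesion series from the same patient.
#' @param max_lag Maximum number of visit-index shifts searched in each
#'   direction (default 12).
#' @param time_tolerance Passed to [align_series()].
#' @return A list of class `cc_record`: `patient_id`, `id_a`, `id_b`,
#'   `cc_zero`, `cc_max`, `best_lag`, `n_overlap_zero`, `lag_profile` (named
#'   numeric, names are lags), and `computable` (`FALSE` when fewer than 2
#'   common visits, in which case the CC fields are `NA`).
#' @export
cc_profile <- function(a, b, max_lag = 12, time_tolerance = 0) {
  stopifnot(max_lag >= 0)
  al <- align_series(a, b, time_tolerance)
  rec <- list(patient_id = a$patient_id, id_a = a$series_id, id_b = b$series_id,
              cc_zero = NA_real_, cc_max = NA_real_, best_lag = NA_integer_,
              n_overlap_zero = al$n, lag_profile = numeric(0),
              computable = FALSE)
  class(rec) <- "cc_record"
  if (al$n < 2) return(rec)

  L <- as.integer(min(max_lag, al$n - 2L))
  lags <- seq.int(-L, L)
  prof <- vapply(lags, function(k) cc_at_lag(al$x, al$y, k), numeric(1))
  names(prof) <- lags
  rec$computable <- TRUE
  rec$lag_profile <- prof
  rec$cc_zero <- prof[[as.character(0)]]
  defined <- which(!is.na(prof))
  if (length(defined) > 0) {
    m <- max(prof[defined])
    cand <- lags[defined][prof[defined] == m]
    # smallest |lag| first, negative before positive on equal magnitude
    cand <- cand[order(abs(cand), cand)]
    rec$cc_max <- m
    rec$best_lag <- as.integer(cand[1])
  }
  rec
}

#' Collect cross-correlation records into a table
#'
#' @param cc_records List of `cc_record` objects.
#' @param analysis Label stored in the `analysis` column (e.g.
#'   `"inter-class"`, `"intra-class:Liver"`).
#' @return A `data.frame` with one row per pair: `patient_id`, `id_a`, `id_b`,
#'   `cc_zero`, `cc_max`, `best_lag`, `n_overlap`, `computable`, `analysis`.
#' @export
cc_table <- function(cc_records, analysis = "inter-class") {
  if (length(cc_records) == 0) {
    return(data.frame(patient_id = character(0), id_a = character(0),
                      id_b = character(0), cc_zero = numeric(0),
                      cc_max = numeric(0), best_lag = integer(0),
                      n_overlap = integer(0), computable = logical(0),
                      analysis = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    patient_id = vapply(cc_records, `[[`, character(1), "patient_id"),
    id_a = vapply(cc_records, `[[`, character(1), "id_a"),
    id_b = vapply(cc_records, `[[`, character(1), "id_b"),
    cc_zero = vapply(cc_records, `[[`, numeric(1), "cc_zero"),
    cc_max = vapply(cc_records, `[[`, numeric(1), "cc_max"),
    best_lag = vapply(cc_records, `[[`, integer(1), "best_lag"),
    n_overlap = vapply(cc_records, function(r) as.integer(r$n_overlap_zero),
                       integer(1)),
    computable = vapply(cc_records, `[[`, logical(1), "computable"),
    analysis = analysis,
    stringsAsFactors = FALSE
  )
}
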