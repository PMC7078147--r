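# Inter-class and intra-class heterogeneity analyses.
#
# Inter-class: per patient, lesions are aggregated into one class-related
# target lesion (cTL) per organ class and every unordered pair of cTLs is
# compared by lagged cross-correlation; only patients with lesions in more
# than one class contribute. Intra-class: within one organ class, every
# unordered pair of that patient's individual lesions is compared; only
# patients with more than one lesion in the class contribute. The resulting
# CC values are grouped by 1-D K-means (elbow-selected or fixed k) and
# summarized per cluster.

#' Build class-related target lesions (cTLs) for one patient
#'
#' A cTL is the per-class sum of lesion sizes, evaluated only at visits where
#' all of that patient's lesions of the class were measured (complete-case
#' visit rule, so the summed series never drops artificially when a single
#' lesion misses a visit). Classes whose summed series has fewer than 2 visits
#' are dropped — they cannot enter a cross-correlation.
#'
#' @param lesions Named list of lesion series for one patient (one element of
#'   [build_series()] output).
#' @param classified Classification table ([classify_lesions()]) covering this
#'   patient's lesions.
#' @return Named list (class name -> lesion series with `series_id` = class
#'   name).
#' @export
build_ctls <- function(lesions, classified) {
  if (length(lesions) == 0) return(list())
  pid <- lesions[[1]]$patient_id
  cls <- classified[classified$patient_id == pid, , drop = FALSE]
  out <- list()
  for (cl in unique(cls$class_name)) {
    ids <- cls$lesion_id[cls$class_name == cl]
    ids <- intersect(ids, names(lesions))
    if (length(ids) == 0) next
    common <- lesions[[ids[1]]]$times
    for (id in ids[-1]) common <- intersect(common, lesions[[id]]$times)
    common <- sort(common)
    if (length(common) < 2) next
    sizes <- rowSums(vapply(ids, function(id) {
      s <- lesions[[id]]
      s$sizes[match(common, s$times)]
    }, numeric(length(common))))
    out[[cl]] <- list(patient_id = pid, series_id = cl,
                      times = common, sizes = sizes,
                      organ_text = cl, lesion_type = "ctl")
  }
  out
}

#' Inter-class lesion-pair cross-correlations
#'
#' Builds cTLs per patient and computes one CC record per unordered pair of
#' classes; patients with fewer than 2 eligible classes contribute nothing.
#'
#' @param series_by_patient Output of [build_series()].
#' @param classified Classification table covering all lesions.
#' @param max_lag,time_tolerance Passed to [cc_profile()].
#' @return List of `cc_record` objects (see [cc_profile()]).
#' @export
interclass_pairs <- function(series_by_patient, classified, max_lag = 12,
                             time_tolerance = 0) {
  recs <- list()
  for (pid in names(series_by_patient)) {
    ctls <- build_ctls(series_by_patient[[pid]], classified)
    if (length(ctls) < 2) next
    cls <- sort(names(ctls))
    for (i in seq_len(length(cls) - 1)) {
      for (j in seq.int(i + 1, length(cls))) {
        recs[[length(recs) + 1]] <-
          cc_profile(ctls[[cls[i]]], ctls[[cls[j]]], max_lag, time_tolerance)
      }
    }
  }
  recs
}

#' Intra-class lesion-pair cross-correlations
#'
#' All unordered pairs of one class's individual lesions within each patient;
#' patients with at most one lesion in the class contribute nothing.
#'
#' @inheritParams interclass_pairs
#' @param class_name The organ class analyzed.
#' @return List of `cc_record` objects.
#' @export
intraclass_pairs <- function(series_by_patient, classified, class_name,
                             max_lag = 12, time_tolerance = 0) {
  recs <- list()
  keep <- classified[classified$class_name == class_name, , drop = FALSE]
  for (pid in names(series_by_patient)) {
    ids <- keep$lesion_id[keep$patient_id == pid]
    ids <- sort(intersect(ids, names(series_by_patient[[pid]])))
    if (length(ids) < 2) next
    lesions <- series_by_patient[[pid]]
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq.int(i + 1, length(ids))) {
        recs[[length(recs) + 1]] <-
          cc_profile(lesions[[ids[i]]], lesions[[ids[j]]], max_lag,
                     time_tolerance)
      }
    }
  }
  recs
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Exact 1-D k-means for small inputs: optimal scalar clusters are contiguous
# in sorted order, so enumerating the C(n-1, k-1) boundary placements finds
# the global optimum.
exhaustive_1d <- function(vs, cs, cs2, k) {
  n <- length(vs)
  cs0 <- c(0, cs)
  cs20 <- c(0, cs2)
  block_sse <- function(i, j) {
    len <- j - i + 1
    s <- cs0[j + 1] - cs0[i]
    (cs20[j + 1] - cs20[i]) - s * s / len
  }
  best_sse <- Inf
  best_b <- NULL
  cuts <- if (k == 1) matrix(integer(0), nrow = 0, ncol = 1)
          else utils::combn(n - 1, k - 1)
  for (col in seq_len(ncol(cuts))) {
    b <- c(0L, cuts[, col], n)
    sse <- 0
    for (j in seq_len(k)) sse <- sse + block_sse(b[j] + 1L, b[j + 1L])
    if (sse < best_sse) {
      best_sse <- sse
      best_b <- b
    }
  }
  sizes <- diff(best_b)
  centroids <- vapply(seq_len(k), function(j)
    (cs0[best_b[j + 1L] + 1L] - cs0[best_b[j] + 1L]) / sizes[j], numeric(1))
  list(centroids = centroids,
       assignment_sorted = rep.int(seq_len(k), sizes),
       sizes = sizes, sse = max(best_sse, 0))
}

# One Lloyd descent on sorted scalar data. In 1-D the nearest-centroid
# assignment is the interval partition at midpoints between sorted centroids,
# so each iteration is O(n log k) via findInterval over cumulative sums.
lloyd_1d <- function(vs, cs, cs2, centroids, max_iter = 100) {
  n <- length(vs)
  k <- length(centroids)
  centroids <- sort(centroids)
  for (iter in seq_len(max_iter)) {
    bounds <- (centroids[-k] + centroids[-1]) / 2
    idx <- findInterval(vs, bounds) + 1L
    cnt <- tabulate(idx, k)
    if (any(cnt == 0)) return(NULL)  # empty cluster: restart discarded
    ends <- cumsum(cnt)
    starts <- ends - cnt + 1L
    sums <- cs[ends] - c(0, cs)[starts]
    new_cent <- sums / cnt
    if (max(abs(new_cent - centroids)) == 0) break
    centroids <- new_cent
  }
  bounds <- (centroids[-k] + centroids[-1]) / 2
  idx <- findInterval(vs, bounds) + 1L
  cnt <- tabulate(idx, k)
  if (any(cnt == 0)) return(NULL)
  ends <- cumsum(cnt)
  starts <- ends - cnt + 1L
  sums <- cs[ends] - c(0, cs)[starts]
  sq <- cs2[ends] - c(0, cs2)[starts]
  centroids <- sums / cnt
  sse <- sum(sq - sums^2 / cnt)
  list(centroids = centroids, assignment_sorted = idx, sizes = cnt,
       sse = max(sse, 0))
}

#' 1-D K-means clustering of cross-correlation values
#'
#' Lloyd's algorithm on scalars with seeded random restarts; the best
#' (lowest-SSE) solution is kept and restarts that collapse a cluster are
#' discarded. The first restart uses evenly spaced order statistics as
#' centers, the rest sample k distinct values. Small inputs (up to a few
#' thousand contiguous partitions) are instead solved exactly by enumerating
#' cluster boundaries — optimal 1-D clusters are contiguous in sorted order —
#' so small problems always receive the global optimum, deterministically.
#' Clusters are renumbered 1..k by
#' ascending centroid, so cluster 1 always holds the lowest (most negative)
#' CC values.
#'
#' @param values Numeric vector without `NA`s (undefined CCs are excluded
#'   upstream).
#' @param k Number of clusters (must not exceed the number of distinct
#'   values).
#' @param seed Integer seed driving the restarts; the caller's RNG state is
#'   untouched.
#' @param n_restarts Number of initializations (default 50).
#' @return An object of class `kmeans1d`: list with `k`, `centroids` (sorted
#'   ascending), `assignment` (cluster index per input value), `sizes`, `sse`.
#' @export
kmeans_1d <- function(values, k, seed = 1, n_restarts = 50) {
  stopifnot(k >= 1, n_restarts >= 1)
  if (anyNA(values)) stop("values must not contain NA; filter undefined CCs first",
                          call. = FALSE)
  uv <- unique(values)
  if (k > length(uv)) {
    stop("k (", k, ") exceeds the number of distinct values (", length(uv), ")",
         call. = FALSE)
  }
  o <- order(values)
  vs <- values[o]
  cs <- cumsum(vs)
  cs2 <- cumsum(vs^2)

  best <- NULL
  if (choose(length(vs) - 1, k - 1) <= 2000) {
    # small problem: the global optimum is cheap to enumerate exactly
    best <- exhaustive_1d(vs, cs, cs2, k)
  } else with_local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- if (r == 1) {
        # deterministic spread: evenly spaced order statistics
        vs[unique(round(seq(1, length(vs), length.out = k)))]
      } else {
        sample(uv, k)
      }
      if (length(unique(init)) < k) next
      fit <- lloyd_1d(vs, cs, cs2, init)
      if (is.null(fit)) next
      if (is.null(best) || fit$sse < best$sse - 1e-12) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed: no restart produced k non-empty clusters",
                          call. = FALSE)
  assignment <- integer(length(values))
  assignment[o] <- best$assignment_sorted
  structure(list(k = k, centroids = best$centroids, assignment = assignment,
                 sizes = best$sizes, sse = best$sse),
            class = "kmeans1d")
}

#' Elbow rule on an SSE-versus-k curve
#'
#' Returns the k with maximum discrete curvature of `log SSE(k)`
#' (`log SSE(k-1) - 2 log SSE(k) + log SSE(k+1)`); ties go to the smaller k.
#' The logarithmic scale makes the curvature respond to *relative* SSE drops,
#' so the bend is located at the last k that still removes a large share of
#' the remaining within-cluster variance; raw-scale curvature is dominated by
#' the huge absolute drop out of k = 1 and collapses to k = 2 on almost any
#' clustered data. Exposed separately from [choose_k_elbow()] so
#' hand-constructed SSE sequences can be checked directly.
#'
#' @param sse Numeric vector, `sse[k]` being the within-cluster sum of
#'   squares at k clusters, k = 1..length(sse); length >= 3.
#' @return The selected k.
#' @export
elbow_from_sse <- function(sse) {
  stopifnot(length(sse) >= 3)
  floor_ <- max(sse[1], 1) * 1e-12   # guard against log(0) at perfect fits
  ls <- log(pmax(sse, floor_))
  ks <- 2:(length(sse) - 1)
  curv <- ls[ks - 1] - 2 * ls[ks] + ls[ks + 1]
  ks[which.max(curv)]
}

#' Select the number of clusters by the elbow method
#'
#' Fits K-means for k = 1..`k_max`, asserts that the best-of-restarts SSE is
#' non-increasing in k, and returns the k of maximum curvature of the
#' log-SSE curve (see [elbow_from_sse()]).
#'
#' @inheritParams kmeans_1d
#' @param k_max Largest k considered (default 6, must be >= 3). Shrunk with a
#'   warning when the data have fewer than `k_max + 1` distinct values.
#' @param n_restarts Restarts per k (default 10: the elbow only needs the
#'   relative SSE profile).
#' @return A list with `k` (the selection) and `sse` (named vector, SSE per
#'   candidate k).
#' @export
choose_k_elbow <- function(values, k_max = 6, seed = 1, n_restarts = 10) {
  stopifnot(k_max >= 3)
  d <- length(unique(values))
  if (d < k_max + 1) {
    k_max <- d
    warning("fewer distinct values than k_max + 1; shrinking k_max to ", k_max)
    if (k_max < 3) stop("need at least 3 distinct values for an elbow",
                        call. = FALSE)
  }
  sse <- vapply(seq_len(k_max), function(k)
    kmeans_1d(values, k, seed = seed + k, n_restarts = n_restarts)$sse,
    numeric(1))
  names(sse) <- seq_len(k_max)
  if (any(diff(sse) > 1e-8)) {
    stop("SSE(k) increased with k; increase n_restarts", call. = FALSE)
  }
  list(k = elbow_from_sse(sse), sse = sse)
}

#' Cluster the CC values of a pair table
#'
#' @param cc_df A CC table ([cc_table()]).
#' @param use_max_cc Cluster the lag-maximized CCs instead of the zero-shift
#'   CCs.
#' @param k Number of clusters; `NULL` selects k by [choose_k_elbow()].
#' @inheritParams kmeans_1d
#' @return An object of class `cc_clustering`: `clusters` (the [kmeans_1d()]
#'   fit), `pairs` (the rows with a defined CC, in clustering order),
#'   `values`, `use_max_cc`, `n_undefined` (pairs excluded because their CC
#'   was undefined or non-computable), and `elbow` (the elbow diagnostic when
#'   k was selected automatically, else `NULL`).
#' @export
cluster_cc_pairs <- function(cc_df, use_max_cc = FALSE, k = 3, seed = 1,
                             n_restarts = 50) {
  values <- if (use_max_cc) cc_df$cc_max else cc_df$cc_zero
  defined <- !is.na(values) & cc_df$computable
  vals <- values[defined]
  elbow <- NULL
  if (is.null(k)) {
    elbow <- choose_k_elbow(vals, seed = seed)
    k <- elbow$k
  }
  fit <- kmeans_1d(vals, k, seed = seed, n_restarts = n_restarts)
  structure(list(clusters = fit, pairs = cc_df[defined, , drop = FALSE],
                 values = vals, use_max_cc = use_max_cc,
                 n_undefined = sum(!defined), elbow = elbow),
            class = "cc_clustering")
}

#' Per-cluster summary report
#'
#' For each cluster: centroid, number and percentage of CC pairs, number and
#' percentage of patients (a patient is counted once in every cluster where
#' it has at least one pair, so patient percentages may sum to more than
#' 100), and an interpretation label: `different` when the centroid is below
#' `-cutoff`, `similar` when above `cutoff`, `undefined` in between.
#'
#' @param clustering A `cc_clustering` from [cluster_cc_pairs()].
#' @param cutoff Centroid cutoff for the interpretation labels (default 0.35).
#' @return A list with `table` (one row per cluster), `similar_pct_pairs` /
#'   `similar_pct_patients` (totals over every cluster labeled `similar`,
#'   merging high-centroid clusters), `n_pairs`, `n_patients`,
#'   `n_undefined`.
#' @export
cluster_report <- function(clustering, cutoff = 0.35) {
  fit <- clustering$clusters
  pairs <- clustering$pairs
  n_pairs <- nrow(pairs)
  patients <- unique(pairs$patient_id)
  n_patients <- length(patients)
  rows <- lapply(seq_len(fit$k), function(cl) {
    in_cl <- fit$assignment == cl
    pts <- unique(pairs$patient_id[in_cl])
    centroid <- fit$centroids[cl]
    data.frame(
      cluster = cl,
      centroid = centroid,
      n_pairs = sum(in_cl),
      pct_pairs = 100 * sum(in_cl) / n_pairs,
      n_patients = length(pts),
      pct_patients = 100 * length(pts) / n_patients,
      label = if (centroid < -cutoff) "different"
              else if (centroid > cutoff) "similar" else "undefined",
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  sim <- tab$label == "similar"
  sim_patients <- unique(pairs$patient_id[fit$assignment %in% tab$cluster[sim]])
  list(table = tab,
       similar_pct_pairs = sum(tab$pct_pairs[sim]),
       similar_pct_patients = 100 * length(sim_patients) / max(n_patients, 1),
       n_pairs = n_pairs, n_patients = n_patients,
       n_undefined = clustering$n_undefined)
}

#' Histogram of best lags per cluster
#'
#' Counts, within each cluster, the visit-index lags at which the maximum CC
#' was attained.
#'
#' @param clustering A `cc_clustering`.
#' @return A `data.frame` with `cluster`, `lag`, `count`.
#' @export
lag_histogram <- function(clustering) {
  fit <- clustering$clusters
  lag <- clustering$pairs$best_lag
  out <- list()
  for (cl in seq_len(fit$k)) {
    lags <- lag[fit$assignment == cl & !is.na(lag)]
    if (length(lags) == 0) next
    tb <- table(lags)
    out[[length(out) + 1]] <- data.frame(cluster = cl,
                                         lag = as.integer(names(tb)),
                                         count = as.integer(tb))
  }
  if (length(out) == 0) {
    return(data.frame(cluster = integer(0), lag = integer(0),
                      count = integer(0)))
  }
  do.call(rbind, out)
}
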