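# Canonical column sets ----------------------------------------------------

LESION_COLUMNS <- c("patient_id", "lesion_id", "organ_text", "lesion_type",
                    "time", "size", "metric")
COVARIATE_COLUMNS <- c("patient_id", "arm", "kras", "ecog", "surgery_time",
                       "os_time", "os_event")

VALID_LESION_TYPES <- c("primary", "metastatic", "node")
VALID_METRICS <- c("SLD", "SOPD")

#' Read a long-format lesion measurement table
#'
#' One row per patient x lesion x assessment visit. Sizes are in mm for the
#' longest-diameter metric (SLD) or mm^2 for the product-of-diameters metric
#' (SOPD); times are weeks since baseline. Columns may be renamed in the file
#' and mapped back via `col_map`.
#'
#' @param path Path to a delimited text file (`.csv` or tab-delimited
#'   otherwise) with a header.
#' @param col_map Optional named character vector mapping canonical names
#'   (`patient_id`, `lesion_id`, `organ_text`, `lesion_type`, `time`, `size`,
#'   `metric`) to the column names used in the file.
#' @param sep Field separator; defaults to `","` for `.csv` files and tab
#'   otherwise.
#' @return A validated `data.frame` of lesion records with the canonical
#'   columns.
#' @export
read_lesion_table <- function(path, col_map = NULL, sep = NULL) {
  df <- read_mapped_table(path, col_map, sep, LESION_COLUMNS)
  validate_lesion_records(df)
}

#' Read a patient covariate table
#'
#' @inheritParams read_lesion_table
#' @return A validated `data.frame` with columns `patient_id`, `arm`
#'   (`cetuximab`/`control`), `kras` (`wt`/`mut`/`missing`), `ecog`
#'   (`fully_active`/`not_fully_active`/`missing`), `surgery_time` (weeks, `NA`
#'   when no surgery), `os_time` (weeks), `os_event` (1 death, 0 censored).
#' @export
read_covariate_table <- function(path, col_map = NULL, sep = NULL) {
  df <- read_mapped_table(path, col_map, sep, COVARIATE_COLUMNS)
  validate_covariates(df)
}

read_mapped_table <- function(path, col_map, sep, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), comment.char = "")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      idx <- match(col_map[[canon]], names(df))
      if (!is.na(idx)) names(df)[idx] <- canon
    }
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df[required]
}

#' Validate lesion records
#'
#' Enforces the record invariants: numeric non-negative `time` and `size`,
#' known `lesion_type`, a single `metric` per dataset, and uniqueness of
#' (`patient_id`, `lesion_id`, `time`). Violations raise errors naming the
#' offending rows.
#'
#' @param df A `data.frame` with the canonical lesion columns.
#' @return The validated `data.frame` (character ids, numeric time/size).
#' @export
validate_lesion_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(LESION_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[LESION_COLUMNS]
  df$patient_id <- as.character(df$patient_id)
  df$lesion_id <- as.character(df$lesion_id)
  df$organ_text <- ifelse(is.na(df$organ_text), "", as.character(df$organ_text))
  df$lesion_type <- as.character(df$lesion_type)
  time_num <- suppressWarnings(as.numeric(df$time))
  size_num <- suppressWarnings(as.numeric(df$size))

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      stop(what, " in row(s): ", paste(utils::head(rows, 20), collapse = ", "),
           call. = FALSE)
    }
  }
  bad(is.na(df$patient_id) | df$patient_id == "", "missing patient_id")
  bad(is.na(df$lesion_id) | df$lesion_id == "", "missing lesion_id")
  bad(is.na(time_num) & !is.na(df$time), "non-numeric time")
  bad(is.na(size_num) & !is.na(df$size), "non-numeric size")
  bad(is.na(time_num), "missing time")
  bad(is.na(size_num), "missing size")
  bad(time_num < 0, "negative time")
  bad(size_num < 0, "negative size")
  bad(!(df$lesion_type %in% VALID_LESION_TYPES),
      paste0("lesion_type outside {", paste(VALID_LESION_TYPES, collapse = ", "), "}"))
  bad(!(df$metric %in% VALID_METRICS),
      paste0("metric outside {", paste(VALID_METRICS, collapse = ", "), "}"))
  if (length(unique(df$metric)) > 1) {
    stop("metric must be constant within a dataset; found: ",
         paste(unique(df$metric), collapse = ", "), call. = FALSE)
  }
  df$time <- time_num
  df$size <- size_num
  key <- paste(df$patient_id, df$lesion_id, df$time, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    k <- strsplit(key[which(dup)[1]], "\r", fixed = TRUE)[[1]]
    stop("duplicated (patient_id, lesion_id, time) key: (",
         paste(k, collapse = ", "), ")", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' @keywords internal
validate_covariates <- function(df) {
  stopifnot(is.data.frame(df))
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    stop("duplicated patient_id in covariate table", call. = FALSE)
  }
  df$os_time <- as.numeric(df$os_time)
  df$os_event <- as.integer(df$os_event)
  df$surgery_time <- suppressWarnings(as.numeric(df$surgery_time))
  if (any(is.na(df$os_time)) || any(df$os_time <= 0)) {
    stop("os_time must be positive for every patient", call. = FALSE)
  }
  if (!all(df$os_event %in% c(0L, 1L))) {
    stop("os_event must be 0 (censored) or 1 (death)", call. = FALSE)
  }
  df
}

#' Preprocess lesion records before heterogeneity analysis
#'
#' Applies the study exclusion rules: (a) drop all records of patients whose
#' only assessment time is baseline (a single distinct time value); (b) for
#' patients with a recorded tumor surgery, drop measurements taken strictly
#' after the surgery time (the last pre-surgery assessment is kept); then (c)
#' re-apply rule (a), since surgery truncation may leave a patient with only
#' the baseline visit.
#'
#' @param records Validated lesion records (see [validate_lesion_records()]).
#' @param covariates Patient covariate table providing `surgery_time`; every
#'   patient present in `records` must appear here.
#' @return A list with `records` (the surviving rows) and `report`, a list of
#'   per-rule exclusion counts
#'   (`n_patients_baseline_only`, `n_records_baseline_only`,
#'   `n_records_post_surgery`, `n_patients_baseline_only_after_surgery`,
#'   `n_records_baseline_only_after_surgery`, plus input/output totals).
#' @export
preprocess_lesions <- function(records, covariates) {
  covariates$patient_id <- as.character(covariates$patient_id)
  unknown <- setdiff(unique(records$patient_id), covariates$patient_id)
  if (length(unknown) > 0) {
    stop("covariates missing for patient(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n_in <- nrow(records)

  baseline_only_patients <- function(df) {
    n_times <- tapply(df$time, df$patient_id, function(t) length(unique(t)))
    names(n_times)[n_times <= 1]
  }

  # (a) baseline-only patients
  drop_a <- baseline_only_patients(records)
  keep <- !(records$patient_id %in% drop_a)
  n_rec_a <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  # (b) post-surgery truncation (strict inequality: time > surgery_time goes)
  surg <- stats::setNames(covariates$surgery_time, covariates$patient_id)
  st <- surg[records$patient_id]
  post <- !is.na(st) & records$time > st
  n_rec_b <- sum(post)
  records <- records[!post, , drop = FALSE]

  # (c) re-apply (a)
  drop_c <- if (nrow(records) > 0) baseline_only_patients(records) else character(0)
  keep <- !(records$patient_id %in% drop_c)
  n_rec_c <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  rownames(records) <- NULL

  report <- list(
    n_records_in = n_in,
    n_patients_baseline_only = length(drop_a),
    n_records_baseline_only = n_rec_a,
    n_records_post_surgery = n_rec_b,
    n_patients_baseline_only_after_surgery = length(drop_c),
    n_records_baseline_only_after_surgery = n_rec_c,
    n_records_out = nrow(records),
    n_records_removed = n_in - nrow(records)
  )
  list(records = records, report = report)
}

#' Write a preprocessing report as JSON
#'
#' @param report The `report` element returned by [preprocess_lesions()].
#' @param path Output path.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Assemble per-lesion time series
#'
#' @param records Preprocessed lesion records.
#' @return A named list keyed by `patient_id`; each element is a named list
#'   keyed by `lesion_id` whose elements are lesion series: lists with
#'   `patient_id`, `series_id`, `times` (strictly increasing weeks), `sizes`,
#'   `organ_text` and `lesion_type`.
#' @export
build_series <- function(records) {
  out <- list()
  if (nrow(records) == 0) return(out)
  for (pid in unique(records$patient_id)) {
    prec <- records[records$patient_id == pid, , drop = FALSE]
    lesions <- list()
    for (lid in unique(prec$lesion_id)) {
      lrec <- prec[prec$lesion_id == lid, , drop = FALSE]
      o <- order(lrec$time)
      lesions[[lid]] <- list(
        patient_id = pid,
        series_id = lid,
        times = lrec$time[o],
        sizes = lrec$size[o],
        organ_text = lrec$organ_text[1],
        lesion_type = lrec$lesion_type[1]
      )
    }
    out[[pid]] <- lesions
  }
  out
}

#' Total tumor size at a landmark time
#'
#' For each patient, sums the sizes of all lesions measured at the assessment
#' visit whose time is nearest to `t_query` within `tolerance` weeks (ties go
#' to the earlier visit). Only lesions actually measured at that visit enter
#' the sum. Patients with no qualifying visit get `NA` — missingness is a
#' value here, not an error.
#'
#' @param series_by_patient Output of [build_series()].
#' @param t_query Landmark time in weeks (e.g. 0 for baseline, 8 for the early
#'   tumor shrinkage landmark).
#' @param tolerance Half-width in weeks of the visit-matching window
#'   (default 2).
#' @return A named numeric vector (one entry per patient, `NA` when missing).
#' @export
total_ts <- function(series_by_patient, t_query, tolerance = 2) {
  stopifnot(t_query >= 0, tolerance >= 0)
  vapply(series_by_patient, function(lesions) {
    all_times <- sort(unique(unlist(lapply(lesions, `[[`, "times"))))
    d <- abs(all_times - t_query)
    ok <- d <= tolerance
    if (!any(ok)) return(NA_real_)
    visit <- all_times[ok][which.min(d[ok])]
    sum(vapply(lesions, function(s) {
      i <- match(visit, s$times)
      if (is.na(i)) 0 else s$sizes[i]
    }, numeric(1)))
  }, numeric(1))
}
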