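# Rule-based organ classification of individual target lesions.
#
# Free-text lesion locations from case report forms are matched against an
# ordered, user-editable keyword ruleset. Two class names are reserved:
# "Primary lesions" (assigned by lesion type, never by keyword) and
# "Unclassified lesions" (no keyword hit or missing location text).

PRIMARY_CLASS <- "Primary lesions"
UNCLASSIFIED_CLASS <- "Unclassified lesions"
OTHER_CLASS <- "Other"
MAIN_CLASSES <- c("Liver", "Lung", "Lymph node")

#' Load an organ-classification ruleset
#'
#' A ruleset is an ordered list of `(class name, keywords)` blocks; matching is
#' case-insensitive first-match-wins in ruleset order. The YAML layout is a
#' mapping from class name to a list of keywords; mapping order is preserved.
#'
#' @param path Path to a YAML ruleset. Defaults to the ruleset shipped with
#'   the package, a reconstruction of the organ keyword lists used in
#'   metastatic colorectal cancer lesion classification (liver, lung, lymph
#'   node, other respiratory / digestive / specified organs).
#' @return An object of class `lesion_ruleset`: a named list of character
#'   keyword vectors.
#' @export
read_ruleset <- function(path = system.file("extdata", "organ_classes.yaml",
                                            package = "lesiondyn")) {
  raw <- yaml::read_yaml(path)
  validate_ruleset(raw)
}

#' Validate (or build) a classification ruleset
#'
#' @param raw Named list: class name -> character vector of keywords, in
#'   matching priority order.
#' @return A `lesion_ruleset` object.
#' @export
validate_ruleset <- function(raw) {
  if (length(raw) == 0 || is.null(names(raw)) || any(names(raw) == "")) {
    stop("ruleset must be a named list of keyword vectors", call. = FALSE)
  }
  if (anyDuplicated(names(raw))) stop("duplicate class names in ruleset", call. = FALSE)
  rules <- lapply(raw, function(kw) {
    kw <- as.character(unlist(kw))
    if (length(kw) == 0 || any(!nzchar(kw))) {
      stop("every class needs at least one non-empty keyword", call. = FALSE)
    }
    kw
  })
  reserved <- intersect(names(rules), c(PRIMARY_CLASS, UNCLASSIFIED_CLASS))
  if (length(reserved) > 0) {
    stop("reserved class name(s) in ruleset: ", paste(reserved, collapse = ", "),
         call. = FALSE)
  }
  structure(rules, class = "lesion_ruleset")
}

# Uppercase and strip punctuation so keyword matching is a plain substring
# test on normalized text; no stemming.
normalize_organ_text <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[^A-Z0-9 ]+", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Classify lesions into organ classes
#'
#' Primary (non-metastatic) lesions go to `"Primary lesions"` regardless of
#' location text. Otherwise the first ruleset class (in ruleset order) with a
#' keyword contained case-insensitively in the normalized location text wins;
#' lesions with empty/missing location text or no keyword hit fall into
#' `"Unclassified lesions"`.
#'
#' @param lesion_meta A `data.frame` with one row per lesion: `patient_id`,
#'   `lesion_id`, `organ_text`, `lesion_type`. Typically built with
#'   [lesion_metadata()].
#' @param ruleset A `lesion_ruleset` (see [read_ruleset()]).
#' @return A `data.frame` with `patient_id`, `lesion_id`, `class_name` and
#'   `matched_keyword` (`NA` when no keyword decided the class).
#' @export
classify_lesions <- function(lesion_meta, ruleset = read_ruleset()) {
  stopifnot(is.data.frame(lesion_meta),
            all(c("patient_id", "lesion_id", "organ_text", "lesion_type") %in%
                  names(lesion_meta)))
  norm <- normalize_organ_text(lesion_meta$organ_text)
  n <- nrow(lesion_meta)
  class_name <- rep(UNCLASSIFIED_CLASS, n)
  matched <- rep(NA_character_, n)
  undecided <- rep(TRUE, n)

  is_primary <- lesion_meta$lesion_type == "primary"
  class_name[is_primary] <- PRIMARY_CLASS
  undecided[is_primary] <- FALSE

  for (cls in names(ruleset)) {
    for (kw in normalize_organ_text(ruleset[[cls]])) {
      hit <- undecided & grepl(kw, norm, fixed = TRUE)
      class_name[hit] <- cls
      matched[hit] <- kw
      undecided[hit] <- FALSE
    }
    # keywords within a class are unordered: a later class never overrides
  }
  data.frame(patient_id = as.character(lesion_meta$patient_id),
             lesion_id = as.character(lesion_meta$lesion_id),
             class_name = class_name,
             matched_keyword = matched,
             stringsAsFactors = FALSE)
}

#' One row of metadata per lesion
#'
#' @param records Lesion records (long format).
#' @return A `data.frame` with one row per (patient, lesion): `patient_id`,
#'   `lesion_id`, `organ_text`, `lesion_type`.
#' @export
lesion_metadata <- function(records) {
  key <- paste(records$patient_id, records$lesion_id, sep = "\r")
  first <- !duplicated(key)
  out <- records[first, c("patient_id", "lesion_id", "organ_text", "lesion_type")]
  rownames(out) <- NULL
  out
}

#' Merge rare organ classes into "Other"
#'
#' Classes supported by fewer than `min_patients` distinct patients are
#' relabeled `"Other"`. The three main classes (Liver, Lung, Lymph node) are
#' always reported separately and never merged.
#'
#' @param classified Output of [classify_lesions()].
#' @param min_patients Classes with strictly fewer distinct patients than this
#'   are merged (default 30; a class with exactly `min_patients` patients is
#'   kept).
#' @param protected Classes never merged regardless of size.
#' @return A list with `classified` (relabeled copy) and `report`, a
#'   `data.frame` of the merged classes and their patient counts.
#' @export
merge_rare_classes <- function(classified, min_patients = 30,
                               protected = MAIN_CLASSES) {
  counts <- tapply(classified$patient_id, classified$class_name,
                   function(p) length(unique(p)))
  candidates <- setdiff(names(counts), protected)
  merged <- candidates[counts[candidates] < min_patients]
  out <- classified
  out$class_name[out$class_name %in% merged] <- OTHER_CLASS
  report <- data.frame(class_name = merged,
                       n_patients = as.integer(counts[merged]),
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(classified = out, report = report)
}

#' Class summary table (cTL and iTL counts)
#'
#' For each organ class and patient subset, counts class-related target
#' lesions (cTLs: distinct patients with at least one lesion of the class —
#' each patient contributes one per-class aggregate) and individual target
#' lesions (iTLs: lesion count), in the conventional "cTL (iTL)" layout.
#'
#' @param classified Output of [classify_lesions()] (possibly after
#'   [merge_rare_classes()]).
#' @param subsets Named list of patient-id character vectors; each defines one
#'   column pair of the summary. Defaults to a single `ALL` subset containing
#'   every patient present.
#' @return A `data.frame` with one row per class plus a `Total` row and, per
#'   subset, integer columns `<subset>_ctl` / `<subset>_itl` and a formatted
#'   `<subset>` column `"cTL (iTL)"`.
#' @export
class_summary <- function(classified, subsets = NULL) {
  if (is.null(subsets)) subsets <- list(ALL = unique(classified$patient_id))
  classes <- unique(classified$class_name)
  out <- data.frame(class_name = c(classes, "Total"), stringsAsFactors = FALSE)
  for (sub_name in names(subsets)) {
    sub <- classified[classified$patient_id %in% subsets[[sub_name]], , drop = FALSE]
    ctl <- vapply(classes, function(cl)
      length(unique(sub$patient_id[sub$class_name == cl])), integer(1))
    itl <- vapply(classes, function(cl)
      sum(sub$class_name == cl), integer(1))
    out[[paste0(sub_name, "_ctl")]] <- c(ctl, sum(ctl))
    out[[paste0(sub_name, "_itl")]] <- c(itl, sum(itl))
    out[[sub_name]] <- sprintf("%d (%d)", c(ctl, sum(ctl)), c(itl, sum(itl)))
  }
  out
}
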