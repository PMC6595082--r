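#' Percentage volume change
#'
#' `PVC = (V_FU - V_BL) / V_BL * 100`; negative values indicate atrophy.
#'
#' @param v_bl baseline volume (mm^3), strictly positive.
#' @param v_fu follow-up volume (mm^3).
#' @return PVC in percent (vectorised).
#' @examples
#' pvc(1000, 950)  # -5
#' @export
pvc <- function(v_bl, v_fu) {
  if (any(!is.finite(v_bl)) || any(v_bl <= 0))
    stop("baseline volume must be positive")
  (v_fu - v_bl) / v_bl * 100
}

#' Cohort table of PVC records
#'
#' The tabular atom of the statistics layer: one row per
#' (subject, scan replicate, side, method) measurement with baseline and
#' follow-up volumes and the derived PVC.  Records are never deleted;
#' implausible measurements are flagged by [apply_exclusion()] and masked
#' per-analysis, which keeps the table auditable.
#'
#' @param records data.frame with columns `subject_id`, `group`, `scan`
#'   (`"A"`/`"B"`), `side` (`"L"`/`"R"`), `method`, `v_bl`, `v_fu`, and
#'   optionally `pvc` (recomputed and checked when present), `excluded`,
#'   `exclusion_reason`.
#' @param threshold exclusion threshold in percent (default 25).
#' @param provenance free-form list stored as an attribute (method, dataset
#'   tag, simulation seed, ...).
#' @return A `cohort_table`: the validated data.frame with class and
#'   attributes.
#' @export
cohort_table <- function(records, threshold = 25, provenance = list()) {
  req <- c("subject_id", "group", "scan", "side", "method", "v_bl", "v_fu")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (any(records$v_bl <= 0)) stop("baseline volume must be positive")
  computed <- pvc(records$v_bl, records$v_fu)
  if (!is.null(records$pvc)) {
    if (max(abs(records$pvc - computed)) > 1e-6)
      stop("stored pvc column inconsistent with volumes")
  }
  records$pvc <- computed
  if (is.null(records$excluded)) records$excluded <- FALSE
  if (is.null(records$exclusion_reason)) records$exclusion_reason <- NA_character_
  if (!all(records$scan %in% c("A", "B"))) stop("scan must be 'A' or 'B'")
  if (!all(records$side %in% c("L", "R"))) stop("side must be 'L' or 'R'")
  key <- with(records, paste(subject_id, scan, side, method))
  if (anyDuplicated(key))
    stop("duplicate (subject, scan, side, method) records")
  if (threshold <= 0) stop("'threshold' must be positive")
  structure(records, class = c("cohort_table", "data.frame"),
            threshold = threshold, provenance = provenance)
}

#' Flag implausible PVC records
#'
#' Flags (does not delete) records whose `|PVC|` strictly exceeds the
#' threshold: changes that large in a small structure indicate a failed
#' segmentation or registration rather than biology.  Flag counts per group
#' and scan are logged and attached as attribute `exclusion_summary`.
#'
#' @param table a [cohort_table()].
#' @param threshold percent threshold (default 25; strict inequality, so a
#'   PVC of exactly -25 is kept).
#' @return The table with updated `excluded` / `exclusion_reason` columns.
#' @export
apply_exclusion <- function(table, threshold = 25) {
  stopifnot(inherits(table, "cohort_table"))
  if (threshold <= 0) stop("'threshold' must be positive")
  hit <- abs(table$pvc) > threshold
  table$excluded <- hit
  table$exclusion_reason <- ifelse(
    hit, sprintf("|PVC| > %g%%", threshold), NA_character_)
  summ <- as.data.frame(table(group = table$group[hit], scan = table$scan[hit]))
  if (any(hit))
    log_event("flagged %d of %d records beyond +/-%g%% PVC", sum(hit),
              nrow(table), threshold)
  attr(table, "threshold") <- threshold
  attr(table, "exclusion_summary") <- summ
  table
}

#' Subject-level PVC by left/right averaging
#'
#' For each (method, subject, scan) the left and right structure PVCs are
#' averaged into one subject atrophy rate.  A subject-scan is omitted
#' (and logged) when either side is missing or flagged; nothing is imputed.
#'
#' @param table a [cohort_table()].
#' @return data.frame with columns `method`, `subject_id`, `group`, `scan`,
#'   `pvc` (one row per kept subject-scan).
#' @export
subject_pvc <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  keep <- !table$excluded
  df <- table[keep, , drop = FALSE]
  key <- with(df, interaction(method, subject_id, scan, drop = TRUE))
  n_sides <- tapply(df$side, key, function(s) length(unique(s)))
  groups <- tapply(as.character(df$group), key, `[`, 1)
  subj <- tapply(as.character(df$subject_id), key, `[`, 1)
  meth <- tapply(as.character(df$method), key, `[`, 1)
  scan <- tapply(as.character(df$scan), key, `[`, 1)
  mean_pvc <- tapply(df$pvc, key, mean)
  complete <- n_sides == 2L
  n_drop <- sum(!complete)
  if (n_drop > 0)
    log_event("omitted %d subject-scan(s) with a missing or flagged side", n_drop)
  out <- data.frame(method = meth[complete], subject_id = subj[complete],
                    group = groups[complete], scan = scan[complete],
                    pvc = as.numeric(mean_pvc[complete]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$method, out$subject_id, out$scan), , drop = FALSE]
}

#' Read and write cohort tables as CSV
#'
#' The on-disk schema is UTF-8 CSV with "." as decimal separator and the
#' columns `subject_id, group, scan, side, method, v_bl, v_fu, pvc,
#' excluded, exclusion_reason`.
#'
#' @param path CSV file path.
#' @param threshold exclusion threshold recorded on the loaded table.
#' @return `read_cohort_csv()` returns a [cohort_table()];
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path, threshold = 25) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(df$excluded)) df$excluded <- as.logical(df$excluded)
  cohort_table(df, threshold = threshold,
               provenance = list(source = path))
}

#' @rdname read_cohort_csv
#' @param table a [cohort_table()] to write.
#' @export
write_cohort_csv <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
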