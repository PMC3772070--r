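#' Cohort inclusion specification
#'
#' A cohort is defined by a referral window, a strict lower age bound at
#' referral, and (optionally) a minimum duration of active care measured in
#' whole calendar months from referral.
#'
#' @param referral_window length-2 `Date` (or ISO string) vector,
#'   `start <= end`. Default: calendar years 2008-2011.
#' @param min_age_exclusive patients must be strictly older than this at
#'   referral (default 15, i.e. "aged over 15").
#' @param min_care_months minimum whole calendar months of care from referral
#'   (default 12), or `NULL` to disable the care-duration filter.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(referral_window = c("2008-01-01", "2011-12-31"),
                        min_age_exclusive = 15,
                        min_care_months = 12) {
  w <- as.Date(referral_window)
  stopifnot(length(w) == 2L, !anyNA(w), w[1] <= w[2])
  structure(list(referral_window = w,
                 min_age_exclusive = min_age_exclusive,
                 min_care_months = min_care_months),
            class = "cohort_spec")
}

# Whole calendar months from `from` to `to` (floor), e.g. Jan 15 -> Feb 14 = 0.
months_between <- function(from, to) {
  from <- as.POSIXlt(from); to <- as.POSIXlt(to)
  m <- 12L * (to$year - from$year) + (to$mon - from$mon)
  m - as.integer(to$mday < from$mday)
}

#' Apply cohort inclusion criteria to a patient table
#'
#' Retains patients referred inside the window, strictly older than the age
#' bound at referral, and — when `min_care_months` is set — with at least that
#' many whole calendar months between referral and care end. Patients with an
#' open care episode (`NA` care_end_date) satisfy any care-duration bound.
#' Rows with unparseable dates are dropped with a warning, not an error.
#' Idempotent.
#'
#' @param patients data frame with columns `patient_id`, `age_at_referral`,
#'   `sex`, `marital`, `deprivation_tertile`, `diagnosis`, `referral_date`,
#'   `care_end_date` (dates as `Date` or ISO strings; `care_end_date` may be
#'   `NA` for open episodes).
#' @param spec a [cohort_spec()].
#' @return the filtered patient table, referral/care dates as `Date`.
#' @export
build_cohort <- function(patients, spec = cohort_spec()) {
  stopifnot(is.data.frame(patients), inherits(spec, "cohort_spec"),
            all(c("patient_id", "age_at_referral", "referral_date",
                  "care_end_date") %in% names(patients)))
  as_iso_date <- function(x) {
    if (inherits(x, "Date")) return(x)
    as.Date(as.character(x), format = "%Y-%m-%d")  # NA on malformed input
  }
  ref <- as_iso_date(patients$referral_date)
  end <- as_iso_date(patients$care_end_date)
  if (any(is.na(ref))) {
    warning(sum(is.na(ref)), " patient record(s) with missing/malformed ",
            "referral_date dropped", call. = FALSE)
  }
  patients$referral_date <- ref
  patients$care_end_date <- end
  keep <- !is.na(ref) &
    ref >= spec$referral_window[1] & ref <= spec$referral_window[2] &
    patients$age_at_referral > spec$min_age_exclusive
  if (!is.null(spec$min_care_months)) {
    dur_ok <- is.na(end) | months_between(ref, end) >= spec$min_care_months
    dur_ok[is.na(ref)] <- FALSE
    keep <- keep & dur_ok
  }
  out <- patients[which(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.STATUS_LEVELS <- c("current", "past", "never")

#' Resolve one smoking status per patient
#'
#' Pools dated status records from two sources — structured smoking-status
#' fields and text-derived annotations carried to their document's date —
#' discards records dated before the patient's referral, and keeps the
#' earliest surviving record per patient (the first-record-after-referral
#' rule). Ties on date are broken by source (`tie_break`, default: the
#' structured field wins) and, within a source, by status precedence
#' current > past > never. Patients with no surviving record are absent from
#' the output (the "missing smoking information" state). Order-invariant in
#' the input record order.
#'
#' @param annotations annotation data frame (as from [annotate_corpus()])
#'   *joined to document metadata*: must carry `patient_id` and `date`
#'   columns in addition to `status`. Alternatively any data frame with
#'   `patient_id`, `date`, `status`.
#' @param structured data frame with `patient_id`, `date`, `status`.
#' @param patients patient table with `patient_id`, `referral_date`.
#' @param tie_break `"structured"` (default) or `"text"`: which source wins a
#'   same-date tie.
#' @return data frame `patient_id`, `status`, `date`, `source` with at most
#'   one row per patient.
#' @export
resolve_patient_status <- function(annotations, structured, patients,
                                   tie_break = c("structured", "text")) {
  tie_break <- match.arg(tie_break)
  recs <- pool_status_records(annotations, structured)
  stopifnot(all(c("patient_id", "referral_date") %in% names(patients)))
  ref <- data.frame(patient_id = as.character(patients$patient_id),
                    referral_date = as.Date(patients$referral_date),
                    stringsAsFactors = FALSE)
  recs <- merge(recs, ref, by = "patient_id")
  recs <- recs[!is.na(recs$date) & recs$date >= recs$referral_date, ,
               drop = FALSE]
  if (nrow(recs) == 0L) {
    return(data.frame(patient_id = character(0), status = character(0),
                      date = as.Date(character(0)), source = character(0),
                      stringsAsFactors = FALSE))
  }
  src_rank <- if (tie_break == "structured") c(structured = 1L, text = 2L)
              else c(structured = 2L, text = 1L)
  o <- order(recs$patient_id, recs$date, src_rank[recs$source],
             match(recs$status, .STATUS_LEVELS))
  recs <- recs[o, , drop = FALSE]
  recs <- recs[!duplicated(recs$patient_id),
               c("patient_id", "status", "date", "source"), drop = FALSE]
  rownames(recs) <- NULL
  recs
}

pool_status_records <- function(annotations, structured) {
  pieces <- list()
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    stopifnot(all(c("patient_id", "date", "status") %in% names(annotations)))
    pieces$text <- data.frame(
      patient_id = as.character(annotations$patient_id),
      date = as.Date(annotations$date),
      status = as.character(annotations$status),
      source = "text", stringsAsFactors = FALSE)
  }
  if (!is.null(structured) && nrow(structured) > 0L) {
    stopifnot(all(c("patient_id", "date", "status") %in% names(structured)))
    pieces$structured <- data.frame(
      patient_id = as.character(structured$patient_id),
      date = as.Date(structured$date),
      status = as.character(structured$status),
      source = "structured", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(pieces, list(
    data.frame(patient_id = character(0), date = as.Date(character(0)),
               status = character(0), source = character(0),
               stringsAsFactors = FALSE))))
  bad <- !out$status %in% .STATUS_LEVELS
  if (any(bad)) stop("invalid smoking status: ",
                     paste(unique(out$status[bad]), collapse = ", "),
                     call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Smoking-status coverage by information source
#'
#' Computes, for one cohort, how many patients have any resolved smoking
#' status (a) using the structured field alone and (b) using structured plus
#' text-derived records, with percentages relative to cohort size.
#'
#' @param cohort patient table (after [build_cohort()]).
#' @param annotations,structured as in [resolve_patient_status()].
#' @param tie_break passed through.
#' @return data frame with rows `structured_only` and `structured_plus_text`,
#'   columns `n_with_status`, `n_cohort`, `percent`.
#' @export
coverage_by_source <- function(cohort, annotations, structured,
                               tie_break = "structured") {
  if (nrow(cohort) == 0L) {
    stop("empty cohort: coverage percentages undefined", call. = FALSE)
  }
  ids <- as.character(cohort$patient_id)
  res_s <- resolve_patient_status(NULL, structured, cohort, tie_break)
  res_b <- resolve_patient_status(annotations, structured, cohort, tie_break)
  n_s <- sum(unique(res_s$patient_id) %in% ids)
  n_b <- sum(unique(res_b$patient_id) %in% ids)
  data.frame(
    source = c("structured_only", "structured_plus_text"),
    n_with_status = c(n_s, n_b),
    n_cohort = nrow(cohort),
    percent = round(100 * c(n_s, n_b) / nrow(cohort), 1),
    stringsAsFactors = FALSE)
}

#' Smoking-status coverage by referral year
#'
#' Per referral year: cohort size and percentage of patients with any
#' resolved status under the structured-only and combined regimes, plus a
#' Cochran-Armitage linear-trend p-value across years for each regime
#' (requires >= 3 years with patients).
#'
#' @inheritParams coverage_by_source
#' @param years integer vector of referral years to tabulate; years with no
#'   patients are omitted with a warning.
#' @return list with `table` (per-year data frame) and `trend` (named vector
#'   of trend p-values, `NA` when fewer than 3 usable years).
#' @export
coverage_by_year <- function(cohort, annotations, structured,
                             years = NULL, tie_break = "structured") {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  yr <- as.integer(format(as.Date(cohort$referral_date), "%Y"))
  if (is.null(years)) years <- sort(unique(yr))
  res_s <- resolve_patient_status(NULL, structured, cohort, tie_break)
  res_b <- resolve_patient_status(annotations, structured, cohort, tie_break)
  rows <- lapply(years, function(y) {
    sub <- cohort$patient_id[yr == y]
    if (length(sub) == 0L) {
      warning("year ", y, " has no patients; row omitted", call. = FALSE)
      return(NULL)
    }
    ks <- sum(res_s$patient_id %in% sub)
    kb <- sum(res_b$patient_id %in% sub)
    data.frame(year = y, n = length(sub),
               n_structured = ks,
               pct_structured = round(100 * ks / length(sub), 1),
               n_combined = kb,
               pct_combined = round(100 * kb / length(sub), 1))
  })
  tab <- do.call(rbind, rows)
  trend <- c(structured = NA_real_, combined = NA_real_)
  if (!is.null(tab) && nrow(tab) >= 3L) {
    trend["structured"] <- cochran_armitage(
      rbind(tab$n_structured, tab$n - tab$n_structured))$p.value
    trend["combined"] <- cochran_armitage(
      rbind(tab$n_combined, tab$n - tab$n_combined))$p.value
  }
  list(table = tab, trend = trend)
}
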