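# Exposure construction: prescription durations, per-medicine coverage
# intervals, and the windowed maximum overlapping prescription count.

#' Default duration rules
#'
#' Loads the bundled formulation-class duration rule table
#' (`formulation_class`, `default_days`, `cap_days`). The default assigns 28
#' days to common formulation classes with a 183-day cap; both are data, not
#' constants, and users can supply their own table.
#'
#' @param path Optional path to an alternative rule table.
#' @return A `data.table` with columns `formulation_class`, `default_days`,
#'   `cap_days`.
#' @export
default_duration_rules <- function(path = mr_extdata("duration_rules.csv")) {
  rules <- data.table::fread(path)
  stopifnot(all(c("formulation_class", "default_days", "cap_days") %in%
                  names(rules)))
  rules
}

#' Estimate prescription durations
#'
#' For each prescription row the intended duration in days is
#' `round(quantity / daily_dose)` clamped to `[1, cap]` when both fields are
#' present and positive. Rows where this is not computable fall back, in
#' order, to (1) the median computed duration for the same medicine
#' (substance + formulation) across the supplied dataset, then (2) the
#' formulation-class default from the rule table. A row with no computable
#' duration and a formulation absent from the rule table is a configuration
#' error.
#'
#' @param rx Prescriptions `data.table` (after [filter_medicinal()]).
#' @param rules Duration rule table; see [default_duration_rules()].
#' @return Integer vector of durations (days), aligned with `rx` rows.
#' @export
estimate_duration <- function(rx, rules = default_duration_rules()) {
  rx <- data.table::as.data.table(rx)
  n <- nrow(rx)
  if (n == 0L) return(integer(0))
  key <- mr_medicine_key(rx$substance, rx$formulation)
  cap <- rules$cap_days[match(mr_by_unique(rx$formulation,
                                           function(x) tolower(trimws(x))),
                              rules$formulation_class)]
  cap[is.na(cap)] <- max(rules$cap_days)
  ok <- !is.na(rx$quantity) & !is.na(rx$daily_dose) &
    rx$quantity > 0 & rx$daily_dose > 0
  dur <- rep(NA_integer_, n)
  dur[ok] <- pmin(pmax(as.integer(round(rx$quantity[ok] / rx$daily_dose[ok])),
                       1L), as.integer(cap[ok]))
  if (any(!ok)) {
    med_median <- data.table::data.table(med_key = key[ok], dur = dur[ok])[
      , list(med = as.integer(round(stats::median(dur)))), by = "med_key"]
    fb1 <- med_median$med[match(key[!ok], med_median$med_key)]
    dur[!ok] <- fb1
    still <- is.na(dur)
    if (any(still)) {
      cls <- tolower(trimws(rx$formulation[still]))
      fb2 <- rules$default_days[match(cls, rules$formulation_class)]
      if (anyNA(fb2)) {
        stop("configuration error: no duration rule for formulation(s): ",
             paste(unique(cls[is.na(fb2)]), collapse = ", "))
      }
      dur[still] <- as.integer(fb2)
    }
    dur <- pmin(pmax(dur, 1L), as.integer(cap))
  }
  dur
}

# Merge sorted closed intervals per (patient, medicine); overlapping or
# adjacent (gap of zero days) intervals become one. Works on integer days.
mr_merge_intervals <- function(dt) {
  if (nrow(dt) == 0L) return(dt)
  data.table::setorder(dt, patient_id, medicine, start, end)
  dt[, run_end := cummax(end), by = c("patient_id", "medicine")]
  dt[, grp := cumsum(start > data.table::shift(run_end, fill = -.Machine$integer.max) + 1L),
     by = c("patient_id", "medicine")]
  out <- dt[, list(start = min(start), end = max(end),
                   source_repeat = any(source_repeat)),
            by = c("patient_id", "medicine", "grp")]
  out[, grp := NULL]
  out
}

#' Build per-medicine coverage intervals
#'
#' Each prescription issue covers the closed day interval
#' `[issue_date, issue_date + duration - 1]`. Per patient and medicine,
#' overlapping and adjacent intervals are merged so that chained refills form
#' one continuous covered episode. An interval is repeat-sourced when any
#' contributing issue was flagged as a repeat prescription.
#'
#' @param rx Prescriptions `data.table` (any number of patients); rows in BNF
#'   chapters 14/15 or matching the non-medicinal list should be removed with
#'   [filter_medicinal()] first.
#' @param rules Duration rule table.
#' @return `data.table` with columns `patient_id`, `medicine`, `start_date`,
#'   `end_date` (class `Date`), `source_repeat`, sorted by
#'   (patient, medicine, start).
#' @export
build_coverage <- function(rx, rules = default_duration_rules()) {
  rx <- data.table::as.data.table(rx)
  if (nrow(rx) == 0L) {
    return(data.table::data.table(patient_id = character(0),
                                  medicine = character(0),
                                  start_date = as.Date(character(0)),
                                  end_date = as.Date(character(0)),
                                  source_repeat = logical(0)))
  }
  dur <- estimate_duration(rx, rules)
  dt <- data.table::data.table(
    patient_id = rx$patient_id,
    medicine = mr_medicine_key(rx$substance, rx$formulation),
    start = as.integer(rx$issue_date),
    end = as.integer(rx$issue_date) + dur - 1L,
    source_repeat = isTRUE_vec(rx$repeat_flag))
  out <- mr_merge_intervals(dt)
  out[, `:=`(start_date = as.Date(start, origin = "1970-01-01"),
             end_date = as.Date(end, origin = "1970-01-01"))]
  data.table::setorder(out, patient_id, medicine, start_date)
  out[, list(patient_id, medicine, start_date, end_date, source_repeat)]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Maximum overlapping prescription count in a window
#'
#' The prescription count on a given day is the number of distinct medicines
#' whose coverage contains that day; this returns the maximum daily count over
#' a closed window, computed by an endpoint sweep (intervals clipped to the
#' window, per-medicine re-merged for distinctness, then a running count over
#' sorted endpoints).
#'
#' @param cov Coverage intervals for one patient ([build_coverage()] output).
#' @param window_start,window_end Closed window bounds (`Date` or ISO string).
#' @param repeat_only Drop intervals not sourced from repeat prescriptions
#'   before counting.
#' @return Non-negative integer.
#' @export
max_overlap_count <- function(cov, window_start, window_end,
                              repeat_only = FALSE) {
  counts <- max_overlap_by_patient(cov, window_start, window_end, repeat_only)
  if (nrow(counts) == 0L) return(0L)
  if (nrow(counts) > 1L) stop("cov contains more than one patient; use max_overlap_by_patient()")
  counts$max_count[1L]
}

#' Maximum overlapping prescription count, per patient
#'
#' Vectorised form of [max_overlap_count()] over a multi-patient coverage
#' table. Patients with no coverage intersecting the window are absent from
#' the result (their count is 0).
#'
#' @inheritParams max_overlap_count
#' @return `data.table(patient_id, max_count)`.
#' @export
max_overlap_by_patient <- function(cov, window_start, window_end,
                                   repeat_only = FALSE) {
  ws <- as.integer(as.Date(window_start))
  we <- as.integer(as.Date(window_end))
  if (is.na(ws) || is.na(we) || ws > we) {
    stop("invalid window: start must be <= end")
  }
  cov <- data.table::as.data.table(cov)
  empty <- data.table::data.table(patient_id = character(0),
                                  max_count = integer(0))
  if (nrow(cov) == 0L) return(empty)
  dt <- data.table::data.table(patient_id = cov$patient_id,
                               medicine = cov$medicine,
                               start = pmax(as.integer(cov$start_date), ws),
                               end = pmin(as.integer(cov$end_date), we),
                               source_repeat = cov$source_repeat)
  if (repeat_only) dt <- dt[isTRUE_vec(source_repeat)]
  dt <- dt[start <= end]
  if (nrow(dt) == 0L) return(empty)
  dt <- mr_merge_intervals(dt)
  ev <- data.table::rbindlist(list(
    dt[, list(patient_id, pos = start, delta = 1L)],
    dt[, list(patient_id, pos = end + 1L, delta = -1L)]))
  ev <- ev[, list(delta = sum(delta)), by = c("patient_id", "pos")]
  data.table::setorder(ev, patient_id, pos)
  ev[, list(max_count = max(cumsum(delta))), by = "patient_id"]
}

#' Band a prescription count
#'
#' Maps counts into the categorical bands used for baseline description and
#' modelling: 0, 1, 2-4, 5-9, 10-14, 15-19, 20+.
#'
#' @param count Non-negative integer vector.
#' @return Factor with the band levels.
#' @export
count_band <- function(count) {
  if (any(is.na(count)) || any(count < 0)) {
    stop("count must be non-negative")
  }
  cut(count, breaks = c(-0.5, 0.5, 1.5, 4.5, 9.5, 14.5, 19.5, Inf),
      labels = mr_levels$count_band)
}

#' Medicines with ongoing coverage on a date
#'
#' A medicine is ongoing on a date when one of its (closed) coverage
#' intervals contains the date; intervals ending the day before do not count.
#'
#' @param cov Coverage table (any number of patients).
#' @param date The reference date.
#' @return `data.table(patient_id, medicine)` of ongoing medicines.
#' @export
ongoing_at <- function(cov, date) {
  d <- as.integer(as.Date(date))
  cov <- data.table::as.data.table(cov)
  out <- cov[as.integer(start_date) <= d & as.integer(end_date) >= d,
             list(patient_id, medicine)]
  unique(out)
}

#' Per-patient count of medicines ongoing on a date
#'
#' @inheritParams ongoing_at
#' @return `data.table(patient_id, baseline_count)`; patients with zero
#'   ongoing medicines are absent.
#' @export
baseline_counts <- function(cov, date) {
  ongoing_at(cov, date)[, list(baseline_count = .N), by = "patient_id"]
}
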