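# Medication-review identification and classification.

#' Find medication-review events
#'
#' Selects clinical events whose code appears in a review code list and whose
#' date falls inside the given calendar year, carrying the consultation-type
#' and staff-role classification. Each returned review is marked
#' `conservative_eligible` when it would survive the conservative review
#' definition: recorded during a face-to-face or telephone consultation and
#' coded with a code not flagged as a review of specific medicines or
#' conditions.
#'
#' @param events Events `data.table` (see [read_table()]).
#' @param review_codelist An `mr_codelist` of kind `"review"`.
#' @param year Calendar year of interest (default 2019).
#' @return `data.table(patient_id, review_date, code, consultation_type,
#'   staff_role, conservative_eligible)` sorted by (patient, date, code).
#' @export
find_reviews <- function(events, review_codelist, year = 2019L) {
  stopifnot(inherits(review_codelist, "mr_codelist"),
            review_codelist$kind == "review")
  ev <- data.table::as.data.table(events)
  idx <- match(ev$code, review_codelist$entries$code)
  keep <- !is.na(idx) & !is.na(ev$event_date) &
    as.integer(format(ev$event_date, "%Y")) == as.integer(year)
  out <- ev[keep, list(patient_id, review_date = event_date, code,
                       consultation_type, staff_role)]
  out[, conservative_eligible :=
        consultation_type %in% c("face_to_face", "telephone") &
        !review_codelist$entries$conservative_excluded[
          match(code, review_codelist$entries$code)]]
  out[, .ord := seq_len(.N)]
  data.table::setorder(out, patient_id, review_date, code, .ord)
  out[, .ord := NULL]
  out[]
}

#' First review per patient
#'
#' The earliest-dated review per patient; same-day ties are broken by code
#' string, then input order, so the result is invariant to shuffling the
#' input.
#'
#' @param reviews Output of [find_reviews()] (or a subset of it).
#' @return One row per patient with a review.
#' @export
first_review <- function(reviews) {
  rv <- data.table::as.data.table(reviews)
  if (nrow(rv) == 0L) return(rv)
  rv <- data.table::copy(rv)
  rv[, .ord := seq_len(.N)]
  data.table::setorder(rv, patient_id, review_date, code, .ord)
  out <- rv[, utils::head(.SD, 1L), by = "patient_id"]
  out[, .ord := NULL]
  out[]
}

#' Apply the conservative review definition
#'
#' Keeps reviews recorded during face-to-face or telephone consultations whose
#' code is not flagged as a review for specific medicines/conditions. The
#' first review should be re-derived within the returned subset.
#'
#' @param reviews Output of [find_reviews()].
#' @return Subset of `reviews`.
#' @export
conservative_filter <- function(reviews) {
  rv <- data.table::as.data.table(reviews)
  rv[isTRUE_vec(conservative_eligible)]
}
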