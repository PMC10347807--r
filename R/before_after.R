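# Before/after comparison of repeat-prescribed medicines around a review.

#' Window specification around a review
#'
#' Named window pairs, as day offsets relative to the review date `R`. The
#' review day itself belongs to the "after" window (prescriptions issued at
#' the review consultation are consequences of it). The named pairs are:
#' `3m3m` = \[R-91, R-1\] vs \[R, R+91\]; `6m6m` = \[R-183, R-1\] vs
#' \[R, R+183\]; `3m1to4m` = \[R-91, R-1\] vs \[R+30, R+121\]; `1m1m` =
#' \[R-30, R-1\] vs \[R, R+30\].
#'
#' @param name One of `"3m3m"`, `"6m6m"`, `"3m1to4m"`, `"1m1m"`.
#' @param review_day_in_after If `FALSE`, the before window ends on `R` and
#'   the after window starts on `R+1` (sensitivity toggle).
#' @return List with `name`, `before`, `after` (integer offset pairs).
#' @export
window_spec <- function(name = c("3m3m", "6m6m", "3m1to4m", "1m1m"),
                        review_day_in_after = TRUE) {
  name <- match.arg(name)
  spec <- switch(name,
    "3m3m"    = list(before = c(-91L, -1L), after = c(0L, 91L)),
    "6m6m"    = list(before = c(-183L, -1L), after = c(0L, 183L)),
    "3m1to4m" = list(before = c(-91L, -1L), after = c(30L, 121L)),
    "1m1m"    = list(before = c(-30L, -1L), after = c(0L, 30L)))
  if (!review_day_in_after) {
    spec$before[2L] <- 0L
    if (spec$after[1L] == 0L) spec$after[1L] <- 1L
  }
  spec$name <- name
  stopifnot(spec$before[2L] < spec$after[1L] || spec$before[2L] <= 0L)
  spec
}

# Per-patient maximum overlap count in a window expressed relative to each
# patient's review date. cov_rel has integer columns rstart/rend (days
# relative to the review).
mr_max_count_rel <- function(cov_rel, off) {
  dt <- data.table::data.table(patient_id = cov_rel$patient_id,
                               medicine = cov_rel$medicine,
                               start = pmax(cov_rel$rstart, off[1L]),
                               end = pmin(cov_rel$rend, off[2L]),
                               source_repeat = cov_rel$source_repeat)
  dt <- dt[start <= end]
  if (nrow(dt) == 0L) {
    return(data.table::data.table(patient_id = character(0),
                                  max_count = integer(0)))
  }
  dt <- mr_merge_intervals(dt)
  ev <- data.table::rbindlist(list(
    dt[, list(patient_id, pos = start, delta = 1L)],
    dt[, list(patient_id, pos = end + 1L, delta = -1L)]))
  ev <- ev[, list(delta = sum(delta)), by = c("patient_id", "pos")]
  data.table::setorder(ev, patient_id, pos)
  ev[, list(max_count = max(cumsum(delta))), by = "patient_id"]
}

#' Per-review change records
#'
#' For each patient with a first review, derives the sets of medicines whose
#' coverage intersects the before and after windows, the stopped / started /
#' continued classification, and the maximum prescription count in each
#' window. By default only repeat-sourced coverage is considered, to reduce
#' noise from short-course medicines. Patients whose follow-up ends before
#' the end of the after window are flagged `insufficient_followup` and should
#' be excluded from summaries.
#'
#' @param cov Coverage table from [build_coverage()].
#' @param first_reviews Output of [first_review()].
#' @param eligible Patient table carrying `death_date`, `transfer_out_date`
#'   and `last_collection_date` (from [select_population()]).
#' @param spec Window specification from [window_spec()].
#' @param repeat_only Restrict to repeat-sourced coverage (default `TRUE`).
#' @param study_end Last date with data.
#' @return `data.table` with one row per reviewed patient: `patient_id`,
#'   `review_date`, list columns `before_set`, `after_set`, `stopped`,
#'   `started`, `continued`, integer `count_before`, `count_after`, `delta`,
#'   and `excluded_reason` (`"none"` or `"insufficient_followup"` at this
#'   stage).
#' @export
change_records <- function(cov, first_reviews, eligible,
                           spec = window_spec("3m3m"), repeat_only = TRUE,
                           study_end = mr_study_end_default) {
  fr <- data.table::as.data.table(first_reviews)
  el <- data.table::as.data.table(eligible)
  cov <- data.table::as.data.table(cov)
  fr <- fr[patient_id %in% el$patient_id]
  if (nrow(fr) == 0L) {
    return(data.table::data.table(patient_id = character(0)))
  }
  idx <- match(fr$patient_id, el$patient_id)
  fu_end <- pmin(el$death_date[idx], el$transfer_out_date[idx],
                 el$last_collection_date[idx], as.Date(study_end),
                 na.rm = TRUE)
  rec <- data.table::data.table(
    patient_id = fr$patient_id,
    review_date = fr$review_date,
    excluded_reason = data.table::fifelse(
      as.integer(fu_end - fr$review_date) < spec$after[2L],
      "insufficient_followup", "none"))

  cj <- merge(cov, rec[, list(patient_id, review_date)], by = "patient_id")
  if (repeat_only) cj <- cj[isTRUE_vec(source_repeat)]
  cj[, `:=`(rstart = as.integer(start_date - review_date),
            rend = as.integer(end_date - review_date))]

  in_b <- cj[rstart <= spec$before[2L] & rend >= spec$before[1L],
             list(patient_id, medicine)]
  in_a <- cj[rstart <= spec$after[2L] & rend >= spec$after[1L],
             list(patient_id, medicine)]
  in_b <- unique(in_b); in_a <- unique(in_a)
  bs <- in_b[, list(set = list(sort(medicine))), by = "patient_id"]
  as_ <- in_a[, list(set = list(sort(medicine))), by = "patient_id"]
  rec[, before_set := bs$set[match(patient_id, bs$patient_id)]]
  rec[, after_set := as_$set[match(patient_id, as_$patient_id)]]
  none <- list(character(0))
  rec[vapply(before_set, is.null, logical(1)), before_set := none]
  rec[vapply(after_set, is.null, logical(1)), after_set := none]
  rec[, stopped := Map(setdiff, before_set, after_set)]
  rec[, started := Map(setdiff, after_set, before_set)]
  rec[, continued := Map(intersect, before_set, after_set)]

  cb <- mr_max_count_rel(cj, spec$before)
  ca <- mr_max_count_rel(cj, spec$after)
  rec[, count_before := cb$max_count[match(patient_id, cb$patient_id)]]
  rec[, count_after := ca$max_count[match(patient_id, ca$patient_id)]]
  rec[is.na(count_before), count_before := 0L]
  rec[is.na(count_after), count_after := 0L]
  rec[, delta := count_after - count_before]
  rec[]
}

#' Classify medicines as stopped, started or continued
#'
#' Plain set algebra on two medicine sets: stopped = before only, started =
#' after only, continued = both.
#'
#' @param before_set,after_set Character vectors of medicine keys.
#' @return List with sorted `stopped`, `started`, `continued`.
#' @export
classify_changes <- function(before_set, after_set) {
  list(stopped = sort(setdiff(before_set, after_set)),
       started = sort(setdiff(after_set, before_set)),
       continued = sort(intersect(before_set, after_set)))
}

#' Rank the medicines most frequently stopped and/or started
#'
#' Counts, per medicine, the numbers of people who stopped, started or
#' continued it around their review, and returns the top `k` medicines by
#' stopped + started count (ties broken alphabetically by medicine key).
#' Records flagged `insufficient_followup` are ignored.
#'
#' @param records Output of [change_records()].
#' @param k Number of medicines to return (default 20).
#' @param formulation Optional formulation restriction (e.g. `"tablet"`).
#' @return `data.table(medicine, n_stopped, n_started, n_continued,
#'   n_changed)` sorted by rank.
#' @export
rank_top_changed <- function(records, k = 20L, formulation = NULL) {
  if (k < 1L) stop("k must be >= 1")
  rec <- data.table::as.data.table(records)
  rec <- rec[excluded_reason != "insufficient_followup"]
  unroll <- function(col, status) {
    sets <- rec[[col]]
    data.table::data.table(patient_id = rep(rec$patient_id, lengths(sets)),
                           medicine = as.character(unlist(sets)),
                           status = status)
  }
  long <- data.table::rbindlist(list(unroll("stopped", "stopped"),
                                     unroll("started", "started"),
                                     unroll("continued", "continued")))
  if (nrow(long) == 0L) {
    return(data.table::data.table(medicine = character(0),
                                  n_stopped = integer(0),
                                  n_started = integer(0),
                                  n_continued = integer(0),
                                  n_changed = integer(0)))
  }
  if (!is.null(formulation)) {
    long <- long[sub("^.*\\|", "", medicine) == tolower(formulation)]
  }
  tab <- data.table::dcast(long[, list(n = .N),
                                by = c("medicine", "status")],
                           medicine ~ status, value.var = "n", fill = 0L)
  for (col in c("stopped", "started", "continued")) {
    if (!col %in% names(tab)) data.table::set(tab, j = col, value = 0L)
  }
  data.table::setnames(tab, c("stopped", "started", "continued"),
                       c("n_stopped", "n_started", "n_continued"))
  tab[, n_changed := n_stopped + n_started]
  data.table::setorder(tab, -n_changed, medicine)
  utils::head(tab[, list(medicine, n_stopped, n_started, n_continued,
                         n_changed)], k)
}

#' Apply the count-change exclusion rules
#'
#' Starting from the change records with adequate follow-up, first drops
#' people with no (repeat) prescriptions in the before window
#' (`count_before == 0`), then computes the mean and SD of the count change
#' over the remainder and drops records more than three SDs from the mean.
#' The screen is applied once, not iterated. A degenerate SD of zero drops
#' nothing.
#'
#' @param records Output of [change_records()].
#' @return List with `retained` (records entering the change analysis),
#'   `tally` (named counts per exclusion reason plus retained), `mean` and
#'   `sd` of delta over the post-first-exclusion set.
#' @export
delta_counts <- function(records) {
  rec <- data.table::copy(data.table::as.data.table(records))
  if (nrow(rec) == 0L) {
    return(list(retained = rec,
                tally = c(insufficient_followup = 0L,
                          no_prescriptions_before = 0L,
                          extreme_delta = 0L, retained = 0L),
                mean = NA_real_, sd = NA_real_))
  }
  rec[excluded_reason == "none" & count_before == 0L,
      excluded_reason := "no_prescriptions_before"]
  pool <- rec[excluded_reason == "none"]
  m <- mean(pool$delta)
  s <- stats::sd(pool$delta)
  if (is.finite(s) && s > 0) {
    rec[excluded_reason == "none" & abs(delta - m) > 3 * s,
        excluded_reason := "extreme_delta"]
  }
  retained <- rec[excluded_reason == "none"]
  tally <- c(insufficient_followup =
               sum(rec$excluded_reason == "insufficient_followup"),
             no_prescriptions_before =
               sum(rec$excluded_reason == "no_prescriptions_before"),
             extreme_delta = sum(rec$excluded_reason == "extreme_delta"),
             retained = nrow(retained))
  list(retained = retained, tally = tally, mean = m, sd = s)
}
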