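# Cohort construction: eligibility, censoring, baseline covariates.

mr_baseline_default <- as.Date("2019-01-01")
mr_study_end_default <- as.Date("2019-12-31")

#' Select the eligible population
#'
#' Applies the eligibility rules for the 65-plus cohort: aged 65 or over in
#' the baseline year, recorded sex male or female, at least one year of
#' up-to-standard follow-up before baseline (both registration and
#' up-to-standard dates on/before one year pre-baseline), and active at
#' baseline (no death or transfer-out before baseline, practice still
#' collecting data at baseline). When `baseline_counts` is supplied, patients
#' with no ongoing prescription at baseline are additionally excluded (the
#' incidence-analysis population).
#'
#' @param patients,practices Typed tables from [read_table()].
#' @param baseline Baseline date (default 2019-01-01).
#' @param baseline_counts Optional `data.table(patient_id, baseline_count)`
#'   from [baseline_counts()]; patients absent from it count as zero.
#' @return List with `eligible` (patients joined with practice columns
#'   `region`, `practice_townsend`, `last_collection_date`) and `counts`, a
#'   named integer vector of flow counts (total, each exclusion, retained).
#' @export
select_population <- function(patients, practices,
                              baseline = mr_baseline_default,
                              baseline_counts = NULL) {
  baseline <- as.Date(baseline)
  pt <- data.table::as.data.table(patients)
  pr <- data.table::as.data.table(practices)
  unknown <- setdiff(pt$practice_id, pr$practice_id)
  if (length(unknown)) {
    stop("integrity error: patients reference unknown practice(s): ",
         paste(unknown, collapse = ", "))
  }
  pt <- merge(pt,
              pr[, list(practice_id, region,
                        practice_townsend = townsend_quintile,
                        last_collection_date)],
              by = "practice_id", sort = FALSE)
  yr <- as.integer(format(baseline, "%Y"))
  uts_cut <- baseline - 365L
  age_ok <- !is.na(pt$birth_year) & (yr - pt$birth_year) >= 65L
  sex_ok <- pt$sex %in% c("male", "female")
  uts_ok <- !is.na(pt$uts_date) & !is.na(pt$registration_date) &
    pmax(pt$uts_date, pt$registration_date) <= uts_cut
  active <- (is.na(pt$death_date) | pt$death_date >= baseline) &
    (is.na(pt$transfer_out_date) | pt$transfer_out_date >= baseline) &
    pt$last_collection_date >= baseline
  base_ok <- age_ok & sex_ok & uts_ok & active
  counts <- c(total = nrow(pt),
              excluded_age = sum(!age_ok),
              excluded_sex = sum(age_ok & !sex_ok),
              excluded_uts = sum(age_ok & sex_ok & !uts_ok),
              excluded_not_active = sum(age_ok & sex_ok & uts_ok & !active),
              eligible = sum(base_ok))
  eligible <- pt[base_ok]
  if (!is.null(baseline_counts)) {
    bc <- data.table::as.data.table(baseline_counts)
    n0 <- eligible[!patient_id %in% bc[baseline_count > 0L, patient_id]]
    counts <- c(counts,
                excluded_no_ongoing = nrow(n0),
                study_population = nrow(eligible) - nrow(n0))
    eligible <- eligible[!patient_id %in% n0$patient_id]
  }
  list(eligible = eligible, counts = counts)
}

#' Censor follow-up at first review or study exit
#'
#' Follow-up runs from baseline to the earliest of death, transfer out of the
#' practice, the practice's last collection date, the first medication review
#' and the study end. The event indicator is true when the first review
#' attains the minimum; a review on the same day as a censoring event counts
#' as an event.
#'
#' @param eligible Output `eligible` table from [select_population()].
#' @param first_reviews Output of [first_review()].
#' @param baseline,study_end Study window bounds.
#' @return `eligible` with added columns `entry_date`, `exit_date`, `event`,
#'   `time_days`, `review_date` (NA when unobserved in follow-up).
#' @export
censor_followup <- function(eligible, first_reviews,
                            baseline = mr_baseline_default,
                            study_end = mr_study_end_default) {
  baseline <- as.Date(baseline); study_end <- as.Date(study_end)
  el <- data.table::copy(data.table::as.data.table(eligible))
  fr <- data.table::as.data.table(first_reviews)
  rv <- if (nrow(fr)) fr$review_date[match(el$patient_id, fr$patient_id)]
        else as.Date(rep(NA, nrow(el)))
  censor <- pmin(el$death_date, el$transfer_out_date,
                 el$last_collection_date, study_end, na.rm = TRUE)
  event <- !is.na(rv) & rv <= censor
  exit <- data.table::fifelse(event, rv, censor)
  el[, `:=`(entry_date = baseline,
            exit_date = exit,
            event = event,
            time_days = as.integer(exit - baseline),
            review_date = data.table::fifelse(event, rv, as.Date(NA)))]
  if (any(el$time_days < 0L)) stop("negative follow-up time; check input dates")
  el[]
}

#' Baseline covariates
#'
#' Derives the baseline covariate vector per eligible patient, all defined
#' with respect to the baseline date: 10-year age band; sex; ethnicity;
#' Townsend quintile (person-level where available, otherwise
#' practice-level); practice region; care-home flag; medication review in the
#' previous calendar year; baseline prescription count and band (medicines
#' ongoing on the baseline date); diagnosis flags (any matching code ever
#' recorded on/before baseline); and drug-group flags (any matching
#' prescription issued on baseline or in the 183 days before it).
#'
#' @param eligible Eligible patients (with practice columns) from
#'   [select_population()].
#' @param events Events table.
#' @param prescriptions Prescriptions table (after [filter_medicinal()]).
#' @param cov Coverage table from [build_coverage()].
#' @param codelists Named list of `mr_codelist` objects; kinds `diagnosis`
#'   and `drug_group` become flag columns `diag_<name>` / `drug_<name>`.
#' @param review_codelist Review code list used for the previous-year review
#'   flag.
#' @param baseline Baseline date.
#' @return `eligible` with added covariate columns.
#' @export
baseline_covariates <- function(eligible, events, prescriptions, cov,
                                codelists = list(),
                                review_codelist = NULL,
                                baseline = mr_baseline_default) {
  baseline <- as.Date(baseline)
  el <- data.table::copy(data.table::as.data.table(eligible))
  ev <- data.table::as.data.table(events)
  rx <- data.table::as.data.table(prescriptions)
  yr <- as.integer(format(baseline, "%Y"))

  age <- yr - el$birth_year
  el[, age_band := cut(age, breaks = c(64, 74, 84, 94, Inf),
                       labels = mr_levels$age_band)]
  el[, townsend := factor(
    data.table::fifelse(isTRUE_vec(el$person_level_townsend) &
                          !is.na(el$townsend_quintile),
                        el$townsend_quintile, el$practice_townsend),
    levels = 1:5)]

  bc <- baseline_counts(cov, baseline)
  el[, baseline_count := bc$baseline_count[match(patient_id, bc$patient_id)]]
  el[is.na(baseline_count), baseline_count := 0L]
  el[, baseline_count_band := count_band(baseline_count)]

  if (!is.null(review_codelist)) {
    prev <- ev[code %in% review_codelist$entries$code &
                 !is.na(event_date) &
                 as.integer(format(event_date, "%Y")) == yr - 1L, patient_id]
    el[, prior_year_review := patient_id %in% prev]
  }

  rx_window <- rx[!is.na(issue_date) & issue_date >= baseline - 183L &
                    issue_date <= baseline]
  rx_sub <- mr_by_unique(rx_window$substance,
                         function(x) gsub("\\s+", " ", trimws(tolower(x))))
  for (nm in names(codelists)) {
    cl <- codelists[[nm]]
    if (!inherits(cl, "mr_codelist")) stop("config error: unknown code list: ", nm)
    if (cl$kind == "diagnosis") {
      hits <- ev[code %in% cl$entries$code & !is.na(event_date) &
                   event_date <= baseline, patient_id]
      data.table::set(el, j = paste0("diag_", cl$name),
                      value = el$patient_id %in% hits)
    } else if (cl$kind == "drug_group") {
      terms <- tolower(cl$entries$code)
      hit <- mr_by_unique(rx_sub, function(ss) {
        Reduce(`|`, lapply(terms, function(t) grepl(t, ss, fixed = TRUE)),
               init = logical(length(ss)))
      })
      data.table::set(el, j = paste0("drug_", cl$name),
                      value = el$patient_id %in% unique(rx_window$patient_id[hit]))
    }
  }
  el[]
}

#' Build the analysis-ready cohort
#'
#' Convenience wrapper running [select_population()],
#' [baseline_covariates()] and [censor_followup()] in order for the
#' incidence (time-to-first-review) analysis.
#'
#' @inheritParams baseline_covariates
#' @inheritParams censor_followup
#' @param patients,practices Typed tables.
#' @param reviews Output of [find_reviews()] (already filtered to the chosen
#'   review definition).
#' @return List with `cohort` (one row per study-population patient, with
#'   covariates and follow-up columns), `first_reviews`, and `counts` (the
#'   exclusion-flow tally).
#' @export
build_cohort <- function(patients, practices, events, prescriptions, cov,
                         reviews, codelists = list(), review_codelist = NULL,
                         baseline = mr_baseline_default,
                         study_end = mr_study_end_default) {
  bc <- baseline_counts(cov, baseline)
  sel <- select_population(patients, practices, baseline,
                           baseline_counts = bc)
  el <- baseline_covariates(sel$eligible, events, prescriptions, cov,
                            codelists, review_codelist, baseline)
  fr <- first_review(reviews)
  cohort <- censor_followup(el, fr, baseline, study_end)
  counts <- c(sel$counts,
              events = sum(cohort$event),
              censored = sum(!cohort$event))
  list(cohort = cohort, first_reviews = fr, counts = counts)
}
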