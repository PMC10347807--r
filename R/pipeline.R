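# End-to-end orchestration: simulate/load -> cohort -> reviews -> exposure ->
# before/after -> models, with a run manifest mirroring the exclusion flow.

mr_cox_covariates <- function(cohort) {
  base <- c("age_band", "sex", "townsend", "region", "baseline_count_band",
            "prior_year_review", "care_home")
  extra <- grep("^(diag|drug)_", names(cohort), value = TRUE)
  c(intersect(base, names(cohort)), extra)
}

mr_linear_covariates <- function(records) {
  intersect(c("age_band", "sex", "count_before_band", "region",
              "consultation_type", "staff_role", "townsend"),
            names(records))
}

#' Run the whole analysis pipeline
#'
#' Orchestrates one configured run: obtain the input tables (either by
#' simulation or from a directory of delimited files), drop excluded
#' products, build coverage, identify and classify reviews under the chosen
#' definition, build the censored cohort with baseline covariates, fit the
#' Cox models, derive before/after change records under the chosen window,
#' apply the exclusion rules, rank the most-changed medicines, and fit the
#' linear change model. All stage outputs and a manifest (seed, config hash,
#' row counts at every stage) are written to the output directory; identical
#' configuration and seed give identical outputs.
#'
#' @param config A named list or the path of a YAML file with elements:
#'   `simulate` (a list of [sim_config()] arguments) or `tables_dir` (a
#'   directory with `patients.csv`, `practices.csv`, `events.csv`,
#'   `prescriptions.csv`); `seed`; `out_dir`; optional `review_definition`
#'   (`"main"` or `"conservative"`), `window` (see [window_spec()]),
#'   `repeat_only`, `review_day_in_after`, `ties`, `study_year`.
#' @return Invisibly, a list with `cohort`, `first_reviews`, `records`,
#'   `delta`, `top_changed`, `cox_full`, `linear`, and `manifest`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(review_definition = "main", window = "3m3m", repeat_only = TRUE,
         review_day_in_after = TRUE, ties = "efron", seed = 1L,
         out_dir = NULL, simulate = NULL, tables_dir = NULL), config)
  if (is.null(cfg$out_dir)) stop("config error: out_dir is required")
  if (is.null(cfg$simulate) && is.null(cfg$tables_dir)) {
    stop("config error: either 'simulate' or 'tables_dir' must be given")
  }
  if (!is.null(cfg$tables_dir)) {
    need <- file.path(cfg$tables_dir,
                      paste0(c("patients", "practices", "events",
                               "prescriptions"), ".csv"))
    missing <- need[!file.exists(need)]
    if (length(missing)) {
      stop("config error: missing input table(s): ",
           paste(missing, collapse = ", "))
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$simulate)) {
    sim <- simulate_ehr(do.call(sim_config, cfg$simulate), seed = cfg$seed)
    patients <- sim$patients; practices <- sim$practices
    events <- sim$events; prescriptions <- sim$prescriptions
  } else {
    patients <- read_table(file.path(cfg$tables_dir, "patients.csv"),
                           "patients")
    practices <- read_table(file.path(cfg$tables_dir, "practices.csv"),
                            "practices")
    events <- read_table(file.path(cfg$tables_dir, "events.csv"), "events")
    prescriptions <- read_table(
      file.path(cfg$tables_dir, "prescriptions.csv"), "prescriptions")
  }

  review_codelist <- mr_review_codelist()
  codelists <- mr_default_codelists()
  rx <- filter_medicinal(prescriptions)
  cov <- build_coverage(rx)

  reviews <- find_reviews(events, review_codelist)
  if (cfg$review_definition == "conservative") {
    reviews <- conservative_filter(reviews)
  }

  ch <- build_cohort(patients, practices, events, rx, cov, reviews,
                     codelists = codelists,
                     review_codelist = review_codelist)
  cohort <- ch$cohort

  cox_full <- fit_cox(cohort, mr_cox_covariates(cohort), kind = "cox_full",
                      ties = cfg$ties)
  ph <- tryCatch(check_ph(cox_full), warning = function(w) NULL)

  # before/after population: reviewed people with adequate follow-up,
  # without the ongoing-prescription requirement
  sel_all <- select_population(patients, practices)
  elig_cov <- baseline_covariates(sel_all$eligible, events, rx, cov,
                                  codelists, review_codelist)
  spec <- window_spec(cfg$window,
                      review_day_in_after = cfg$review_day_in_after)
  fr <- first_review(reviews)
  records <- change_records(cov, fr, elig_cov, spec,
                            repeat_only = cfg$repeat_only)
  records <- merge(records,
                   elig_cov[, c("patient_id", "practice_id", "age_band",
                                "sex", "townsend", "region"), with = FALSE],
                   by = "patient_id")
  records <- merge(records,
                   fr[, list(patient_id, consultation_type, staff_role)],
                   by = "patient_id")
  top <- rank_top_changed(records)
  dc <- delta_counts(records)
  linear <- if (nrow(dc$retained) > 1L) {
    fit_linear_change(dc$retained, mr_linear_covariates(dc$retained))
  } else NULL

  manifest <- list(
    seed = cfg$seed,
    review_definition = cfg$review_definition,
    window = spec$name,
    counts = c(as.list(ch$counts),
               list(reviewed_with_followup =
                      sum(records$excluded_reason != "insufficient_followup"),
                    insufficient_followup =
                      unname(dc$tally[["insufficient_followup"]]),
                    no_prescriptions_before =
                      unname(dc$tally[["no_prescriptions_before"]]),
                    extreme_delta = unname(dc$tally[["extreme_delta"]]),
                    change_analysis_retained =
                      unname(dc$tally[["retained"]]))))
  # the hash covers the analysis configuration only, so identical runs into
  # different directories produce identical manifests
  cfg_hashed <- cfg[setdiff(names(cfg), "out_dir")]
  cfg_json <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg_hashed[order(names(cfg_hashed))], cfg_json,
                       auto_unbox = TRUE, null = "null")
  manifest$config_hash <- unname(tools::md5sum(cfg_json))

  out <- cfg$out_dir
  flat <- data.table::copy(records)
  for (col in c("before_set", "after_set", "stopped", "started", "continued")) {
    data.table::set(flat, j = col,
                    value = vapply(flat[[col]], paste, character(1),
                                   collapse = ";"))
  }
  data.table::fwrite(flat, file.path(out, "change_records.csv"))
  data.table::fwrite(top, file.path(out, "top_changed.csv"))
  data.table::fwrite(cox_full$table, file.path(out, "model_cox_full.csv"))
  if (!is.null(ph)) data.table::fwrite(ph, file.path(out, "ph_check.csv"))
  if (!is.null(linear)) {
    data.table::fwrite(linear$table, file.path(out, "model_linear.csv"))
  }
  coh_out <- data.table::copy(cohort)
  data.table::fwrite(coh_out, file.path(out, "cohort.csv"))
  data.table::fwrite(ch$first_reviews, file.path(out, "first_reviews.csv"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, first_reviews = ch$first_reviews,
                 records = records, delta = dc, top_changed = top,
                 cox_full = cox_full, ph = ph, linear = linear,
                 manifest = manifest))
}
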