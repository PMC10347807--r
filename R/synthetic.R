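# Synthetic EHR generator: CPRD-GOLD-like tables with planted, recoverable
# effects. Portfolio medicines are re-issued on a refill cycle so coverage
# chains without gaps; the planted review-hazard model is exponential
# (constant hazard within the study year), which makes the planted log-HRs
# exactly the estimands of a proportional-hazards fit; the planted
# post-review effect operates at medicine level (stop/start draws) so the
# stopped/started/continued classification has exact ground truth.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_ehr()]. Defaults emulate
#' the source study's conditions: 54.5% female; age-band, region, ethnicity
#' (50.8% missing), care-home (1.9%), previous-year-review (55.4%) and
#' baseline count-band distributions matching the descriptive tables; an
#' expected 51.6% of the eligible prescribed population reviewed within the
#' year (the baseline hazard is calibrated to this by root-finding);
#' fully-adjusted hazard ratios planted at 1.5 (care home), 1.83 (previous
#' review) and a rising count-band gradient (1.27 to 1.64); 28-day refill
#' cycles with up to 3 days of early-refill jitter; consultation-type and
#' staff-role mixes matching the review-characteristics table; and a planted
#' mean change of +0.13 medicines in the maximum prescription count after a
#' review.
#'
#' @param n_patients,n_practices Population size.
#' @param baseline,study_end Study year bounds.
#' @param female_prop,sex_missing_prob,age_band_probs,ethnicity_probs
#'   Demographic marginals.
#' @param region_probs,care_home_prob,prior_review_prob,person_townsend_prob
#'   Further covariate marginals.
#' @param uts_ok_prob Fraction with at least one year of up-to-standard
#'   history before baseline.
#' @param exit_prob Fraction with a death/transfer date inside the study
#'   year.
#' @param portfolio_probs Distribution of persistent portfolio size over the
#'   count bands (including band `"0"`).
#' @param cycle_days,jitter_max Refill cycle length and maximum early-refill
#'   jitter, days.
#' @param dose_choices Daily doses sampled per medicine.
#' @param repeat_prob Probability a portfolio issue is flagged repeat.
#' @param noise_rate,noise_duration Short-course (non-repeat) medicines per
#'   patient-year and their duration.
#' @param nonmedicinal_rate Excluded products (dressings, vaccines,
#'   anaesthesia) per patient-year, exercising the parse-time filter.
#' @param target_review_prop Expected within-year review fraction among the
#'   eligible prescribed population; the baseline hazard is solved from it.
#' @param log_hr Named log hazard ratios for `care_home` and `prior_review`.
#' @param band_log_hr Named log hazard ratios per baseline count band
#'   (reference band `"1"` = 0).
#' @param diag_prevalence,diag_log_hr Diagnosis-flag prevalences and optional
#'   planted log-HRs (default zero).
#' @param practice_frailty_sd SD of a practice-level normal log-hazard
#'   frailty (default 0: no cluster correlation).
#' @param recurrence_prob Probability of a second within-year review.
#' @param consultation_probs,staff_probs Review classification mixes.
#' @param review_excluded_code_prob Probability a review carries a code
#'   flagged as a specific-medicine/condition review.
#' @param delta_mean Planted mean change in post-review maximum count.
#' @param delta_by_band Optional named per-band override of `delta_mean`.
#' @param p_stop Per-medicine stop probability at review.
#' @return An object of class `mr_sim_config`.
#' @export
sim_config <- function(
    n_patients = 2000L, n_practices = 20L,
    baseline = "2019-01-01", study_end = "2019-12-31",
    female_prop = 0.545, sex_missing_prob = 0.001,
    age_band_probs = c("65-74" = 0.502, "75-84" = 0.349, "85-94" = 0.135,
                       "95+" = 0.014),
    ethnicity_probs = c(asian = 0.007, black = 0.002, mixed = 0.001,
                        other = 0.004, white = 0.478, missing = 0.508),
    region_probs = c(scotland = 0.396, wales = 0.285,
                     northern_ireland = 0.077, london = 0.033,
                     rest_of_england = 0.209),
    care_home_prob = 0.019, prior_review_prob = 0.554,
    person_townsend_prob = 0.5,
    uts_ok_prob = 0.97, exit_prob = 0.05,
    portfolio_probs = c("0" = 0.181, "1" = 0.093, "2-4" = 0.306,
                        "5-9" = 0.321, "10-14" = 0.084, "15-19" = 0.013,
                        "20+" = 0.002),
    cycle_days = 28L, jitter_max = 3L, dose_choices = c(1, 2),
    repeat_prob = 1.0,
    noise_rate = 1.0, noise_duration = 7L, nonmedicinal_rate = 0.1,
    target_review_prop = 0.516,
    log_hr = c(care_home = log(1.5), prior_review = log(1.83)),
    band_log_hr = c("1" = 0, "2-4" = log(1.27), "5-9" = log(1.41),
                    "10-14" = log(1.48), "15-19" = log(1.51),
                    "20+" = log(1.64)),
    diag_prevalence = c(af = 0.10, diabetes = 0.17, hypertension = 0.50,
                        depression = 0.10, ckd = 0.15, copd = 0.09),
    diag_log_hr = NULL,
    practice_frailty_sd = 0,
    recurrence_prob = 0.25,
    consultation_probs = c(face_to_face = 0.424, telephone = 0.031,
                           other = 0.544, missing = 0.001),
    staff_probs = c(pharmacist = 0.160, gp = 0.672, nurse = 0.085,
                    other = 0.055, admin = 0.013, missing = 0.016),
    review_excluded_code_prob = 0.15,
    delta_mean = 0.13, delta_by_band = NULL, p_stop = 0.05) {
  cfg <- as.list(environment())
  if (cfg$n_patients < 1L) stop("config error: n_patients must be >= 1")
  if (cfg$n_practices < 1L) stop("config error: n_practices must be >= 1")
  probs <- c(cfg$female_prop, cfg$sex_missing_prob, cfg$care_home_prob,
             cfg$prior_review_prob, cfg$person_townsend_prob, cfg$uts_ok_prob,
             cfg$exit_prob, cfg$repeat_prob, cfg$recurrence_prob,
             cfg$review_excluded_code_prob, cfg$p_stop,
             cfg$age_band_probs, cfg$ethnicity_probs, cfg$region_probs,
             cfg$portfolio_probs, cfg$consultation_probs, cfg$staff_probs,
             cfg$diag_prevalence)
  if (any(probs < 0 | probs > 1)) stop("config error: probabilities must be in [0, 1]")
  if (cfg$target_review_prop <= 0 || cfg$target_review_prop >= 1) {
    stop("config error: target_review_prop must be in (0, 1)")
  }
  if (any(c(cfg$noise_rate, cfg$nonmedicinal_rate) < 0)) {
    stop("config error: rates must be non-negative")
  }
  if (any(!is.finite(c(cfg$log_hr, cfg$band_log_hr)))) {
    stop("config error: planted log hazard ratios must be finite")
  }
  cfg$baseline <- as.Date(cfg$baseline)
  cfg$study_end <- as.Date(cfg$study_end)
  structure(cfg, class = "mr_sim_config")
}

mr_band_range <- function(band) {
  switch(band, "0" = 0L, "1" = 1L, "2-4" = 2:4, "5-9" = 5:9,
         "10-14" = 10:14, "15-19" = 15:19, "20+" = 20:24)
}

#' Bundled synthetic formulary
#'
#' A synthetic formulary of 60-plus medicines (substance, formulation, BNF
#' chapter and paragraph) used by the generator; includes the substances most
#' frequently stopped or started in practice (statins, proton-pump
#' inhibitors, antiplatelets, anticoagulants, vitamins).
#'
#' @return `data.table(substance, formulation, bnf_chapter, bnf_paragraph)`.
#' @export
mr_formulary <- function() {
  data.table::fread(mr_extdata("formulary.csv"),
                    colClasses = list(character = c("substance", "formulation",
                                                    "bnf_paragraph"),
                                      integer = "bnf_chapter"))
}

#' Bundled review code list
#' @return An `mr_codelist` of kind `"review"`.
#' @export
mr_review_codelist <- function() {
  load_codelist(mr_extdata("codelists", "medication_review.csv"),
                name = "medication_review", kind = "review")
}

#' Bundled diagnosis and drug-group code lists
#' @return Named list of `mr_codelist` objects (diagnosis lists `af`,
#'   `diabetes`, `hypertension`, `depression`, `ckd`, `copd`; drug-group term
#'   lists `opioids`, `antidepressants`, `ras_drugs`, `oral_anticoagulants`,
#'   `statins`, `nsaids`).
#' @export
mr_default_codelists <- function() {
  dir <- mr_extdata("codelists")
  diag <- c("af", "diabetes", "hypertension", "depression", "ckd", "copd")
  drug <- c("opioids", "antidepressants", "ras_drugs", "oral_anticoagulants",
            "statins", "nsaids")
  out <- c(
    lapply(diag, function(nm) load_codelist(
      file.path(dir, paste0("diag_", nm, ".csv")), name = nm,
      kind = "diagnosis")),
    lapply(drug, function(nm) load_codelist(
      file.path(dir, paste0("drug_", nm, ".csv")), name = nm,
      kind = "drug_group")))
  stats::setNames(out, c(diag, drug))
}

#' Generate the synthetic population
#'
#' Emits the patients and practices tables: all patients aged 65+ in the
#' study year, demographic marginals per the configuration, a configurable
#' fraction with at least one year of pre-baseline up-to-standard history,
#' and a configurable fraction exiting (death or transfer) inside the study
#' year.
#'
#' @param cfg An [sim_config()] object.
#' @param seed Optional RNG seed (set once in [simulate_ehr()] normally).
#' @return List with typed `patients` and `practices` tables.
#' @export
generate_population <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "mr_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_patients
  npr <- cfg$n_practices
  practices <- data.table::data.table(
    practice_id = sprintf("PR%04d", seq_len(npr)),
    region = factor(sample(names(cfg$region_probs), npr, TRUE,
                           prob = cfg$region_probs), levels = mr_levels$region),
    last_collection_date = cfg$study_end,
    townsend_quintile = sample(1:5, npr, TRUE))

  yr <- as.integer(format(cfg$baseline, "%Y"))
  band <- sample(names(cfg$age_band_probs), n, TRUE,
                 prob = cfg$age_band_probs)
  age <- vapply(band, function(b) switch(b, "65-74" = sample(65:74, 1L),
                                         "75-84" = sample(75:84, 1L),
                                         "85-94" = sample(85:94, 1L),
                                         sample(95:105, 1L)), integer(1))
  sex <- sample(c("male", "female"), n, TRUE,
                prob = c(1 - cfg$female_prop, cfg$female_prop))
  sex[runif(n) < cfg$sex_missing_prob] <- "missing"
  reg_date <- cfg$baseline - sample(400:9000, n, TRUE)
  uts_ok <- runif(n) < cfg$uts_ok_prob
  uts_date <- data.table::fifelse(uts_ok, reg_date,
                                  cfg$baseline - sample(1:364, n, TRUE))
  exits <- runif(n) < cfg$exit_prob
  exit_date <- as.Date(rep(NA, n))
  exit_date[exits] <- cfg$baseline +
    sample.int(as.integer(cfg$study_end - cfg$baseline) + 1L,
               sum(exits), TRUE) - 1L
  is_death <- exits & runif(n) < 0.5
  person_t <- runif(n) < cfg$person_townsend_prob
  patients <- data.table::data.table(
    patient_id = sprintf("P%07d", seq_len(n)),
    sex = factor(sex, levels = mr_levels$sex),
    birth_year = yr - age,
    practice_id = sample(practices$practice_id, n, TRUE),
    registration_date = reg_date,
    uts_date = uts_date,
    transfer_out_date = data.table::fifelse(exits & !is_death, exit_date,
                                            as.Date(NA)),
    death_date = data.table::fifelse(is_death, exit_date, as.Date(NA)),
    care_home = runif(n) < cfg$care_home_prob,
    ethnicity = factor(sample(names(cfg$ethnicity_probs), n, TRUE,
                              prob = cfg$ethnicity_probs),
                       levels = mr_levels$ethnicity),
    townsend_quintile = data.table::fifelse(person_t, sample(1:5, n, TRUE),
                                            NA_integer_),
    person_level_townsend = person_t)
  list(patients = patients, practices = practices)
}

# Follow-up end per patient: earliest of death, transfer, last collection,
# study end.
mr_fu_end <- function(patients, practices, study_end) {
  lc <- practices$last_collection_date[match(patients$practice_id,
                                             practices$practice_id)]
  pmin(patients$death_date, patients$transfer_out_date, lc,
       as.Date(study_end), na.rm = TRUE)
}

#' Generate synthetic prescribing
#'
#' Assigns each patient a persistent portfolio of medicines (size drawn from
#' the configured count-band distribution) from the bundled formulary, and
#' issues each portfolio medicine on a refill cycle with early-refill jitter
#' (quantity = cycle days x daily dose), so per-medicine coverage chains
#' without gaps from half a year before baseline to the end of follow-up.
#' Short-course non-repeat medicines and occasional excluded products
#' (dressings, vaccines) are injected as noise.
#'
#' @param cfg An [sim_config()] object.
#' @param population Output of [generate_population()].
#' @param seed Optional RNG seed.
#' @return Typed prescriptions table with attribute `"portfolio"` (the
#'   per-patient medicine portfolio used downstream by
#'   [generate_reviews()]).
#' @export
generate_prescribing <- function(cfg, population, seed = NULL) {
  stopifnot(inherits(cfg, "mr_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  patients <- population$patients
  practices <- population$practices
  form <- mr_formulary()
  if (nrow(form) == 0L) stop("config error: empty formulary")
  n <- nrow(patients)
  gen_start <- cfg$baseline - 184L
  fu_end <- mr_fu_end(patients, practices, cfg$study_end)

  size_band <- sample(names(cfg$portfolio_probs), n, TRUE,
                      prob = cfg$portfolio_probs)
  sizes <- vapply(size_band, function(b) {
    r <- mr_band_range(b); if (length(r) == 1L) r else sample(r, 1L)
  }, integer(1))
  sizes <- pmin(sizes, nrow(form))

  has <- sizes > 0L
  med_idx <- unlist(lapply(sizes[has],
                           function(k) sample.int(nrow(form), k)))
  portfolio <- data.table::data.table(
    patient_id = rep(patients$patient_id[has], sizes[has]),
    med_idx = med_idx,
    dose = sample(cfg$dose_choices, sum(sizes), TRUE),
    start0 = rep(gen_start, sum(sizes)) -
      sample.int(cfg$cycle_days, sum(sizes), TRUE) + 1L)
  portfolio[, `:=`(substance = form$substance[med_idx],
                   formulation = form$formulation[med_idx],
                   bnf_chapter = form$bnf_chapter[med_idx],
                   bnf_paragraph = form$bnf_paragraph[med_idx])]
  portfolio[, medicine := mr_medicine_key(substance, formulation)]
  portfolio[, fu_end := fu_end[match(patient_id, patients$patient_id)]]

  step_min <- cfg$cycle_days - cfg$jitter_max
  n_issue <- ceiling(as.integer(cfg$study_end - gen_start + cfg$cycle_days) /
                       max(step_min, 1L)) + 2L
  np <- nrow(portfolio)
  grid <- portfolio[rep(seq_len(np), each = n_issue)]
  grid[, issue_no := rep(seq_len(n_issue), np)]
  steps <- cfg$cycle_days -
    sample.int(cfg$jitter_max + 1L, np * n_issue, TRUE) + 1L
  grid[, step := steps]
  grid[issue_no == 1L, step := 0L]
  grid[, issue_date := start0 + cumsum(step), by = c("patient_id", "med_idx")]
  grid <- grid[issue_date <= fu_end]
  rx_port <- grid[, list(
    patient_id, issue_date, substance, formulation, bnf_chapter,
    bnf_paragraph,
    quantity = as.numeric(dose * cfg$cycle_days),
    daily_dose = as.numeric(dose),
    repeat_flag = runif(.N) < cfg$repeat_prob)]

  span_years <- as.numeric(fu_end - gen_start + 1L) / 365
  n_noise <- rpois(n, cfg$noise_rate * span_years)
  noise_rows <- sum(n_noise)
  rx_noise <- NULL
  if (noise_rows > 0L) {
    pid <- rep(patients$patient_id, n_noise)
    fe <- rep(fu_end, n_noise)
    span <- as.integer(fe - rep(gen_start, noise_rows)) + 1L
    d0 <- rep(gen_start, noise_rows) +
      floor(runif(noise_rows) * span)
    idx <- sample.int(nrow(form), noise_rows, TRUE)
    dose <- sample(cfg$dose_choices, noise_rows, TRUE)
    rx_noise <- data.table::data.table(
      patient_id = pid, issue_date = d0,
      substance = form$substance[idx], formulation = form$formulation[idx],
      bnf_chapter = form$bnf_chapter[idx],
      bnf_paragraph = form$bnf_paragraph[idx],
      quantity = as.numeric(dose * cfg$noise_duration),
      daily_dose = as.numeric(dose), repeat_flag = FALSE)
  }

  n_nm <- rpois(n, cfg$nonmedicinal_rate * span_years)
  nm_rows <- sum(n_nm)
  rx_nm <- NULL
  if (nm_rows > 0L) {
    nm_items <- data.table::data.table(
      substance = c("absorbent dressing", "influenza vaccine",
                    "lidocaine"),
      formulation = c("dressing", "injection", "injection"),
      bnf_chapter = c(NA_integer_, 14L, 15L),
      bnf_paragraph = c("", "14.4", "15.2"))
    pid <- rep(patients$patient_id, n_nm)
    fe <- rep(fu_end, n_nm)
    span <- as.integer(fe - rep(gen_start, nm_rows)) + 1L
    idx <- sample.int(nrow(nm_items), nm_rows, TRUE)
    rx_nm <- data.table::data.table(
      patient_id = pid,
      issue_date = rep(gen_start, nm_rows) + floor(runif(nm_rows) * span),
      substance = nm_items$substance[idx],
      formulation = nm_items$formulation[idx],
      bnf_chapter = nm_items$bnf_chapter[idx],
      bnf_paragraph = nm_items$bnf_paragraph[idx],
      quantity = 1, daily_dose = NA_real_, repeat_flag = FALSE)
  }

  rx <- data.table::rbindlist(list(rx_port, rx_noise, rx_nm),
                              use.names = TRUE)
  data.table::setorder(rx, patient_id, issue_date, substance)
  stopifnot(all(rx$quantity > 0, na.rm = TRUE),
            all(rx$daily_dose > 0, na.rm = TRUE))
  data.table::setattr(rx, "portfolio", portfolio)
  rx[]
}

mr_sample_level <- function(probs, n, levels) {
  factor(sample(names(probs), n, TRUE, prob = probs), levels = levels)
}

#' Generate review events and perturb post-review prescribing
#'
#' Draws each patient's first-review time from an exponential hazard
#' `baseline_rate x exp(sum of planted log-HR x covariate)`, with the
#' baseline rate solved so that the expected within-year review fraction in
#' the eligible prescribed population equals the configured target. Observed
#' reviews (those inside follow-up) are emitted as coded clinical events with
#' sampled consultation type and staff role; a previous-year review event is
#' emitted for patients with the prior-review covariate, and diagnosis events
#' for planted diagnosis flags. Post-review prescribing is perturbed at
#' medicine level: each portfolio medicine stops with probability `p_stop`
#' (its coverage truncated to end the day before the review) and a
#' Poisson-distributed number of new medicines starts on the review day, with
#' the per-patient Poisson mean calibrated so the expected change in maximum
#' prescription count equals the planted delta exactly.
#'
#' @param cfg An [sim_config()] object.
#' @param population Output of [generate_population()].
#' @param prescriptions Output of [generate_prescribing()] (must carry the
#'   `"portfolio"` attribute).
#' @param seed Optional RNG seed.
#' @return List with `events`, modified `prescriptions`, and `truth` (the
#'   ground-truth sidecar: per-patient eligibility, portfolio size and band,
#'   linear predictor, uncensored first-review time, observed review date,
#'   stopped/started medicine sets and the true count change).
#' @export
generate_reviews <- function(cfg, population, prescriptions, seed = NULL) {
  stopifnot(inherits(cfg, "mr_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  patients <- population$patients
  practices <- population$practices
  portfolio <- attr(prescriptions, "portfolio")
  if (is.null(portfolio)) {
    stop("prescriptions must come from generate_prescribing()")
  }
  n <- nrow(patients)
  fu_end <- mr_fu_end(patients, practices, cfg$study_end)
  psize <- portfolio[, list(n_med = .N), by = "patient_id"]
  n_med <- psize$n_med[match(patients$patient_id, psize$patient_id)]
  n_med[is.na(n_med)] <- 0L
  band <- as.character(count_band(n_med))

  prior <- runif(n) < cfg$prior_review_prob
  diag_flags <- lapply(cfg$diag_prevalence, function(p) runif(n) < p)

  lp <- cfg$log_hr[["care_home"]] * patients$care_home +
    cfg$log_hr[["prior_review"]] * prior
  band_eff <- cfg$band_log_hr[band]
  band_eff[is.na(band_eff)] <- 0
  lp <- lp + unname(band_eff)
  if (!is.null(cfg$diag_log_hr)) {
    for (nm in names(cfg$diag_log_hr)) {
      if (nm %in% names(diag_flags)) {
        lp <- lp + cfg$diag_log_hr[[nm]] * diag_flags[[nm]]
      }
    }
  }
  if (cfg$practice_frailty_sd > 0) {
    fr <- stats::rnorm(nrow(practices), 0, cfg$practice_frailty_sd)
    lp <- lp + fr[match(patients$practice_id, practices$practice_id)]
  }

  eligible <- patients$sex %in% c("male", "female") &
    pmax(patients$uts_date, patients$registration_date) <=
      cfg$baseline - 365L & n_med > 0L
  lp_cal <- lp[eligible]
  r0 <- stats::uniroot(function(r)
    mean(1 - exp(-r * exp(lp_cal))) - cfg$target_review_prop,
    interval = c(1e-6, 50), tol = 1e-10)$root

  year_days <- as.integer(cfg$study_end - cfg$baseline) + 1L
  t_days <- rexp(n) / (r0 * exp(lp) / year_days)
  review_day <- floor(t_days)
  review_date <- cfg$baseline + review_day
  observed <- review_date <= pmin(fu_end, cfg$study_end)
  review_date[!observed] <- NA

  rl <- mr_review_codelist()
  excl_codes <- rl$entries$code[rl$entries$conservative_excluded]
  main_codes <- rl$entries$code[!rl$entries$conservative_excluded]
  sample_codes <- function(k) {
    use_excl <- runif(k) < cfg$review_excluded_code_prob & length(excl_codes)
    out <- sample(main_codes, k, TRUE)
    if (any(use_excl)) out[use_excl] <- sample(excl_codes, sum(use_excl), TRUE)
    out
  }

  n_obs <- sum(observed)
  ev_review <- data.table::data.table(
    patient_id = patients$patient_id[observed],
    event_date = review_date[observed],
    code = sample_codes(n_obs),
    consultation_type = mr_sample_level(cfg$consultation_probs, n_obs,
                                        mr_levels$consultation_type),
    staff_role = mr_sample_level(cfg$staff_probs, n_obs,
                                 mr_levels$staff_role))

  # within-year recurrence (does not affect first-review analyses)
  rec <- observed & runif(n) < cfg$recurrence_prob
  room <- as.integer(pmin(fu_end, cfg$study_end) - review_date)
  rec <- rec & !is.na(room) & room >= 1L
  n_rec <- sum(rec)
  ev_rec <- NULL
  if (n_rec > 0L) {
    ev_rec <- data.table::data.table(
      patient_id = patients$patient_id[rec],
      event_date = review_date[rec] + 1L +
        floor(runif(n_rec) * room[rec]),
      code = sample_codes(n_rec),
      consultation_type = mr_sample_level(cfg$consultation_probs, n_rec,
                                          mr_levels$consultation_type),
      staff_role = mr_sample_level(cfg$staff_probs, n_rec,
                                   mr_levels$staff_role))
  }

  n_prior <- sum(prior)
  ev_prior <- data.table::data.table(
    patient_id = patients$patient_id[prior],
    event_date = cfg$baseline - sample.int(365L, n_prior, TRUE),
    code = sample_codes(n_prior),
    consultation_type = mr_sample_level(cfg$consultation_probs, n_prior,
                                        mr_levels$consultation_type),
    staff_role = mr_sample_level(cfg$staff_probs, n_prior,
                                 mr_levels$staff_role))

  diag_lists <- mr_default_codelists()
  ev_diag <- data.table::rbindlist(lapply(names(cfg$diag_prevalence),
    function(nm) {
      flag <- diag_flags[[nm]]
      k <- sum(flag)
      if (k == 0L || !nm %in% names(diag_lists)) return(NULL)
      data.table::data.table(
        patient_id = patients$patient_id[flag],
        event_date = cfg$baseline - sample(30:3600, k, TRUE),
        code = diag_lists[[nm]]$entries$code[1L],
        consultation_type = factor("other",
                                   levels = mr_levels$consultation_type),
        staff_role = factor("gp", levels = mr_levels$staff_role))
    }))

  events <- data.table::rbindlist(list(ev_review, ev_rec, ev_prior, ev_diag),
                                  use.names = TRUE)
  data.table::setorder(events, patient_id, event_date, code)

  # post-review perturbation: medicine-level stop/start draws calibrated so
  # E[max count after - before] equals the planted delta per patient.
  delta_target <- rep(cfg$delta_mean, n)
  if (!is.null(cfg$delta_by_band)) {
    ov <- cfg$delta_by_band[band]
    delta_target[!is.na(ov)] <- ov[!is.na(ov)]
  }
  p_stop_i <- rep(cfg$p_stop, n)
  lambda_i <- delta_target + n_med * p_stop_i
  neg <- lambda_i < 0
  lambda_i[neg] <- 0
  p_stop_i[neg] <- pmin(1, -delta_target[neg] / pmax(n_med[neg], 1L))
  p_stop_i[n_med == 0L] <- 0

  rx <- data.table::copy(data.table::as.data.table(prescriptions))
  port <- data.table::copy(portfolio)
  port[, review_date := review_date[match(patient_id, patients$patient_id)]]
  port[, stopped := !is.na(review_date) &
         runif(.N) < p_stop_i[match(patient_id, patients$patient_id)]]

  stopped_port <- port[stopped == TRUE]
  if (nrow(stopped_port) > 0L) {
    rx[, medicine := mr_medicine_key(substance, formulation)]
    rx[, .row := seq_len(.N)]
    hit <- merge(rx[, list(.row, patient_id, medicine, issue_date,
                           daily_dose)],
                 stopped_port[, list(patient_id, medicine, review_date)],
                 by = c("patient_id", "medicine"))
    drop_rows <- hit[issue_date >= review_date, .row]
    trunc <- hit[issue_date < review_date]
    trunc[, new_q := daily_dose *
            pmin(cfg$cycle_days, as.integer(review_date - issue_date))]
    rx[trunc$.row, quantity := trunc$new_q]
    if (length(drop_rows)) rx <- rx[!.row %in% drop_rows]
    rx[, c(".row", "medicine") := NULL]
  }

  started_n <- integer(n)
  started_n[observed] <- rpois(n_obs, lambda_i[observed])
  form <- mr_formulary()
  started_keys <- rep(list(character(0)), n)
  start_rows <- NULL
  if (any(started_n > 0L)) {
    port_by_pt <- split(portfolio$med_idx, portfolio$patient_id)
    widx <- which(started_n > 0L)
    picks <- lapply(widx, function(i) {
      avail <- setdiff(seq_len(nrow(form)),
                       port_by_pt[[patients$patient_id[i]]])
      sample(avail, min(started_n[i], length(avail)))
    })
    npick <- lengths(picks)
    started_n[widx] <- npick
    sp <- data.table::data.table(
      patient_id = rep(patients$patient_id[widx], npick),
      med_idx = unlist(picks),
      review_date = rep(review_date[widx], npick),
      fu_end = rep(pmin(fu_end, cfg$study_end)[widx], npick),
      dose = sample(cfg$dose_choices, sum(npick), TRUE))
    sp[, `:=`(substance = form$substance[med_idx],
              formulation = form$formulation[med_idx],
              bnf_chapter = form$bnf_chapter[med_idx],
              bnf_paragraph = form$bnf_paragraph[med_idx])]
    step_min <- cfg$cycle_days - cfg$jitter_max
    n_issue <- ceiling(as.integer(cfg$study_end - cfg$baseline +
                                    cfg$cycle_days) / max(step_min, 1L)) + 2L
    nsp <- nrow(sp)
    grid <- sp[rep(seq_len(nsp), each = n_issue)]
    grid[, issue_no := rep(seq_len(n_issue), nsp)]
    grid[, step := cfg$cycle_days -
           sample.int(cfg$jitter_max + 1L, .N, TRUE) + 1L]
    grid[issue_no == 1L, step := 0L]
    grid[, issue_date := review_date + cumsum(step),
         by = c("patient_id", "med_idx")]
    grid <- grid[issue_date <= fu_end]
    start_rows <- grid[, list(
      patient_id, issue_date, substance, formulation, bnf_chapter,
      bnf_paragraph, quantity = as.numeric(dose * cfg$cycle_days),
      daily_dose = as.numeric(dose), repeat_flag = TRUE)]
    key_by_pt <- split(medicine_key(sp$substance, sp$formulation),
                       sp$patient_id)
    started_keys[match(names(key_by_pt), patients$patient_id)] <-
      lapply(key_by_pt, sort)
  }
  if (!is.null(start_rows)) {
    rx <- data.table::rbindlist(list(rx, start_rows), use.names = TRUE)
  }
  data.table::setorder(rx, patient_id, issue_date, substance)

  stopped_by_pt <- split(stopped_port$medicine, stopped_port$patient_id)
  stopped_keys <- rep(list(character(0)), n)
  stopped_keys[match(names(stopped_by_pt), patients$patient_id)] <-
    lapply(stopped_by_pt, sort)

  truth <- data.table::data.table(
    patient_id = patients$patient_id,
    practice_id = patients$practice_id,
    eligible = eligible,
    portfolio_size = n_med,
    band_true = band,
    care_home = patients$care_home,
    prior_review = prior,
    lp = lp,
    true_review_time_days = t_days,
    review_date = review_date,
    fu_end = fu_end,
    event = observed,
    n_stopped = vapply(stopped_keys, length, integer(1)),
    n_started = started_n,
    stopped = vapply(stopped_keys, paste, character(1), collapse = ";"),
    started = vapply(started_keys, paste, character(1), collapse = ";"))
  truth[, delta_true := n_started - n_stopped]
  for (nm in names(diag_flags)) {
    data.table::set(truth, j = paste0("diag_", nm), value = diag_flags[[nm]])
  }
  data.table::setattr(rx, "portfolio", portfolio)
  list(events = events, prescriptions = rx, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Runs [generate_population()], [generate_prescribing()] and
#' [generate_reviews()] under one seed. Fixed seed and configuration give
#' byte-identical output.
#'
#' @param cfg An [sim_config()] object.
#' @param seed Integer RNG seed.
#' @return List with `patients`, `practices`, `prescriptions`, `events`,
#'   `truth` and the `cfg` used.
#' @export
simulate_ehr <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  pop <- generate_population(cfg)
  rx <- generate_prescribing(cfg, pop)
  rev <- generate_reviews(cfg, pop, rx)
  list(patients = pop$patients, practices = pop$practices,
       prescriptions = rev$prescriptions, events = rev$events,
       truth = rev$truth, cfg = cfg, seed = seed)
}

#' Write a simulated dataset to delimited files
#'
#' Emits the four record tables plus the ground-truth sidecar `truth.csv`.
#'
#' @param sim Output of [simulate_ehr()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(sim$patients, file.path(dir, "patients.csv"), "patients")
  write_table(sim$practices, file.path(dir, "practices.csv"), "practices")
  write_table(sim$events, file.path(dir, "events.csv"), "events")
  write_table(sim$prescriptions, file.path(dir, "prescriptions.csv"),
              "prescriptions")
  truth <- data.table::copy(sim$truth)
  data.table::fwrite(truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
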