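mk_practices <- function(ids = "PR1", region = "scotland",
                         last = "2019-12-31") {
  data.table::data.table(
    practice_id = ids, region = factor(region, levels = mr_levels$region),
    last_collection_date = as.Date(last), townsend_quintile = 3L)
}

mk_patients <- function(n = 1L, ...) {
  base <- data.table::data.table(
    patient_id = paste0("P", seq_len(n)), sex = factor("male", levels = mr_levels$sex),
    birth_year = 1940L, practice_id = "PR1",
    registration_date = as.Date("2010-01-01"),
    uts_date = as.Date("2010-01-01"),
    transfer_out_date = as.Date(NA), death_date = as.Date(NA),
    care_home = FALSE, ethnicity = factor("white", levels = mr_levels$ethnicity),
    townsend_quintile = NA_integer_, person_level_townsend = FALSE)
  mods <- list(...)
  for (nm in names(mods)) data.table::set(base, j = nm, value = mods[[nm]])
  base
}

test_that("eligibility boundaries are exact", {
  pr <- mk_practices()
  # birth year 1954 turns 65 during 2019 -> eligible; 1955 does not
  pt <- mk_patients(2, birth_year = c(1954L, 1955L))
  sel <- select_population(pt, pr)
  expect_identical(sel$eligible$patient_id, "P1")
  expect_identical(unname(sel$counts[["excluded_age"]]), 1L)
  # registration/uts exactly one year before baseline is in; one day later out
  pt2 <- mk_patients(2, uts_date = as.Date(c("2018-01-01", "2018-01-02")))
  sel2 <- select_population(pt2, pr)
  expect_identical(sel2$eligible$patient_id, "P1")
  # the later of registration and uts governs
  pt3 <- mk_patients(1, registration_date = as.Date("2018-06-01"))
  expect_identical(nrow(select_population(pt3, pr)$eligible), 0L)
  # death on baseline day still counts as active at baseline
  pt4 <- mk_patients(2, death_date = as.Date(c("2019-01-01", "2018-12-31")))
  expect_identical(select_population(pt4, pr)$eligible$patient_id, "P1")
  # missing sex excluded
  pt5 <- mk_patients(1, sex = factor("missing", levels = mr_levels$sex))
  sel5 <- select_population(pt5, pr)
  expect_identical(unname(sel5$counts[["excluded_sex"]]), 1L)
})

test_that("flow counts add up and unknown practices error", {
  toy <- read_toy()
  sel <- select_population(toy$patients, toy$practices)
  cnt <- sel$counts
  expect_identical(unname(cnt[["total"]]),
                   unname(cnt[["excluded_age"]] + cnt[["excluded_sex"]] +
                            cnt[["excluded_uts"]] +
                            cnt[["excluded_not_active"]] + cnt[["eligible"]]))
  bad <- data.table::copy(toy$patients)[1L, practice_id := "NOPE"]
  expect_error(select_population(bad, toy$practices), "unknown practice")
})

test_that("censoring takes the earliest exit and resolves same-day ties to events", {
  pr <- mk_practices()
  pt <- mk_patients(3, death_date = as.Date(c(NA, "2019-05-10", "2019-03-01")))
  el <- select_population(pt, pr)$eligible
  fr <- data.table::data.table(patient_id = c("P1", "P2", "P3"),
                               review_date = as.Date(c("2019-04-01",
                                                       "2019-05-10",
                                                       "2019-06-01")))
  coh <- censor_followup(el, fr)
  # P1: review before any exit -> event
  expect_true(coh$event[coh$patient_id == "P1"])
  expect_identical(coh$time_days[coh$patient_id == "P1"], 90L)
  # P2: review on the death day -> event
  expect_true(coh$event[coh$patient_id == "P2"])
  # P3: review after death -> censored at death, review_date cleared
  expect_false(coh$event[coh$patient_id == "P3"])
  expect_identical(coh$exit_date[coh$patient_id == "P3"],
                   as.Date("2019-03-01"))
  expect_true(is.na(coh$review_date[coh$patient_id == "P3"]))
})

test_that("baseline covariates match a per-patient loop oracle", {
  set.seed(41)
  n <- 40L
  pr <- mk_practices(c("PR1", "PR2"), c("scotland", "wales"))
  pt <- mk_patients(n,
                    practice_id = sample(c("PR1", "PR2"), n, TRUE),
                    birth_year = sample(1920:1954, n, TRUE),
                    townsend_quintile = sample(c(1:5, NA), n, TRUE),
                    person_level_townsend = sample(c(TRUE, FALSE), n, TRUE))
  codes <- mr_default_codelists()
  ev <- data.table::data.table(
    patient_id = sample(pt$patient_id, 60, TRUE),
    event_date = as.Date("2017-01-01") + sample(0:1200, 60, TRUE),
    code = sample(c(codes$af$entries$code, codes$copd$entries$code,
                    "8B3V.", "zzz"), 60, TRUE),
    consultation_type = factor("face_to_face",
                               levels = mr_levels$consultation_type),
    staff_role = factor("gp", levels = mr_levels$staff_role))
  rx <- data.table::data.table(
    patient_id = sample(pt$patient_id, 80, TRUE),
    issue_date = as.Date("2018-01-01") + sample(0:400, 80, TRUE),
    substance = sample(c("atorvastatin", "ramipril", "paracetamol"), 80, TRUE),
    formulation = "tablet", bnf_chapter = 2L, bnf_paragraph = "x",
    quantity = 28, daily_dose = 1, repeat_flag = TRUE)
  cov <- build_coverage(rx)
  el <- select_population(pt, pr)$eligible
  got <- baseline_covariates(el, ev, rx, cov,
                             codelists = codes[c("af", "copd", "statins",
                                                 "ras_drugs")],
                             review_codelist = mr_review_codelist())
  baseline <- as.Date("2019-01-01")
  for (i in seq_len(nrow(got))) {
    p <- got$patient_id[i]
    age <- 2019L - got$birth_year[i]
    expect_identical(as.character(got$age_band[i]),
                     as.character(cut(age, c(64, 74, 84, 94, Inf),
                                      labels = mr_levels$age_band)))
    row <- pt[pt$patient_id == p, ]
    want_t <- if (isTRUE(row$person_level_townsend) &&
                  !is.na(row$townsend_quintile)) row$townsend_quintile else 3L
    expect_identical(as.character(got$townsend[i]), as.character(want_t))
    # ongoing count: medicines covering baseline, counted by loop
    pc <- cov[cov$patient_id == p & cov$start_date <= baseline &
                cov$end_date >= baseline, ]
    expect_identical(got$baseline_count[i], length(unique(pc$medicine)))
    # prior-year review flag
    prev <- ev[ev$patient_id == p & ev$code == "8B3V." &
                 format(ev$event_date, "%Y") == "2018", ]
    expect_identical(got$prior_year_review[i], nrow(prev) > 0L)
    # diagnosis flag: any code on/before baseline
    af <- ev[ev$patient_id == p & ev$code %in% codes$af$entries$code &
               ev$event_date <= baseline, ]
    expect_identical(got$diag_af[i], nrow(af) > 0L)
    # drug-group flag: statin issue in the half year up to baseline
    st <- rx[rx$patient_id == p & rx$substance == "atorvastatin" &
               rx$issue_date >= baseline - 183L & rx$issue_date <= baseline, ]
    expect_identical(got$drug_statins[i], nrow(st) > 0L)
  }
})
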