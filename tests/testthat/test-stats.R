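mk_cox_cohort <- function(n = 60L, n_cl = 6L, seed = 61L) {
  set.seed(seed)
  data.table::data.table(
    patient_id = paste0("P", seq_len(n)),
    practice_id = paste0("PR", rep_len(seq_len(n_cl), n)),
    group = rep_len(c(0L, 1L), n),
    time_days = sample(1:400, n, replace = TRUE),
    event = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.6, 0.4)))
}

test_that("cox fit matches a partial-likelihood grid-search oracle", {
  # two-group data without ties: the Efron and Breslow likelihoods coincide,
  # so compare against a direct optimisation of the log partial likelihood
  set.seed(62)
  n <- 18L
  dt <- data.table::data.table(
    patient_id = paste0("P", 1:n),
    practice_id = rep(c("PR1", "PR2"), each = n / 2),
    group = rep(c(0L, 1L), n / 2),
    time_days = sample(seq(10, 1000, by = 7), n),  # distinct -> no ties
    event = rep(c(TRUE, TRUE, TRUE, FALSE), length.out = n))
  fit <- fit_cox(dt, "group", kind = "cox_full")
  loglik <- function(beta) {
    ord <- order(dt$time_days)
    t <- dt$time_days[ord]; d <- dt$event[ord]; x <- dt$group[ord]
    ll <- 0
    for (i in seq_len(n)) {
      if (d[i]) {
        risk <- which(t >= t[i])
        ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
      }
    }
    ll
  }
  oracle <- stats::optimize(loglik, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(fit$table$estimate[1L], oracle, tolerance = 1e-4)
})

test_that("with one observation per cluster the cluster-robust SE is the HC SE", {
  set.seed(63)
  n <- 40L
  dt <- data.table::data.table(x = rnorm(n), cl = paste0("C", seq_len(n)))
  dt$y <- 1 + 0.5 * dt$x + rnorm(n) * (1 + abs(dt$x))
  fit <- stats::lm(y ~ x, data = dt)
  v_cl <- sandwich::vcovCL(fit, cluster = dt$cl, type = "HC1")
  v_hc <- sandwich::vcovHC(fit, type = "HC1")
  expect_lt(max(abs(v_cl - v_hc)), 1e-8)
})

test_that("linear fit on an orthogonal design reproduces group means exactly", {
  rec <- data.table::data.table(
    patient_id = paste0("P", 1:8),
    practice_id = rep(c("PR1", "PR2"), 4),
    count_before = 6L,
    delta = c(1, 1, 3, 3, 2, 2, 6, 6),
    grp = factor(rep(c("a", "a", "b", "b"), 2)))
  res <- fit_linear_change(rec, "grp")
  est <- res$table
  expect_equal(est$estimate[est$term == "(Intercept)"], 1.5)
  expect_equal(est$estimate[est$term == "grpb"],
               mean(rec$delta[rec$grp == "b"]) -
                 mean(rec$delta[rec$grp == "a"]))
  expect_equal(unname(res$mean_delta[["mean"]]), mean(rec$delta))
})

test_that("robust SE exceeds naive SE on average under cluster correlation", {
  set.seed(64)
  ratios <- replicate(20, {
    g <- rep(1:10, each = 20)
    u <- rnorm(10)[g]                 # shared cluster effect
    rec <- data.table::data.table(
      patient_id = seq_along(g), practice_id = paste0("PR", g),
      count_before = 6L, delta = 0.2 + u + rnorm(length(g), sd = 0.5))
    fit <- stats::lm(delta ~ 1, data = rec)
    se_naive <- sqrt(diag(stats::vcov(fit)))[1L]
    se_rob <- sqrt(diag(sandwich::vcovCL(fit, cluster = rec$practice_id,
                                         type = "HC1")))[1L]
    se_rob / se_naive
  })
  expect_gt(mean(ratios), 1)
})

test_that("fit_cox guards its inputs", {
  dt <- mk_cox_cohort()
  dt$event <- FALSE
  expect_error(fit_cox(dt, "group"), "no events")
  dt2 <- mk_cox_cohort()
  dt2$practice_id <- "PR1"
  expect_error(fit_cox(dt2, "group"), "two clusters")
  dt3 <- mk_cox_cohort()
  dt3$flat <- 1L
  expect_warning(fit_cox(dt3, c("group", "flat")), "single level")
  # perfectly separating covariate -> explicit fit error naming the term
  dt4 <- mk_cox_cohort(n = 40L)
  dt4$time_days <- ifelse(dt4$group == 1L, sample(1:10, 40, TRUE),
                          sample(300:400, 40, TRUE))
  dt4$event <- TRUE
  expect_error(suppressWarnings(fit_cox(dt4, "group")), "fit error")
})

test_that("model kinds and reference levels behave as documented", {
  set.seed(65)
  n <- 300L
  dt <- data.table::data.table(
    patient_id = paste0("P", seq_len(n)),
    practice_id = paste0("PR", rep_len(1:10, n)),
    sex = factor(sample(c("male", "female"), n, TRUE), levels = mr_levels$sex),
    age_band = factor(sample(mr_levels$age_band, n, TRUE),
                      levels = mr_levels$age_band),
    care_home = runif(n) < 0.3,
    time_days = pmax(1L, as.integer(rexp(n, 1 / 200))),
    event = runif(n) < 0.5)
  full <- fit_cox(dt, c("age_band", "sex", "care_home"), kind = "cox_full")
  expect_identical(full$model_kind, "cox_full")
  expect_false(is.null(full$fit))
  expect_false("age_band65-74" %in% full$table$term)  # reference level
  expect_identical(full$n_clusters, 10L)
  una <- fit_cox(dt, c("age_band", "care_home"), kind = "cox_unadjusted")
  expect_true(all(c("age_band", "care_home") %in% una$table$model_term))
  adj <- fit_cox(dt, c("age_band", "sex", "care_home"), kind = "cox_agesex")
  expect_false(anyDuplicated(adj$table$term) > 0)
  # CI invariants on the estimation scale
  tab <- full$table
  expect_equal(tab$conf_low, tab$estimate - 1.96 * tab$se_robust)
  expect_equal(tab$hr, exp(tab$estimate))
})

test_that("check_ph flags violations and guards tiny data", {
  set.seed(66)
  n <- 2000L
  # planted reversal: group hazard high early, low late -> non-proportional
  grp <- rep(c(0L, 1L), n / 2)
  t1 <- rexp(n, ifelse(grp == 1L, 1 / 30, 1 / 120))
  flip <- t1 > 60
  t1[flip] <- 60 + rexp(sum(flip), ifelse(grp[flip] == 1L, 1 / 500, 1 / 60))
  dt <- data.table::data.table(
    patient_id = seq_len(n), practice_id = paste0("PR", rep_len(1:10, n)),
    group = grp, time_days = pmax(1, round(t1)),
    event = t1 < 365)
  fit <- fit_cox(dt, "group", kind = "cox_full")
  ph <- check_ph(fit)
  expect_true(ph$flagged[ph$term == "group"])
  # constant-hazard data: the same check does not flag (nominal rate only)
  dt$time_days <- pmax(1, round(rexp(n, 1 / 100)))
  dt$event <- runif(n) < 0.7
  ph0 <- check_ph(fit_cox(dt, "group", kind = "cox_full"))
  expect_s3_class(ph0, "data.table")
  # fewer than 10 events -> warning and NULL
  small <- mk_cox_cohort(n = 30L)
  small$event <- c(rep(TRUE, 5), rep(FALSE, 25))
  sfit <- fit_cox(small, "group", kind = "cox_full")
  expect_warning(out <- check_ph(sfit), "fewer than 10 events")
  expect_null(out)
})

test_that("loglog curves export one series per factor level", {
  dt <- mk_cox_cohort(n = 200L, seed = 67L)
  dt$band <- factor(rep_len(c("1", "2-4"), 200L))
  cc <- loglog_curves(dt, "band")
  expect_setequal(unique(cc$level), c("1", "2-4"))
  expect_true(all(is.finite(cc$cloglog)))
})

test_that("p-value display convention", {
  expect_identical(format_p(c(0.0004, 0.001, 0.0499, 0.5)),
                   c("<0.001", "0.001", "0.050", "0.500"))
})
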