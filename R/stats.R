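# Regression models with practice-clustered robust variance.

mr_relevel <- function(dt, refs) {
  for (nm in names(refs)) {
    if (nm %in% names(dt) && is.factor(dt[[nm]])) {
      v <- droplevels(dt[[nm]])
      if (refs[[nm]] %in% levels(v)) v <- stats::relevel(v, ref = refs[[nm]])
      data.table::set(dt, j = nm, value = v)
    }
  }
  dt
}

mr_cox_refs <- list(age_band = "65-74", sex = "male", townsend = "1",
                    region = "scotland", baseline_count_band = "1")

mr_result <- function(table, n_obs, n_clusters, kind, fit = NULL) {
  structure(list(table = table, n_observations = n_obs,
                 n_clusters = n_clusters, model_kind = kind, fit = fit),
            class = "mr_model_result")
}

#' @export
print.mr_model_result <- function(x, ...) {
  cat(sprintf("<%s: n=%d, clusters=%d>\n", x$model_kind, x$n_observations,
              x$n_clusters))
  print(x$table)
  invisible(x)
}

mr_cox_table <- function(fit) {
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("fit error: non-estimable term(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  se <- sqrt(diag(fit$var)) # robust (sandwich) variance when cluster is set
  z <- beta / se
  data.table::data.table(
    term = names(beta), estimate = unname(beta), se_robust = unname(se),
    conf_low = unname(beta - 1.96 * se), conf_high = unname(beta + 1.96 * se),
    p = unname(2 * stats::pnorm(-abs(z))),
    hr = exp(unname(beta)), hr_low = exp(unname(beta - 1.96 * se)),
    hr_high = exp(unname(beta + 1.96 * se)))
}

mr_prep_cox_data <- function(cohort, covariates, cluster, zero_time_shift) {
  dt <- data.table::copy(data.table::as.data.table(cohort))
  dt <- mr_relevel(dt, mr_cox_refs)
  dt[, .time := as.numeric(time_days)]
  dt[.time <= 0, .time := zero_time_shift]
  keep <- covariates
  for (nm in covariates) {
    v <- dt[[nm]]
    nlev <- if (is.factor(v)) nlevels(droplevels(v)) else
      length(unique(v[!is.na(v)]))
    if (nlev < 2L) {
      warning("covariate '", nm, "' has a single level and was dropped")
      keep <- setdiff(keep, nm)
    }
  }
  list(data = dt, covariates = keep)
}

mr_coxph <- function(dt, covariates, cluster, ties) {
  f <- stats::as.formula(paste("survival::Surv(.time, event) ~",
                               paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = dt, ties = ties,
                         cluster = dt[[cluster]], x = FALSE, y = TRUE)
  if (!is.null(fit$coefficients) &&
      any(abs(fit$coefficients) > 15, na.rm = TRUE)) {
    stop("fit error: apparent separation / non-convergence in term(s): ",
         paste(names(fit$coefficients)[abs(fit$coefficients) > 15],
               collapse = ", "))
  }
  fit
}

#' Fit a Cox model for time to first medication review
#'
#' Fits a proportional-hazards model for the hazard of a first recorded
#' medication review, with robust standard errors allowing for intragroup
#' correlation within general practices. Ties in event times are handled by
#' the Efron approximation by default (day-granular data guarantee ties);
#' Breslow is available for cross-checking. Three specifications are
#' supported: `cox_unadjusted` fits each covariate in its own model;
#' `cox_agesex` adjusts every covariate for age band and sex; `cox_full` is a
#' single multivariable model with all supplied covariates. Reference levels
#' follow the descriptive tables: age 65-74, male, Townsend quintile 1,
#' Scotland, baseline count band "1".
#'
#' @param cohort Cohort table from [build_cohort()] (needs `time_days`,
#'   `event`, the covariate columns and the cluster column).
#' @param covariates Character vector of covariate column names.
#' @param cluster Cluster column (default `"practice_id"`).
#' @param kind Model specification (see above).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param zero_time_shift Event times of zero days are shifted to this value
#'   to avoid degenerate risk sets (default 0.5 days).
#' @return An `mr_model_result`; for `cox_full` the underlying `coxph` fit is
#'   attached for diagnostics.
#' @export
fit_cox <- function(cohort, covariates, cluster = "practice_id",
                    kind = c("cox_full", "cox_agesex", "cox_unadjusted"),
                    ties = c("efron", "breslow"), zero_time_shift = 0.5) {
  kind <- match.arg(kind); ties <- match.arg(ties)
  prep <- mr_prep_cox_data(cohort, covariates, cluster, zero_time_shift)
  dt <- prep$data; covariates <- prep$covariates
  if (!length(covariates)) stop("no usable covariates")
  if (sum(dt$event) == 0L) stop("fit error: no events in cohort")
  n_cl <- length(unique(dt[[cluster]]))
  if (n_cl < 2L) stop("need at least two clusters")

  if (kind == "cox_full") {
    fit <- mr_coxph(dt, covariates, cluster, ties)
    return(mr_result(mr_cox_table(fit), nrow(dt), n_cl, kind, fit))
  }
  tabs <- lapply(covariates, function(nm) {
    terms <- if (kind == "cox_unadjusted") nm else
      unique(c(nm, "age_band", "sex"))
    terms <- terms[terms %in% names(dt)]
    tab <- mr_cox_table(mr_coxph(dt, terms, cluster, ties))
    if (kind == "cox_agesex" && !nm %in% c("age_band", "sex")) {
      tab <- tab[!grepl("^age_band|^sex", term)]
    }
    tab[, model_term := nm]
    tab
  })
  if (kind == "cox_agesex") {
    keep_as <- covariates %in% c("age_band", "sex")
    if (any(keep_as)) tabs <- tabs[c(which(keep_as)[1L], which(!keep_as))]
    tabs <- unique(data.table::rbindlist(tabs), by = "term")
  } else tabs <- data.table::rbindlist(tabs)
  mr_result(tabs, nrow(dt), n_cl, kind)
}

#' Proportional-hazards diagnostic
#'
#' Numeric check of the proportional-hazards assumption: the scaled
#' Schoenfeld-residual-versus-time score test per term
#' ([survival::cox.zph()]), flagging terms at `p < 0.01`. Optionally also
#' returns log(-log(survival)) curves per level of each factor covariate for
#' visual audit. Skipped with a warning when fewer than 10 events are
#' available.
#'
#' @param result An `mr_model_result` from [fit_cox()] with an attached fit
#'   (i.e. `kind = "cox_full"`).
#' @param p_threshold Flagging threshold (default 0.01).
#' @param loglog Also compute log-minus-log survival curves.
#' @param cohort Cohort table (required when `loglog = TRUE`).
#' @param covariates Factor covariates for the log-minus-log export.
#' @return `data.table(term, chisq, df, p, flagged)`, with attribute
#'   `"loglog"` when requested, or `NULL` when skipped.
#' @export
check_ph <- function(result, p_threshold = 0.01, loglog = FALSE,
                     cohort = NULL, covariates = NULL) {
  fit <- result$fit
  if (is.null(fit)) stop("check_ph needs a cox_full result with stored fit")
  if (fit$nevent < 10L) {
    warning("fewer than 10 events; proportional-hazards diagnostic skipped")
    return(NULL)
  }
  zph <- survival::cox.zph(fit, transform = "km")
  tab <- data.table::data.table(term = rownames(zph$table),
                                chisq = zph$table[, "chisq"],
                                df = zph$table[, "df"],
                                p = zph$table[, "p"])
  tab[, flagged := term != "GLOBAL" & p < p_threshold]
  if (loglog && !is.null(cohort) && length(covariates)) {
    attr(tab, "loglog") <- loglog_curves(cohort, covariates)
  }
  tab[]
}

#' Log-minus-log survival curves per covariate level
#'
#' Kaplan-Meier based log(-log(S(t))) curves for each level of the given
#' factor covariates; approximately parallel curves support proportional
#' hazards.
#'
#' @param cohort Cohort table with `time_days` and `event`.
#' @param covariates Factor covariate names.
#' @return `data.table(covariate, level, time, cloglog)`.
#' @export
loglog_curves <- function(cohort, covariates) {
  dt <- data.table::as.data.table(cohort)
  out <- lapply(covariates, function(nm) {
    sf <- survival::survfit(
      stats::as.formula(paste("survival::Surv(pmax(time_days, 0.5), event) ~",
                              nm)), data = dt)
    strata <- rep(names(sf$strata), sf$strata)
    keep <- sf$surv > 0 & sf$surv < 1
    data.table::data.table(covariate = nm,
                           level = sub("^.*=", "", strata[keep]),
                           time = sf$time[keep],
                           cloglog = log(-log(sf$surv[keep])))
  })
  data.table::rbindlist(out)
}

mr_lm_refs <- list(age_band = "65-74", sex = "male", townsend = "1",
                   region = "scotland", count_before_band = "5-9",
                   consultation_type = "face_to_face", staff_role = "gp")

#' Linear model for change in maximum prescription count
#'
#' Least-squares regression of the change in maximum prescription count
#' (after minus before the review) on covariates, with cluster-robust
#' (CR0/HC1-type) sandwich standard errors grouped by practice. Reference
#' levels follow the descriptive tables: count band before the review "5-9",
#' Scotland, face-to-face consultation, GP, Townsend quintile 1, age 65-74,
#' male. The overall mean change with its cluster-robust confidence interval
#' is returned alongside (an intercept-only fit).
#'
#' @param records Retained change records from [delta_counts()], joined with
#'   the covariate columns (see [run_all()]); a `count_before_band` column is
#'   derived from `count_before` if absent.
#' @param covariates Covariate column names (may be empty for the mean-only
#'   model).
#' @param cluster Cluster column (default `"practice_id"`).
#' @return An `mr_model_result` whose table includes the intercept; element
#'   `mean_delta` holds `c(mean, conf_low, conf_high, p)`.
#' @export
fit_linear_change <- function(records, covariates = character(0),
                              cluster = "practice_id") {
  dt <- data.table::copy(data.table::as.data.table(records))
  if (!"count_before_band" %in% names(dt) && "count_before" %in% names(dt)) {
    dt[, count_before_band := count_band(count_before)]
  }
  dt <- mr_relevel(dt, mr_lm_refs)
  cl <- dt[[cluster]]

  mean_fit <- stats::lm(delta ~ 1, data = dt)
  mv <- sandwich::vcovCL(mean_fit, cluster = cl, type = "HC1")
  m <- unname(stats::coef(mean_fit)[1L]); mse <- sqrt(mv[1L, 1L])
  mean_delta <- c(mean = m, conf_low = m - 1.96 * mse,
                  conf_high = m + 1.96 * mse,
                  p = 2 * stats::pnorm(-abs(m / mse)))

  if (length(covariates)) {
    for (nm in covariates) {
      v <- dt[[nm]]
      nlev <- if (is.factor(v)) nlevels(droplevels(v)) else
        length(unique(v[!is.na(v)]))
      if (nlev < 2L) {
        warning("covariate '", nm, "' has a single level and was dropped")
        covariates <- setdiff(covariates, nm)
      }
    }
  }
  f <- if (length(covariates))
    stats::as.formula(paste("delta ~", paste(covariates, collapse = " + ")))
  else stats::as.formula("delta ~ 1")
  fit <- stats::lm(f, data = dt)
  if (anyNA(stats::coef(fit))) {
    warning("collinear term(s) dropped: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  }
  vc <- sandwich::vcovCL(fit, cluster = cl, type = "HC1")
  ct <- lmtest::coeftest(fit, vcov. = vc)
  est <- ct[, "Estimate"]; se <- ct[, "Std. Error"]
  tab <- data.table::data.table(
    term = rownames(ct), estimate = unname(est), se_robust = unname(se),
    conf_low = unname(est - 1.96 * se), conf_high = unname(est + 1.96 * se),
    p = unname(2 * stats::pnorm(-abs(est / se))))
  res <- mr_result(tab, nrow(dt), length(unique(cl)), "linear_change", fit)
  res$mean_delta <- mean_delta
  res
}

#' Display-format a p-value
#'
#' Three decimals with `<0.001` flooring, matching the reporting convention
#' of the results tables.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}
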