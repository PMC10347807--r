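test_that("window specifications use the documented day offsets", {
  expect_identical(window_spec("3m3m")[c("before", "after")],
                   list(before = c(-91L, -1L), after = c(0L, 91L)))
  expect_identical(window_spec("6m6m")[c("before", "after")],
                   list(before = c(-183L, -1L), after = c(0L, 183L)))
  expect_identical(window_spec("3m1to4m")[c("before", "after")],
                   list(before = c(-91L, -1L), after = c(30L, 121L)))
  expect_identical(window_spec("1m1m")[c("before", "after")],
                   list(before = c(-30L, -1L), after = c(0L, 30L)))
  # sensitivity toggle: review day moves into the before window
  flip <- window_spec("3m3m", review_day_in_after = FALSE)
  expect_identical(flip$before, c(-91L, 0L))
  expect_identical(flip$after, c(1L, 91L))
  expect_error(window_spec("9m9m"))
})

test_that("classify_changes is correct set algebra", {
  set.seed(51)
  pool <- paste0("m", 1:12)
  for (i in 1:50) {
    before <- sample(pool, sample(0:8, 1L))
    after <- sample(pool, sample(0:8, 1L))
    cls <- classify_changes(before, after)
    expect_setequal(c(cls$stopped, cls$continued), before)
    expect_setequal(c(cls$started, cls$continued), after)
    expect_length(intersect(cls$stopped, cls$started), 0L)
    expect_length(intersect(cls$stopped, cls$continued), 0L)
    expect_identical(cls$stopped, sort(cls$stopped))
  }
})

mk_ba_fixture <- function() {
  # one reviewed patient: drug a continues across the review, drug b stops
  # (coverage ends before it), drug c starts at the review, drug d is
  # non-repeat short-course noise
  cov <- data.table::data.table(
    patient_id = "P1",
    medicine = c("a|tablet", "b|tablet", "c|tablet", "d|tablet"),
    start_date = as.Date(c("2019-01-01", "2019-02-01", "2019-06-01",
                           "2019-05-20")),
    end_date = as.Date(c("2019-09-30", "2019-05-15", "2019-08-31",
                         "2019-05-26")),
    source_repeat = c(TRUE, TRUE, TRUE, FALSE))
  fr <- data.table::data.table(patient_id = "P1",
                               review_date = as.Date("2019-06-01"))
  el <- data.table::data.table(patient_id = "P1",
                               death_date = as.Date(NA),
                               transfer_out_date = as.Date(NA),
                               last_collection_date = as.Date("2019-12-31"))
  list(cov = cov, fr = fr, el = el)
}

test_that("change_records classifies and counts around the review", {
  fx <- mk_ba_fixture()
  rec <- change_records(fx$cov, fx$fr, fx$el, window_spec("3m3m"))
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$before_set[[1L]], c("a|tablet", "b|tablet"))
  expect_identical(rec$after_set[[1L]], c("a|tablet", "c|tablet"))
  expect_identical(rec$stopped[[1L]], "b|tablet")
  expect_identical(rec$started[[1L]], "c|tablet")
  expect_identical(rec$continued[[1L]], "a|tablet")
  expect_identical(rec$count_before, 2L)
  expect_identical(rec$count_after, 2L)
  expect_identical(rec$delta, 0L)
  expect_identical(rec$excluded_reason, "none")
  # with repeat_only = FALSE the short course joins the before set
  rec2 <- change_records(fx$cov, fx$fr, fx$el, window_spec("3m3m"),
                         repeat_only = FALSE)
  expect_true("d|tablet" %in% rec2$before_set[[1L]])
})

test_that("insufficient follow-up is flagged, not dropped", {
  fx <- mk_ba_fixture()
  fx$el$death_date <- as.Date("2019-07-01")  # 30 days after the review
  rec <- change_records(fx$cov, fx$fr, fx$el, window_spec("3m3m"))
  expect_identical(rec$excluded_reason, "insufficient_followup")
  # a 1m1m window fits within the shortened follow-up
  rec2 <- change_records(fx$cov, fx$fr, fx$el, window_spec("1m1m"))
  expect_identical(rec2$excluded_reason, "none")
})

test_that("rank_top_changed matches a plain aggregation oracle", {
  set.seed(52)
  pool <- paste0("m", 1:15, "|tablet")
  n <- 80L
  rec <- data.table::data.table(
    patient_id = paste0("P", seq_len(n)),
    review_date = as.Date("2019-06-01"),
    excluded_reason = sample(c("none", "insufficient_followup"), n, TRUE,
                             prob = c(0.9, 0.1)))
  rec$stopped <- replicate(n, sample(pool, sample(0:3, 1L)), simplify = FALSE)
  rec$started <- replicate(n, sample(pool, sample(0:3, 1L)), simplify = FALSE)
  rec$continued <- replicate(n, sample(pool, sample(0:3, 1L)),
                             simplify = FALSE)
  top <- rank_top_changed(rec, k = 10L)
  keep <- rec[rec$excluded_reason != "insufficient_followup", ]
  oracle <- sapply(pool, function(m) {
    sum(vapply(keep$stopped, function(s) m %in% s, logical(1))) +
      sum(vapply(keep$started, function(s) m %in% s, logical(1)))
  })
  oracle <- oracle[oracle > 0]
  oracle <- oracle[order(-oracle, names(oracle))]
  expect_identical(top$medicine, names(oracle)[seq_len(nrow(top))])
  expect_identical(top$n_changed, unname(oracle)[seq_len(nrow(top))])
  expect_lte(nrow(top), 10L)
  expect_error(rank_top_changed(rec, k = 0L))
})

mk_delta_records <- function(deltas, count_before = 5L,
                             excluded = "none") {
  data.table::data.table(
    patient_id = paste0("P", seq_along(deltas)),
    count_before = rep_len(count_before, length(deltas)),
    delta = as.integer(deltas),
    excluded_reason = rep_len(excluded, length(deltas)))
}

test_that("delta_counts applies the documented exclusion rules", {
  # all deltas equal -> SD 0 -> the 3-SD screen drops nothing
  eq <- delta_counts(mk_delta_records(rep(1L, 20)))
  expect_identical(unname(eq$tally[["retained"]]), 20L)
  # {0 x 999, +50}: mean ~0.05, sd ~1.58 -> +50 is beyond 3 SD
  out <- delta_counts(mk_delta_records(c(rep(0L, 999), 50L)))
  expect_identical(unname(out$tally[["extreme_delta"]]), 1L)
  expect_identical(unname(out$tally[["retained"]]), 999L)
  # count_before = 0 is dropped before the SD computation
  rec <- mk_delta_records(c(rep(0L, 10), 50L), count_before = c(rep(5L, 10), 0L))
  out2 <- delta_counts(rec)
  expect_identical(unname(out2$tally[["no_prescriptions_before"]]), 1L)
  expect_identical(unname(out2$tally[["extreme_delta"]]), 0L)
  expect_identical(out2$mean, 0)
  # empty input
  e <- delta_counts(mk_delta_records(integer(0)))
  expect_identical(sum(e$tally), 0L)
  expect_true(is.na(e$mean))
  # the screen is applied once, not iterated: a value just inside 3 SD of the
  # original pool survives even if it would fall outside after removal of the
  # extreme record
  rec3 <- mk_delta_records(c(rep(0L, 50), 4L, 40L))
  out3 <- delta_counts(rec3)
  expect_identical(unname(out3$tally[["extreme_delta"]]), 1L)
  expect_true(4L %in% out3$retained$delta)
})

test_that("band cross-tabulation marginals equal the record count", {
  set.seed(53)
  rec <- mk_delta_records(sample(-3:3, 200, TRUE),
                          count_before = sample(1:25, 200, TRUE))
  rec$count_after <- pmax(rec$count_before + rec$delta, 0L)
  tab <- table(count_band(rec$count_before), count_band(rec$count_after))
  expect_identical(sum(tab), 200L)
  expect_identical(as.integer(rowSums(tab)),
                   as.integer(table(count_band(rec$count_before))))
})
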