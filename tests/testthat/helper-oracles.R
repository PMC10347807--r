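# Shared brute-force oracles and fixture helpers.

toy_path <- function(...) mr_extdata("toy", ...)

read_toy <- function() {
  list(patients = read_table(toy_path("patients.csv"), "patients"),
       practices = read_table(toy_path("practices.csv"), "practices"),
       events = read_table(toy_path("events.csv"), "events"),
       prescriptions = read_table(toy_path("prescriptions.csv"),
                                  "prescriptions"))
}

# Brute-force maximum overlap: walk every day of the window and count
# distinct medicines covering it.
brute_max_overlap <- function(cov, window_start, window_end,
                              repeat_only = FALSE) {
  ws <- as.Date(window_start); we <- as.Date(window_end)
  if (repeat_only) cov <- cov[cov$source_repeat %in% TRUE, ]
  if (nrow(cov) == 0L) return(0L)
  best <- 0L
  for (d in seq(as.integer(ws), as.integer(we))) {
    n <- length(unique(cov$medicine[as.integer(cov$start_date) <= d &
                                      as.integer(cov$end_date) >= d]))
    best <- max(best, n)
  }
  best
}

# Random single-patient coverage instance: up to max_med medicines, up to
# max_int raw intervals, day range anchored near the window.
random_coverage <- function(max_med = 10L, max_int = 20L,
                            origin = as.Date("2019-01-01")) {
  n <- sample.int(max_int, 1L)
  meds <- paste0("med", sample.int(max_med, n, replace = TRUE), "|tablet")
  start <- origin + sample(-60:120, n, replace = TRUE)
  len <- sample(1:90, n, replace = TRUE)
  data.table::data.table(patient_id = "P1", medicine = meds,
                         start_date = start, end_date = start + len - 1L,
                         source_repeat = sample(c(TRUE, FALSE), n,
                                                replace = TRUE))
}

# Set of covered days per medicine, for merge-correctness checks.
covered_days <- function(cov) {
  if (nrow(cov) == 0L) return(character(0))
  unlist(lapply(seq_len(nrow(cov)), function(i) {
    paste(cov$medicine[i],
          seq(as.integer(cov$start_date[i]), as.integer(cov$end_date[i])))
  }))
}
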