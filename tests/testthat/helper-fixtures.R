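# Shared fixtures. The large default cohort is generated once per session
# and reused by the calibration, recovery and acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

default_cohort_50k <- function() {
  if (is.null(.fixture_env$cohort50k)) {
    cfg <- cohort_config(n_patients = 50000L, seed = 2024L)
    .fixture_env$cohort50k <- generate_cohort(cfg)
  }
  .fixture_env$cohort50k
}

default_report_50k <- function() {
  if (is.null(.fixture_env$report50k))
    .fixture_env$report50k <- run_pipeline(default_cohort_50k())
  .fixture_env$report50k
}

# random battery-order history over an evaluation horizon
random_history <- function(horizon = 730L, max_orders = 8L) {
  k <- sample.int(max_orders, 1L)
  days <- sort(sample.int(horizon + 200L, k)) - 1L
  battery_history("p", 0L, unique(c(0L, days)))
}

# independent day-count oracle for the medication possession ratio
mpr_day_oracle <- function(history, window_days,
                           params = persistence_params()) {
  t <- history$order_days - history$fitting_day
  days <- 0:(window_days - 1L)
  covered <- vapply(days, function(d) any(t <= d & d < t + params$dose_days),
                    logical(1))
  sum(covered) / window_days
}

# a minimal valid single-exam audiogram as a long data.frame
make_audiogram <- function(left = c(40, 50, 60, 70),
                           right = c(40, 50, 60, 70),
                           freqs = c(500L, 1000L, 2000L, 4000L),
                           patient_id = "p", exam_day = 0L) {
  data.frame(patient_id = patient_id, exam_day = exam_day,
             ear = rep(c("L", "R"), each = length(freqs)),
             frequency_hz = rep(freqs, 2L),
             entry = as.character(c(left, right)),
             stringsAsFactors = FALSE)
}
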