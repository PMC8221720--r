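test_that("the refill-gap criterion has its floor at dose + gap days", {
  h <- battery_history("p", 0L, 0L)
  expect_true(is_persistent(h, persistence_params(eval_days = 547L)))
  expect_false(is_persistent(h, persistence_params(eval_days = 548L)))
  expect_true(is_persistent_brute(h, persistence_params(eval_days = 547L)))
  expect_false(is_persistent_brute(h, persistence_params(eval_days = 548L)))
  # a later order extends persistence: t_last = 400, 730 < 400 + 548
  h2 <- battery_history("p", 0L, c(0L, 400L))
  expect_true(is_persistent(h2, persistence_params(eval_days = 730L)))
  # an order on day T itself does not count
  h3 <- battery_history("p", 0L, c(0L, 730L))
  expect_false(is_persistent(h3, persistence_params(eval_days = 730L)))
})

test_that("parameters must be strictly positive", {
  expect_error(persistence_params(dose_days = 0), "dose_days")
  expect_error(persistence_params(gap_days = -1), "gap_days")
})

test_that("formula and day-stepping oracle agree on random histories", {
  set.seed(101)
  params_list <- list(persistence_params(),
                      persistence_params(90L, 180L, 400L),
                      persistence_params(30L, 60L, 150L))
  for (i in 1:400) {
    h <- random_history()
    p <- params_list[[1L + i %% 3L]]
    expect_identical(is_persistent(h, p), is_persistent_brute(h, p),
                     info = paste(h$order_days, collapse = ","))
  }
})

test_that("adding an order never breaks persistence; scaling days is neutral", {
  set.seed(55)
  for (i in 1:100) {
    h <- random_history()
    if (is_persistent(h)) {
      extra <- sort(unique(c(h$order_days, sample.int(729L, 1L))))
      expect_true(is_persistent(battery_history("p", 0L, extra)))
    }
    k <- sample(2:5, 1L)
    scaled <- battery_history("p", 0L, h$order_days * k)
    ps <- persistence_params(183L * k, 365L * k, 730L * k)
    expect_identical(is_persistent(scaled, ps), is_persistent(h))
  }
})

test_that("the possession ratio uses interval union over the window", {
  h <- battery_history("p", 0L, 0L)
  expect_equal(medication_possession_ratio(h, 183L), 1)
  expect_equal(medication_possession_ratio(h, 366L), 0.5)
  h2 <- battery_history("p", 0L, c(0L, 100L))
  expect_equal(medication_possession_ratio(h2, 366L), 283 / 366)
  expect_equal(medication_possession_ratio(h2, 366L),
               mpr_day_oracle(h2, 366L))
  set.seed(77)
  for (i in 1:60) {
    h <- random_history()
    w <- sample(100:800, 1L)
    expect_equal(medication_possession_ratio(h, w), mpr_day_oracle(h, w))
  }
})

make_cohort_tables <- function(order_days_per_patient, death_day = NULL) {
  ids <- sprintf("p%03d", seq_along(order_days_per_patient))
  fitting <- data.frame(patient_id = ids, ha_order_day = 0L,
                        fitting_day = 0L, lag = 0L,
                        stringsAsFactors = FALSE)
  bo <- data.frame(
    patient_id = rep(ids, lengths(order_days_per_patient)),
    order_day = unlist(order_days_per_patient), stringsAsFactors = FALSE)
  demo <- data.frame(patient_id = ids, birth_day = -25000L,
                     death_day = if (is.null(death_day)) NA_integer_
                                 else death_day,
                     gender = "M", stringsAsFactors = FALSE)
  list(fitting = fitting, battery_orders = bo, demographics = demo)
}

test_that("cohort persistence aggregates flags and applies death exclusion", {
  tb <- make_cohort_tables(list(0L, 0L, 0L))
  est <- cohort_persistence(tb$fitting, tb$battery_orders, tb$demographics)
  expect_equal(est$proportion, 0)                 # fitting-day order only
  tb2 <- make_cohort_tables(list(c(0L, 400L), c(0L, 500L)))
  est2 <- cohort_persistence(tb2$fitting, tb2$battery_orders,
                             tb2$demographics)
  expect_equal(est2$proportion, 1)
  # a patient dying within the window is excluded, not counted against
  tb3 <- make_cohort_tables(list(c(0L, 400L), 0L),
                            death_day = c(NA, 600L))
  est3 <- cohort_persistence(tb3$fitting, tb3$battery_orders,
                             tb3$demographics)
  expect_identical(est3$n_included, 1L)
  expect_identical(est3$n_excluded_death, 1L)
  expect_equal(est3$proportion, 1)
  expect_error(cohort_persistence(tb$fitting[0, ], tb$battery_orders,
                                  tb$demographics), "eligible")
})

test_that("the persistence curve is flat at 1 before 18 months and matches the scalar", {
  set.seed(31)
  hists <- replicate(300, sort(unique(c(0L, sample.int(1000L,
                                                       sample.int(6L, 1L)) -
                                          1L))), simplify = FALSE)
  tb <- make_cohort_tables(hists)
  crv <- persistence_curve(tb$fitting, tb$battery_orders, tb$demographics,
                           t_grid = c(183L, 365L, 547L, 548L, 730L, 900L))
  expect_true(all(crv$proportion[crv$t < 548L] == 1))
  est <- cohort_persistence(tb$fitting, tb$battery_orders, tb$demographics,
                            persistence_params(eval_days = 730L))
  expect_equal(crv$proportion[crv$t == 730L], est$proportion)
  # death-free cohort: non-increasing in t
  expect_true(all(diff(crv$proportion) <= 1e-12))
})

test_that("pipeline persistence recovers the generator truth", {
  co <- default_cohort_50k()
  rep <- default_report_50k()
  tp <- true_persistence(co$config, 730L, n_sim = 200000L, seed = 404L)
  se <- sqrt(attr(tp, "se")^2 + rep$persistence$se^2)
  expect_lt(abs(rep$persistence$proportion - as.numeric(tp)), 3 * se)
})
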