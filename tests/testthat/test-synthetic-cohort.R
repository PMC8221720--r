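test_that("invalid configuration values are reported with the field name", {
  expect_error(cohort_config(male_fraction = 1.5), "male_fraction")
  expect_error(cohort_config(n_patients = -1), "n_patients")
  expect_error(cohort_config(age_mixture = data.frame(
    mean = c(60, 75), sd = c(7, 9), weight = c(0.5, 0.6))),
    "age_mixture\\$weight")
  expect_error(cohort_config(inter_battery_gap = list(median = -1,
                                                      log_sd = 0.5)),
               "inter_battery_gap\\$median")
  expect_error(cohort_config(anomaly_rates = c(bogus_key = 0.1)),
               "anomaly_rates")
})

test_that("an empty cohort yields empty tables without error", {
  co <- generate_cohort(cohort_config(n_patients = 0L))
  expect_true(all(vapply(co$tables, nrow, 0L) == 0L))
  expect_identical(nrow(co$ground_truth), 0L)
})

test_that("generation is deterministic in (config, seed) and varies with seed", {
  cfg1 <- cohort_config(n_patients = 300L, seed = 42L)
  a <- generate_cohort(cfg1)
  b <- generate_cohort(cfg1)
  expect_identical(a$tables, b$tables)
  expect_identical(a$ground_truth, b$ground_truth)
  c3 <- generate_cohort(cohort_config(n_patients = 300L, seed = 43L))
  expect_false(identical(a$tables$battery_orders,
                         c3$tables$battery_orders))
})

test_that("every patient id in any table appears in demographics", {
  co <- generate_cohort(cohort_config(n_patients = 400L, seed = 5L))
  demo_ids <- unique(co$tables$demographics$patient_id)
  for (nm in setdiff(names(co$tables), "demographics"))
    expect_true(all(co$tables[[nm]]$patient_id %in% demo_ids),
                info = nm)
})

test_that("battery orders stop at death and at the true discontinuation day", {
  co <- generate_cohort(cohort_config(n_patients = 2000L, seed = 7L))
  bo <- co$tables$battery_orders
  gt <- co$ground_truth
  last <- tapply(bo$order_day, bo$patient_id, max)
  m <- match(names(last), gt$patient_id)
  expect_true(all(as.numeric(last) < gt$discont_day[m]))
  dead <- !is.na(gt$death_day[m])
  expect_true(all(as.numeric(last)[dead] < gt$death_day[m][dead]))
  # first order = fitting day, delayed after the HA order, truncated at 0
  first <- tapply(bo$order_day, bo$patient_id, min)
  expect_true(all(as.numeric(first) >= gt$ha_order_day[m]))
  expect_identical(as.integer(first), gt$fitting_day[m])
})

test_that("never_fraction = 1 leaves every discontinuation day infinite", {
  cfg <- cohort_config(n_patients = 500L, seed = 3L,
                       discontinuation = list(never_fraction = 1,
                                              hazard_per_year = 1.18))
  co <- generate_cohort(cfg)
  expect_true(all(is.infinite(co$ground_truth$discont_day)))
})

test_that("patients with and without battery orders partition the cohort", {
  co <- generate_cohort(cohort_config(n_patients = 1500L, seed = 9L))
  with_orders <- length(unique(co$tables$battery_orders$patient_id))
  all_ids <- unique(co$tables$demographics$patient_id)
  without <- sum(!all_ids %in% co$tables$battery_orders$patient_id)
  expect_identical(with_orders + without, length(all_ids))
})

test_that("anomaly injection at rate zero is the identity", {
  co <- generate_cohort(cohort_config(n_patients = 200L, seed = 1L,
                                      anomaly_rates = c(above_limit_code = 0)))
  inj <- inject_anomalies(co$tables, c(above_limit_code = 0,
                                       ambiguous_nonnumeric = 0), seed = 4L)
  expect_identical(inj$tables, co$tables)
  expect_identical(nrow(inj$log), 0L)
})

test_that("anomaly injection rejects unknown keys", {
  co <- generate_cohort(cohort_config(n_patients = 10L, seed = 1L))
  expect_error(inject_anomalies(co$tables, c(not_an_anomaly = 0.1)),
               "unknown anomaly key")
})

test_that("saturating the above-limit rate replaces every threshold entry", {
  cfg <- cohort_config(n_patients = 50L, seed = 2L,
                       audiogram_available_prob = 1,
                       anomaly_rates = c(above_limit_code = 0))
  co <- generate_cohort(cfg)
  inj <- inject_anomalies(co$tables, c(above_limit_code = 1), seed = 8L)
  expect_true(all(inj$tables$audiometry$entry == "NR"))
  expect_identical(nrow(inj$log), nrow(co$tables$audiometry))
})

test_that("injected not-divisible-by-5 count matches an independent recount", {
  cfg <- cohort_config(n_patients = 60L, seed = 6L,
                       audiogram_available_prob = 1,
                       anomaly_rates = c(above_limit_code = 0))
  co <- generate_cohort(cfg)
  n_entries <- nrow(co$tables$audiometry)
  expect_gt(n_entries, 1000L)
  inj <- inject_anomalies(co$tables, c(not_divisible_by_5 = 0.1), seed = 31L)
  vals <- suppressWarnings(as.numeric(inj$tables$audiometry$entry))
  recount <- sum(!is.na(vals) & vals %% 5 != 0)
  expect_identical(recount, nrow(inj$log))
  # binomially plausible around rate * n
  expect_lt(abs(recount - 0.1 * n_entries),
            3 * sqrt(n_entries * 0.1 * 0.9) + 1)
})

test_that("generated marginals match configured values at n = 50,000", {
  co <- default_cohort_50k()
  cfg <- co$config
  n <- cfg$n_patients
  demo1 <- co$tables$demographics[
    !duplicated(co$tables$demographics$patient_id), ]
  se <- function(p) sqrt(p * (1 - p) / n)

  male <- mean(demo1$gender == "M")
  expect_lt(abs(male - cfg$male_fraction), 3 * se(cfg$male_fraction))

  aud_frac <- length(unique(co$tables$audiometry$patient_id)) / n
  expect_lt(abs(aud_frac - cfg$audiogram_available_prob),
            3 * se(cfg$audiogram_available_prob))

  # IOI response among fitted patients
  gt <- co$ground_truth
  fitted <- gt$fitting_day - gt$ha_order_day <= 180L
  resp <- mean(gt$patient_id[fitted] %in% co$tables$ioi$patient_id)
  expect_lt(abs(resp - cfg$ioi_response_prob),
            3 * sqrt(cfg$ioi_response_prob * (1 - cfg$ioi_response_prob) /
                       sum(fitted)))

  # death fraction vs the config-implied expectation, computed from the
  # configured age mixture, order window and hazard bands
  set.seed(99L)
  m <- 200000L
  comp <- sample.int(nrow(cfg$age_mixture), m, replace = TRUE,
                     prob = cfg$age_mixture$weight)
  age <- pmin(pmax(stats::rnorm(m, cfg$age_mixture$mean[comp],
                                cfg$age_mixture$sd[comp]), 20), 100)
  idx <- findInterval(age, cfg$death_hazard$age_min)
  haz <- cfg$death_hazard$rate[pmax(idx, 1L)]
  order_day <- sample(0:943, m, replace = TRUE)
  p_death <- mean(1 - exp(-haz * (2101 - order_day) / 365))
  death_frac <- mean(!is.na(demo1$death_day))
  expect_lt(abs(death_frac - p_death), 3 * se(p_death))
})

test_that("true persistence is exactly 1 before dose + gap has elapsed", {
  cfg <- cohort_config(n_patients = 10L)
  tp <- true_persistence(cfg, 547L)
  expect_identical(as.numeric(tp), 1)
  expect_identical(attr(tp, "se"), 0)
  # degenerate: nobody discontinues, short window
  cfg1 <- cohort_config(discontinuation = list(never_fraction = 1,
                                               hazard_per_year = 0))
  expect_identical(as.numeric(true_persistence(cfg1, 365L)), 1)
})

test_that("Monte-Carlo truth matches the closed form for a degenerate gap", {
  # gaps fixed at 180 days, no never-discontinue mass, hazard chosen so
  # P(discontinue by day 182) = 0.5. Persistence at 730 requires the order
  # at day 360 to exist, i.e. tau > 360: P = 0.5^(360/182).
  h_year <- log(2) / 182 * 365
  cfg <- cohort_config(
    discontinuation = list(never_fraction = 0, hazard_per_year = h_year),
    inter_battery_gap = list(median = 180, log_sd = 1e-9))
  tp <- true_persistence(cfg, 730L, n_sim = 100000L, seed = 21L)
  expected <- 0.5^(360 / 182)
  expect_lt(abs(as.numeric(tp) - expected), 4 * attr(tp, "se"))
  expect_gt(attr(tp, "se"), 0)
})

test_that("cohorts round-trip through CSV with ISO dates", {
  co <- generate_cohort(cohort_config(n_patients = 80L, seed = 12L))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  demo_csv <- utils::read.csv(file.path(dir, "demographics.csv"),
                              nrows = 2L)
  expect_match(demo_csv$birth_date[1L], "^\\d{4}-\\d{2}-\\d{2}$")
  back <- read_cohort(dir)
  for (nm in names(co$tables)) {
    a <- co$tables[[nm]]
    b <- back$tables[[nm]][, names(a), drop = FALSE]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, info = nm)
  }
})
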