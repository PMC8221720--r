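cci <- load_cci_map()

dx <- function(codes, days = -100L) {
  data.frame(icd_code = codes, day = days, stringsAsFactors = FALSE)
}

test_that("the index counts body systems with at least two chronic codes", {
  # two chronic codes in two systems plus hearing-loss codes -> 2
  d <- dx(c("272.4", "244.9", "401.9", "428.0", "389.10", "389.18",
            "389.10"))
  expect_identical(multimorbidity_index(d, 0L, cci)$index, 2L)
  # only hearing-loss codes -> 0
  expect_identical(multimorbidity_index(dx(c("389.10", "389.18")), 0L,
                                        cci)$index, 0L)
  # one chronic code in each of five systems -> 0
  d5 <- dx(c("042", "153.9", "272.4", "282.60", "295.90"))
  expect_identical(multimorbidity_index(d5, 0L, cci)$index, 0L)
  # non-chronic codes never count
  dn <- dx(rep(c("486", "599.0"), 3L))
  expect_identical(multimorbidity_index(dn, 0L, cci)$index, 0L)
})

test_that("the lookback window is half-open [index - 365, index)", {
  d <- dx(rep("272.4", 2L), days = c(-365L, -1L))
  expect_identical(multimorbidity_index(d, 0L, cci)$index, 1L)
  # a code on the index day itself is excluded
  d2 <- dx(rep("272.4", 2L), days = c(-10L, 0L))
  expect_identical(multimorbidity_index(d2, 0L, cci)$index, 0L)
  # a code just outside the window is excluded
  d3 <- dx(rep("272.4", 2L), days = c(-366L, -10L))
  expect_identical(multimorbidity_index(d3, 0L, cci)$index, 0L)
})

test_that("codes match by prefix and unknown codes are non-chronic", {
  d <- dx(c("250.01", "250.93"))     # children of category 250
  expect_identical(multimorbidity_index(d, 0L, cci)$index, 1L)
  expect_identical(multimorbidity_index(dx(rep("999.99", 4L)), 0L,
                                        cci)$index, 0L)
})

test_that("the index is bounded by 18 and reaches it with full coverage", {
  chronic <- cci[cci$chronic == 1L & !startsWith(cci$norm, "389"), ]
  two_each <- do.call(rbind, lapply(1:18, function(s) {
    pool <- chronic$icd_code[chronic$body_system == s]
    dx(rep(pool[1L], 2L))
  }))
  r <- multimorbidity_index(two_each, 0L, cci)
  expect_identical(r$index, 18L)
  # exhaustive small instances: random streams never exceed 18 or go below 0
  set.seed(9)
  for (i in 1:30) {
    d <- dx(sample(cci$icd_code, sample.int(60L, 1L), replace = TRUE),
            days = -sample.int(400L, 1L))
    idx <- multimorbidity_index(d, 0L, cci)$index
    expect_gte(idx, 0L)
    expect_lte(idx, 18L)
  }
})

test_that("adding 389.XX codes never changes the index; chronic codes never lower it", {
  set.seed(4)
  for (i in 1:25) {
    d <- dx(sample(cci$icd_code, 12L, replace = TRUE),
            days = -sample.int(364L, 12L, replace = TRUE))
    base <- multimorbidity_index(d, 0L, cci)$index
    with389 <- rbind(d, dx(rep(c("389.10", "389.18"), 4L)))
    expect_identical(multimorbidity_index(with389, 0L, cci)$index, base)
    more <- rbind(d, dx("272.4", days = -50L))
    expect_gte(multimorbidity_index(more, 0L, cci)$index, base)
  }
})

test_that("scalar and table computations agree", {
  set.seed(14)
  ids <- sprintf("p%02d", 1:20)
  d <- data.frame(patient_id = rep(ids, each = 8L),
                  icd_code = sample(cci$icd_code, 160L, replace = TRUE),
                  day = 200L - sample.int(500L, 160L, replace = TRUE),
                  stringsAsFactors = FALSE)
  tab <- multimorbidity_table(d, data.frame(patient_id = ids,
                                            index_day = 200L), cci)
  for (p in ids) {
    scal <- multimorbidity_index(d[d$patient_id == p, ], 200L, cci)$index
    expect_identical(tab$mm_index[tab$patient_id == p], scal)
  }
})

test_that("condition flags use strict precedence and printed definitions", {
  defs <- condition_definitions()
  expect_true(has_condition(dx("332.0"), defs$parkinsons, 0L))
  expect_false(has_condition(dx("332.2"), defs$parkinsons, 0L))
  expect_true(has_condition(dx("250.01"), defs$diabetes, 0L))
  expect_false(has_condition(dx("332.0", days = 0L), defs$parkinsons, 0L))
  expect_false(has_condition(dx("332.0")[0, ], defs$parkinsons, 0L))
  # range-based definitions match on the 3-digit category
  expect_true(has_condition(dx("365.11"), defs$arthritis, 0L))
  expect_true(has_condition(dx("714.0"), defs$vision_impairment, 0L))
  expect_false(has_condition(dx("714.0"), defs$arthritis, 0L))
})

test_that("inpatient flags use strict admission precedence", {
  inp <- data.frame(admit_day = c(-30L))
  expect_true(had_inpatient_stay(inp, 0L))
  expect_false(had_inpatient_stay(inp[0, , drop = FALSE], 0L))
  expect_false(had_inpatient_stay(data.frame(admit_day = 0L), 0L))
})

test_that("the cohort mean index recovers the configured prevalences", {
  co <- default_cohort_50k()
  rep <- default_report_50k()
  cfg <- co$config
  lam <- cfg$chronic_prevalence$codes_lambda
  # per affected system the code count is 1 + Poisson(lambda), all dated
  # in-window, so P(>= 2 codes) = 1 - dpois(0, lambda)
  p_sys <- cfg$chronic_prevalence$system_prob * (1 - stats::dpois(0, lam))
  expected <- sum(p_sys)
  sd_one <- sqrt(sum(p_sys * (1 - p_sys)))
  mm <- rep$patients$mm_index
  expect_lt(abs(mean(mm) - expected), 3 * sd_one / sqrt(length(mm)))
})
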