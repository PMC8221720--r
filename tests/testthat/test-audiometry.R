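test_that("cleaning maps tokens and off-grid values per the rules", {
  aud <- data.frame(ear = "L", frequency_hz = 4000L,
                    entry = c("NR", "120+", ">120", "55", "47", "DNT",
                              "CNT", "--", "", "125", "-15", "55.5"))
  cl <- clean_audiogram(aud)
  expect_equal(cl$threshold_db,
               c(120, 120, 120, 55, NA, NA, NA, NA, NA, NA, NA, NA))
  expect_identical(cl$provenance,
                   c(rep("ceiling_substituted", 3L), "as_entered",
                     rep("set_missing", 8L)))
})

test_that("cleaning is idempotent on its numeric output", {
  aud <- make_audiogram(left = c(40, 50, 60, 70),
                        right = c(45, 55, 65, 75))
  aud$entry[3L] <- "NR"
  cl <- clean_audiogram(aud)
  # re-clean the cleaned values: every numeric value survives unchanged
  re <- aud
  re$entry <- ifelse(is.na(cl$threshold_db), "--",
                     as.character(cl$threshold_db))
  cl2 <- clean_audiogram(re)
  expect_equal(cl2$threshold_db, cl$threshold_db)
})

test_that("validity depends only on the four PTA frequencies of both ears", {
  full <- clean_audiogram(make_audiogram())
  expect_true(is_valid_audiogram(full))
  with8k <- make_audiogram(freqs = c(500L, 1000L, 2000L, 4000L, 8000L),
                           left = c(40, 50, 60, 70, NA),
                           right = c(40, 50, 60, 70, NA))
  with8k$entry[with8k$frequency_hz == 8000L] <- "DNT"
  expect_true(is_valid_audiogram(clean_audiogram(with8k)))
  miss2k <- make_audiogram()
  miss2k$entry[miss2k$ear == "L" & miss2k$frequency_hz == 2000L] <- "CNT"
  expect_false(is_valid_audiogram(clean_audiogram(miss2k)))
  ceiling_only <- make_audiogram()
  ceiling_only$entry <- "NR"          # 120 dB substitutions still count
  expect_true(is_valid_audiogram(clean_audiogram(ceiling_only)))
})

test_that("averaging is cell-wise over numeric values only", {
  a1 <- clean_audiogram(make_audiogram(left = c(40, 40, 40, 40),
                                       right = c(40, 40, 40, 40)))
  a2 <- clean_audiogram(make_audiogram(left = c(50, 50, 50, 50),
                                       right = c(50, 50, 50, 50),
                                       exam_day = 10L))
  avg <- average_audiograms(rbind(a1, a2))
  expect_true(all(avg$threshold_db == 45))
  # identity on a single audiogram
  one <- average_audiograms(a1)
  expect_equal(one$threshold_db[one$ear == "L" & one$frequency_hz == 1000L],
               40)
  # numeric-in-one, missing-in-the-other keeps the numeric value
  a2m <- a2
  a2m$threshold_db[a2m$ear == "L" & a2m$frequency_hz == 500L] <- NA
  avg2 <- average_audiograms(rbind(a1, a2m))
  expect_equal(avg2$threshold_db[avg2$ear == "L" &
                                   avg2$frequency_hz == 500L], 40)
  expect_equal(avg2$n_exams[avg2$ear == "L" & avg2$frequency_hz == 500L], 1L)
  # permutation invariance
  expect_equal(average_audiograms(rbind(a2, a1))$threshold_db,
               avg$threshold_db)
})

test_that("4F-PTA and asymmetry follow the 15 dB rule", {
  pta <- compute_4f_pta(clean_audiogram(make_audiogram(
    left = c(40, 50, 60, 70), right = c(40, 50, 60, 70))))
  expect_equal(pta$pta_left, 55)
  expect_equal(pta$pta_bilateral, 55)
  expect_false(pta$asymmetric)
  expect_identical(pta$worse_ear, "none")

  # difference of exactly 15 dB qualifies
  p2 <- compute_4f_pta(clean_audiogram(make_audiogram(
    left = c(50, 50, 50, 50), right = c(35, 35, 35, 35))))
  expect_true(p2$asymmetric)
  expect_identical(p2$worse_ear, "left")

  p3 <- compute_4f_pta(clean_audiogram(make_audiogram(
    left = c(50, 50, 50, 50), right = c(35, 35, 40, 35))))
  expect_equal(abs(p3$pta_left - p3$pta_right), 13.75)
  expect_false(p3$asymmetric)

  invalid <- make_audiogram()
  invalid$entry[1L] <- "DNT"
  expect_error(compute_4f_pta(clean_audiogram(invalid)), "not valid")
})

test_that("raising any contributing threshold never lowers a PTA", {
  set.seed(42)
  for (i in 1:25) {
    l <- 5 * sample(0:20, 4, replace = TRUE)
    r <- 5 * sample(0:20, 4, replace = TRUE)
    base <- compute_4f_pta(clean_audiogram(make_audiogram(l, r)))
    j <- sample.int(4L, 1L)
    l2 <- l; l2[j] <- l2[j] + 5
    up <- compute_4f_pta(clean_audiogram(make_audiogram(l2, r)))
    expect_gte(up$pta_left, base$pta_left)
    expect_gte(up$pta_bilateral, base$pta_bilateral)
    expect_equal(up$pta_right, base$pta_right)
  }
})

test_that("ceiling-substitution prevalence matches the injected rate", {
  rate <- 0.02
  cfg <- cohort_config(n_patients = 3000L, seed = 55L,
                       audiogram_available_prob = 1,
                       multi_audiogram_prob = 0,
                       anomaly_rates = c(above_limit_code = rate))
  co <- generate_cohort(cfg)
  cl <- clean_audiogram(co$tables$audiometry)
  exam_key <- paste(cl$patient_id, cl$exam_day)
  affected <- tapply(cl$provenance == "ceiling_substituted", exam_key, any)
  # per-audiogram probability of >= 1 substituted cell among 18 entries
  p_aff <- 1 - (1 - rate)^18
  expect_lt(abs(mean(affected) - p_aff),
            3 * sqrt(p_aff * (1 - p_aff) / length(affected)))
})

test_that("the per-patient summary averages multiple audiograms", {
  aud <- rbind(make_audiogram(left = c(40, 40, 40, 40),
                              right = c(40, 40, 40, 40)),
               make_audiogram(left = c(50, 50, 50, 50),
                              right = c(50, 50, 50, 50), exam_day = 30L),
               make_audiogram(left = c(20, 20, 20, 20),
                              right = c(20, 20, 20, 20),
                              patient_id = "q"))
  s <- summarize_audiometry(aud)
  expect_identical(nrow(s$pta), 2L)
  p <- s$pta[s$pta$patient_id == "p", ]
  expect_equal(p$pta_left, 45)
  expect_identical(p$n_audiograms, 2L)
  expect_equal(s$pta$pta_left[s$pta$patient_id == "q"], 20)
})
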