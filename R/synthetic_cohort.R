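# Synthetic EHR cohort generator.
#
# Emulates the relational extract of a VA-style hearing-aid cohort: duplicate
# per-station demographic records, a death process, sloping bilateral hearing
# losses with a small left-worse asymmetry excess, hearing-aid orders followed
# by battery-order (refill) streams, patient-level discontinuation of battery
# ordering, ICD-9 chronic-condition code streams, partial IOI-HA response,
# and controlled injection of the data anomalies the cleaning rules target.
# Latent ground truth (true discontinuation day, true chronic-system sets,
# pre-anomaly thresholds) is retained for parameter-recovery testing.

AUDIO_FREQS <- c(250L, 500L, 1000L, 1500L, 2000L, 3000L, 4000L, 6000L, 8000L)
# per-frequency offsets (dB) relative to the 4F-PTA of a sloping loss;
# offsets at 0.5/1/2/4 kHz average to zero so the target PTA is preserved
AUDIO_SHAPE <- c(-20, -15, -8, -2, 3, 8, 20, 25, 28)

ANOMALY_KEYS <- c("above_limit_code", "ambiguous_nonnumeric",
                  "not_divisible_by_5", "duplicate_demographic_inconsistency",
                  "implausible_death_date")

#' Configuration of the synthetic hearing-aid cohort generator
#'
#' Defaults are calibrated to the descriptive statistics of a large veteran
#' hearing-aid cohort: mean age near 70.6 years with a bimodal age
#' distribution, 98.4% male, mean 4F-PTAs near 49.9/48.7 dB HL
#' (left/right, SD 16.8), 14.6% clinically relevant asymmetry of which
#' 57.7% left-worse, a mean hearing-aid-order to first-battery-order lag of
#' 42 days (SD 46.6), right-skewed inter-battery gaps with median 7.8 months,
#' roughly 20% mortality over follow-up, 78.6% audiogram availability,
#' 20.1% IOI-HA response, and a two-year use persistence near 63%.
#'
#' @param n_patients number of patients.
#' @param male_fraction probability a patient is male.
#' @param age_mixture data.frame with columns `mean`, `sd`, `weight` (years);
#'   component weights must sum to 1. Age at the index hearing-aid order is
#'   drawn from this normal mixture, truncated to 20-100 years.
#' @param death_hazard data.frame with columns `age_min`, `rate`: piecewise
#'   constant per-year mortality hazard by age band.
#' @param pta_mean_left,pta_mean_right,pta_sd dB HL; distribution of the true
#'   per-ear four-frequency pure-tone averages.
#' @param asymmetry_prob probability of a clinically relevant (>= 15 dB)
#'   left-right asymmetry.
#' @param left_worse_prob_given_asym probability the left ear is the worse
#'   ear given an asymmetry.
#' @param discontinuation list with `never_fraction` (point mass of patients
#'   who never discontinue hearing-aid use) and `hazard_per_year`
#'   (exponential discontinuation hazard for the remainder).
#' @param morbidity_coupling log hazard-ratio of discontinuation per true
#'   chronic body system (0 = discontinuation independent of morbidity).
#' @param order_to_first_battery list with `mean`, `sd` (days): normal lag,
#'   truncated at 0, between the hearing-aid order and the first battery
#'   order (the fitting-date proxy).
#' @param inter_battery_gap list with `median` (days) and `log_sd`:
#'   log-normal gaps between successive battery orders.
#' @param ioi_response_prob probability that a fitted patient returns an
#'   IOI-HA questionnaire.
#' @param audiogram_available_prob probability a patient has audiometric data.
#' @param multi_audiogram_prob probability an audiogram-bearing patient has a
#'   second audiogram.
#' @param experienced_fraction fraction labelled experienced hearing-aid
#'   users by the ordering system.
#' @param second_order_prob probability of a second hearing-aid order.
#' @param station_count_probs probabilities of a patient having 1, 2, or 3
#'   per-station demographic records.
#' @param inpatient_prob probability of at least one inpatient stay before
#'   the hearing-aid order.
#' @param chronic_prevalence list with `system_prob` (length-18 vector of
#'   per-body-system chronic-condition prevalences) and `codes_lambda`
#'   (codes per affected system are 1 + Poisson(`codes_lambda`), all dated
#'   within 12 months before the order).
#' @param anomaly_rates named numeric vector of injection rates; see
#'   [inject_anomalies()].
#' @param seed integer seed; identical configurations (including the seed)
#'   reproduce byte-identical cohorts.
#' @return an object of class `cohort_config` (a validated named list).
#' @export
cohort_config <- function(n_patients = 1000L,
                          male_fraction = 0.984,
                          age_mixture = data.frame(
                            mean = c(62, 75.2), sd = c(7, 9),
                            weight = c(0.35, 0.65)),
                          death_hazard = data.frame(
                            age_min = c(0, 60, 70, 80, 90),
                            rate = c(0.010, 0.025, 0.050, 0.105, 0.220)),
                          pta_mean_left = 49.9,
                          pta_mean_right = 48.7,
                          pta_sd = 16.8,
                          asymmetry_prob = 0.146,
                          left_worse_prob_given_asym = 0.577,
                          discontinuation = list(never_fraction = 0.5,
                                                 hazard_per_year = 1.18),
                          morbidity_coupling = 0,
                          order_to_first_battery = list(mean = 42, sd = 46.6),
                          inter_battery_gap = list(median = 237, log_sd = 0.62),
                          ioi_response_prob = 0.201,
                          audiogram_available_prob = 0.786,
                          multi_audiogram_prob = 0.13,
                          experienced_fraction = 0.47,
                          second_order_prob = 0.022,
                          station_count_probs = c(0.65, 0.28, 0.07),
                          inpatient_prob = 0.25,
                          chronic_prevalence = list(
                            system_prob = c(0.06, 0.09, 0.30, 0.05, 0.10,
                                            0.25, 0.45, 0.08, 0.12, 0.16,
                                            0.06, 0.18, 0.38, 0.10, 0.03,
                                            0.22, 0.26, 0.25),
                            codes_lambda = 2),
                          anomaly_rates = c(
                            above_limit_code = 0.015,
                            ambiguous_nonnumeric = 0.00025,
                            not_divisible_by_5 = 0.00025,
                            duplicate_demographic_inconsistency = 4e-04,
                            implausible_death_date = 6e-05),
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients, male_fraction = male_fraction,
    age_mixture = age_mixture, death_hazard = death_hazard,
    pta_mean_left = pta_mean_left, pta_mean_right = pta_mean_right,
    pta_sd = pta_sd, asymmetry_prob = asymmetry_prob,
    left_worse_prob_given_asym = left_worse_prob_given_asym,
    discontinuation = discontinuation,
    morbidity_coupling = morbidity_coupling,
    order_to_first_battery = order_to_first_battery,
    inter_battery_gap = inter_battery_gap,
    ioi_response_prob = ioi_response_prob,
    audiogram_available_prob = audiogram_available_prob,
    multi_audiogram_prob = multi_audiogram_prob,
    experienced_fraction = experienced_fraction,
    second_order_prob = second_order_prob,
    station_count_probs = station_count_probs,
    inpatient_prob = inpatient_prob,
    chronic_prevalence = chronic_prevalence,
    anomaly_rates = anomaly_rates,
    seed = seed)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
      stop_field(field, "must be a probability in [0, 1]")
  }
  chk_pos <- function(x, field) {
    if (!is.numeric(x) || anyNA(x) || any(x <= 0))
      stop_field(field, "must be strictly positive")
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != round(cfg$n_patients))
    stop_field("n_patients", "must be a non-negative integer")
  chk_prob(cfg$male_fraction, "male_fraction")
  chk_prob(cfg$asymmetry_prob, "asymmetry_prob")
  chk_prob(cfg$left_worse_prob_given_asym, "left_worse_prob_given_asym")
  chk_prob(cfg$ioi_response_prob, "ioi_response_prob")
  chk_prob(cfg$audiogram_available_prob, "audiogram_available_prob")
  chk_prob(cfg$multi_audiogram_prob, "multi_audiogram_prob")
  chk_prob(cfg$experienced_fraction, "experienced_fraction")
  chk_prob(cfg$second_order_prob, "second_order_prob")
  chk_prob(cfg$inpatient_prob, "inpatient_prob")
  chk_prob(cfg$station_count_probs, "station_count_probs")
  if (abs(sum(cfg$station_count_probs) - 1) > 1e-8)
    stop_field("station_count_probs", "must sum to 1")
  am <- cfg$age_mixture
  if (!all(c("mean", "sd", "weight") %in% names(am)))
    stop_field("age_mixture", "needs columns mean, sd, weight")
  chk_pos(am$sd, "age_mixture$sd")
  chk_prob(am$weight, "age_mixture$weight")
  if (abs(sum(am$weight) - 1) > 1e-8)
    stop_field("age_mixture$weight", "weights must sum to 1")
  if (!all(c("age_min", "rate") %in% names(cfg$death_hazard)))
    stop_field("death_hazard", "needs columns age_min, rate")
  if (any(cfg$death_hazard$rate < 0))
    stop_field("death_hazard$rate", "must be non-negative")
  if (is.unsorted(cfg$death_hazard$age_min, strictly = TRUE))
    stop_field("death_hazard$age_min", "must be strictly increasing")
  chk_pos(cfg$pta_sd, "pta_sd")
  chk_prob(cfg$discontinuation$never_fraction,
           "discontinuation$never_fraction")
  if (cfg$discontinuation$hazard_per_year < 0)
    stop_field("discontinuation$hazard_per_year", "must be non-negative")
  chk_pos(cfg$order_to_first_battery$sd, "order_to_first_battery$sd")
  chk_pos(cfg$inter_battery_gap$median, "inter_battery_gap$median")
  chk_pos(cfg$inter_battery_gap$log_sd, "inter_battery_gap$log_sd")
  cp <- cfg$chronic_prevalence
  if (length(cp$system_prob) != 18L)
    stop_field("chronic_prevalence$system_prob", "must have length 18")
  chk_prob(cp$system_prob, "chronic_prevalence$system_prob")
  chk_pos(cp$codes_lambda, "chronic_prevalence$codes_lambda")
  bad <- setdiff(names(cfg$anomaly_rates), ANOMALY_KEYS)
  if (length(bad))
    stop_field("anomaly_rates", paste("unknown anomaly key:",
                                      paste(bad, collapse = ", ")))
  chk_prob(cfg$anomaly_rates, "anomaly_rates")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    stop_field("seed", "must be a single integer")
  invisible(cfg)
}

# piecewise-constant per-year hazard at a given age
.hazard_at_age <- function(age, death_hazard) {
  idx <- findInterval(age, death_hazard$age_min)
  death_hazard$rate[pmax(idx, 1L)]
}

# Vectorised battery-order engine: orders at the fitting day and then at
# log-normal gaps, generated only strictly before the (absolute)
# discontinuation day and while the patient is alive and observed.
# Returns a data.frame(patient_id, order_day).
.sim_battery_stream <- function(patient_id, fitting_day, stop_day,
                                gap_median, gap_log_sd) {
  n <- length(fitting_day)
  meanlog <- log(gap_median)
  ids <- list(); days <- list(); k <- 0L
  alive0 <- fitting_day < stop_day
  if (any(alive0)) {
    k <- k + 1L
    ids[[k]] <- patient_id[alive0]
    days[[k]] <- fitting_day[alive0]
  }
  act <- which(alive0)
  cur <- fitting_day[alive0]
  while (length(act)) {
    gaps <- pmax(1, round(stats::rlnorm(length(act), meanlog, gap_log_sd)))
    nxt <- cur + gaps
    keep <- nxt < stop_day[act]
    act <- act[keep]
    cur <- nxt[keep]
    if (length(act)) {
      k <- k + 1L
      ids[[k]] <- patient_id[act]
      days[[k]] <- cur
    }
  }
  if (k == 0L)
    return(data.frame(patient_id = character(0), order_day = integer(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(patient_id = unlist(ids),
                    order_day = as.integer(unlist(days)),
                    stringsAsFactors = FALSE)
  out[order(out$patient_id, out$order_day), , drop = FALSE]
}

empty_cohort_tables <- function() {
  list(
    demographics = data.frame(patient_id = character(0),
                              station_id = character(0),
                              record_day = integer(0), birth_day = integer(0),
                              death_day = integer(0), gender = character(0),
                              stringsAsFactors = FALSE),
    diagnoses_outpatient = data.frame(patient_id = character(0),
                                      icd_code = character(0),
                                      day = integer(0),
                                      stringsAsFactors = FALSE),
    procedures_outpatient = data.frame(patient_id = character(0),
                                       proc_code = character(0),
                                       day = integer(0),
                                       stringsAsFactors = FALSE),
    inpatient = data.frame(patient_id = character(0), admit_day = integer(0),
                           discharge_day = integer(0),
                           diagnoses = character(0), stringsAsFactors = FALSE),
    audiometry = data.frame(patient_id = character(0), exam_day = integer(0),
                            ear = character(0), frequency_hz = integer(0),
                            entry = character(0), stringsAsFactors = FALSE),
    ha_orders = data.frame(patient_id = character(0), order_day = integer(0),
                           user_type = character(0), style = character(0),
                           laterality = character(0),
                           stringsAsFactors = FALSE),
    battery_orders = data.frame(patient_id = character(0),
                                order_day = integer(0),
                                stringsAsFactors = FALSE),
    ioi = data.frame(patient_id = character(0), completion_day = integer(0),
                     entry_day = integer(0), item1 = integer(0),
                     item2 = integer(0), item3 = integer(0),
                     item4 = integer(0), item5 = integer(0),
                     item6 = integer(0), item7 = integer(0),
                     item8 = integer(0), stringsAsFactors = FALSE))
}

#' Generate a synthetic hearing-aid EHR cohort
#'
#' Produces the seven linked raw tables (plus the IOI-HA survey table) of a
#' hearing-aid outcome cohort together with the latent ground truth used for
#' parameter-recovery testing, then injects data anomalies at the configured
#' rates. All day columns are integer days from the cohort epoch.
#'
#' @param config a [cohort_config()] object.
#' @return an object of class `raw_cohort`: a list with elements
#'   `tables` (named list of data.frames: demographics,
#'   diagnoses_outpatient, procedures_outpatient, inpatient, audiometry,
#'   ha_orders, battery_orders, ioi), `ground_truth` (per-patient latent
#'   variables: true discontinuation day, true chronic body-system count and
#'   set, true per-ear PTAs), `anomaly_log` (one row per injected anomaly)
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_patients)
  tables <- empty_cohort_tables()
  if (n == 0L) {
    gt <- data.frame(patient_id = character(0), ha_order_day = integer(0),
                     fitting_day = integer(0), discont_day = numeric(0),
                     n_chronic_systems = integer(0),
                     chronic_systems = character(0),
                     true_pta_left = numeric(0), true_pta_right = numeric(0),
                     death_day = integer(0), stringsAsFactors = FALSE)
    out <- list(tables = tables, ground_truth = gt,
                anomaly_log = empty_anomaly_log(), config = config)
    class(out) <- "raw_cohort"
    return(out)
  }

  pid <- sprintf("P%06d", seq_len(n))
  order_day <- sample.int(ORDER_WINDOW_END_DAY + 1L, n, replace = TRUE) - 1L
  gender <- ifelse(stats::runif(n) < config$male_fraction, "M", "F")

  comp <- sample.int(nrow(config$age_mixture), n, replace = TRUE,
                     prob = config$age_mixture$weight)
  age <- stats::rnorm(n, config$age_mixture$mean[comp],
                      config$age_mixture$sd[comp])
  age <- pmin(pmax(age, 20), 100)
  birth_day <- order_day - as.integer(round(age * 365.25))

  haz <- .hazard_at_age(age, config$death_hazard)
  death_lag <- stats::rexp(n, 1) / (haz / 365)
  death_day <- order_day + as.integer(ceiling(death_lag))
  death_day[death_day > STUDY_END_DAY] <- NA_integer_

  # chronic body systems (latent truth), ICD-9 codes within 12 months
  sp <- config$chronic_prevalence$system_prob
  sys_mat <- matrix(stats::runif(n * 18L) <
                      matrix(sp, n, 18L, byrow = TRUE), n, 18L)
  n_sys <- as.integer(rowSums(sys_mat))

  # discontinuation: never-discontinue point mass + exponential hazard,
  # optionally coupled to morbidity through a log hazard ratio per system
  never <- stats::runif(n) < config$discontinuation$never_fraction
  h_day <- config$discontinuation$hazard_per_year *
    exp(config$morbidity_coupling * n_sys) / 365
  tau_rel <- ifelse(never | h_day <= 0, Inf, stats::rexp(n, 1) / h_day)

  # battery stream anchored at the first battery order (fitting proxy)
  first_lag <- pmax(0, round(stats::rnorm(n, config$order_to_first_battery$mean,
                                          config$order_to_first_battery$sd)))
  fitting_day <- order_day + as.integer(first_lag)
  stop_day <- pmin(ifelse(is.na(death_day), Inf, death_day),
                   fitting_day + tau_rel, STUDY_END_DAY + 1L)
  tables$battery_orders <- .sim_battery_stream(
    pid, fitting_day, stop_day,
    config$inter_battery_gap$median, config$inter_battery_gap$log_sd)

  # demographics: one row per patient-station, identical fields
  n_stations <- sample.int(3L, n, replace = TRUE,
                           prob = config$station_count_probs)
  stations <- c("506", "523", "608", "640", "653", "663", "687", "691")
  st_idx <- rep(seq_len(n), n_stations)
  station_id <- unlist(lapply(n_stations, function(k) sample(stations, k)))
  record_day <- rep(order_day, n_stations) -
    sample.int(2000L, sum(n_stations), replace = TRUE) + 1L
  tables$demographics <- data.frame(
    patient_id = pid[st_idx], station_id = station_id,
    record_day = as.integer(record_day), birth_day = birth_day[st_idx],
    death_day = death_day[st_idx], gender = gender[st_idx],
    stringsAsFactors = FALSE)

  # hearing-aid orders
  style <- sample(c("BTE", "ITE", "RIC"), n, replace = TRUE,
                  prob = c(0.264, 0.30, 0.437))
  laterality <- sample(c("bilateral", "left", "right"), n, replace = TRUE,
                       prob = c(0.910, 0.049, 0.041))
  user_type <- ifelse(stats::runif(n) < config$experienced_fraction,
                      "experienced", "new")
  ha <- data.frame(patient_id = pid, order_day = order_day,
                   user_type = user_type, style = style,
                   laterality = laterality, stringsAsFactors = FALSE)
  second <- which(stats::runif(n) < config$second_order_prob)
  if (length(second)) {
    ha2 <- ha[second, , drop = FALSE]
    ha2$order_day <- ha2$order_day +
      sample(100:800, length(second), replace = TRUE)
    ha2$user_type <- "experienced"
    alive2 <- is.na(death_day[second]) | ha2$order_day < death_day[second]
    ha <- rbind(ha, ha2[alive2 & ha2$order_day <= STUDY_END_DAY, ,
                        drop = FALSE])
  }
  tables$ha_orders <- ha[order(ha$patient_id, ha$order_day), , drop = FALSE]

  # audiometry: sloping bilateral losses around true per-ear 4F-PTAs
  pta_r <- stats::rnorm(n, config$pta_mean_right, config$pta_sd)
  asym <- stats::runif(n) < config$asymmetry_prob
  left_worse <- stats::runif(n) < config$left_worse_prob_given_asym
  shift <- (15 + stats::rexp(n, 1 / 8)) * ifelse(left_worse, 1, -1)
  pta_l <- pta_r + (config$pta_mean_left - config$pta_mean_right) +
    ifelse(asym, shift, stats::rnorm(n, 0, 4))
  pta_r <- pmin(pmax(pta_r, 0), 105)
  pta_l <- pmin(pmax(pta_l, 0), 105)

  has_aud <- stats::runif(n) < config$audiogram_available_prob
  n_aud <- ifelse(has_aud,
                  1L + (stats::runif(n) < config$multi_audiogram_prob), 0L)
  aud_pat <- rep(seq_len(n), n_aud)
  exam_no <- sequence(n_aud)
  exam_lag0 <- ifelse(stats::runif(length(aud_pat)) < 0.6, 0L,
                      sample.int(180L, length(aud_pat), replace = TRUE))
  exam_day <- order_day[aud_pat] -
    ifelse(exam_no == 1L, exam_lag0,
           -sample.int(400L, length(aud_pat), replace = TRUE))
  nf <- length(AUDIO_FREQS)
  cell_pat <- rep(aud_pat, each = 2L * nf)
  cell_exam <- rep(exam_day, each = 2L * nf)
  ear <- rep(rep(c("L", "R"), each = nf), length(aud_pat))
  freq <- rep(AUDIO_FREQS, 2L * length(aud_pat))
  base <- ifelse(ear == "L", pta_l[cell_pat], pta_r[cell_pat])
  thr <- base + rep(AUDIO_SHAPE, 2L * length(aud_pat)) +
    stats::rnorm(length(cell_pat), 0, 6)
  thr <- pmin(pmax(5 * round(thr / 5), -10), 120)
  tables$audiometry <- data.frame(
    patient_id = pid[cell_pat], exam_day = as.integer(cell_exam), ear = ear,
    frequency_hz = freq, entry = as.character(as.integer(thr)),
    stringsAsFactors = FALSE)

  # outpatient diagnoses: chronic codes per affected system (12-month
  # window), hearing-loss 389.XX codes for everyone, acute noise codes
  cci <- cci_map_synthetic()
  chronic_codes <- cci$icd_code[cci$chronic == 1 &
                                  !startsWith(cci$norm, "389")]
  chronic_sys <- cci$body_system[cci$chronic == 1 &
                                   !startsWith(cci$norm, "389")]
  codes_389 <- cci$icd_code[startsWith(cci$norm, "389")]
  acute_codes <- cci$icd_code[cci$chronic == 0]
  hit <- which(sys_mat, arr.ind = TRUE)
  n_codes <- 1L + stats::rpois(nrow(hit), config$chronic_prevalence$codes_lambda)
  dpat <- rep(hit[, 1L], n_codes)
  dsys <- rep(hit[, 2L], n_codes)
  dcode <- character(length(dsys))
  for (s in unique(dsys)) {
    idx <- which(dsys == s)
    pool <- chronic_codes[chronic_sys == s]
    dcode[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
  }
  dday <- order_day[dpat] - sample.int(365L, length(dpat), replace = TRUE)
  n389 <- sample.int(3L, n, replace = TRUE)
  hpat <- rep(seq_len(n), n389)
  hcode <- sample(codes_389, length(hpat), replace = TRUE)
  hday <- order_day[hpat] - sample.int(500L, length(hpat), replace = TRUE)
  nacute <- stats::rpois(n, 2)
  apat <- rep(seq_len(n), nacute)
  acode <- sample(acute_codes, length(apat), replace = TRUE)
  aday <- order_day[apat] - sample.int(1825L, length(apat), replace = TRUE)
  dx <- data.frame(
    patient_id = pid[c(dpat, hpat, apat)],
    icd_code = c(dcode, hcode, acode),
    day = as.integer(c(dday, hday, aday)), stringsAsFactors = FALSE)
  tables$diagnoses_outpatient <- dx[order(dx$patient_id, dx$day), ,
                                    drop = FALSE]

  # outpatient procedures: audiometry CPT on exam days, hearing-aid
  # examination code on order days, fitting/orientation code on most
  # fitting days
  ex1 <- exam_no == 1L
  pr <- rbind(
    data.frame(patient_id = pid[aud_pat], proc_code = "92557",
               day = as.integer(exam_day), stringsAsFactors = FALSE),
    data.frame(patient_id = pid, proc_code = "V5010", day = order_day,
               stringsAsFactors = FALSE),
    {
      fit62 <- stats::runif(n) < 0.62
      data.frame(patient_id = pid[fit62], proc_code = "V5011",
                 day = fitting_day[fit62], stringsAsFactors = FALSE)
    })
  tables$procedures_outpatient <- pr[order(pr$patient_id, pr$day), ,
                                     drop = FALSE]

  # inpatient stays before the order for a subset of patients
  has_inp <- which(stats::runif(n) < config$inpatient_prob)
  if (length(has_inp)) {
    admit <- order_day[has_inp] -
      sample(30:730, length(has_inp), replace = TRUE)
    tables$inpatient <- data.frame(
      patient_id = pid[has_inp], admit_day = as.integer(admit),
      discharge_day = as.integer(admit +
                                   sample.int(14L, length(has_inp),
                                              replace = TRUE)),
      diagnoses = sample(c(chronic_codes, acute_codes), length(has_inp),
                         replace = TRUE),
      stringsAsFactors = FALSE)
  }

  # IOI-HA surveys among fitted responders; item scores from a per-patient
  # latent satisfaction, item 8 loosely tied to the true bilateral PTA
  fitted <- first_lag <= 180L
  responder <- which(fitted & stats::runif(n) < config$ioi_response_prob)
  if (length(responder)) {
    lag <- .sim_ioi_lag(length(responder))
    comp_day <- fitting_day[responder] + lag
    latent <- stats::rnorm(length(responder), 4.11, 0.55)
    items <- matrix(0L, length(responder), 7L)
    for (i in 1:7)
      items[, i] <- pmin(pmax(round(latent +
                                      stats::rnorm(length(responder),
                                                   0, 0.55)), 1L), 5L)
    pta_bi <- (pta_l[responder] + pta_r[responder]) / 2
    item8 <- pmin(pmax(round(1 + (pta_bi - 15) / 25 +
                               stats::rnorm(length(responder), 0, 0.9)),
                       1L), 5L)
    ioi <- data.frame(patient_id = pid[responder],
                      completion_day = as.integer(comp_day),
                      entry_day = as.integer(comp_day +
                                               sample(0:14, length(responder),
                                                      replace = TRUE)),
                      stringsAsFactors = FALSE)
    for (i in 1:7) ioi[[paste0("item", i)]] <- as.integer(items[, i])
    ioi$item8 <- as.integer(item8)
    tables$ioi <- ioi[order(ioi$patient_id, ioi$completion_day), ,
                      drop = FALSE]
  }

  gt <- data.frame(
    patient_id = pid, ha_order_day = order_day, fitting_day = fitting_day,
    discont_day = fitting_day + tau_rel, n_chronic_systems = n_sys,
    chronic_systems = apply(sys_mat, 1L,
                            function(r) paste(which(r), collapse = ";")),
    true_pta_left = pta_l, true_pta_right = pta_r, death_day = death_day,
    stringsAsFactors = FALSE)

  inj <- inject_anomalies(tables, config$anomaly_rates,
                          seed = as.integer(config$seed) + 1L)
  out <- list(tables = inj$tables, ground_truth = gt,
              anomaly_log = inj$log, config = config)
  class(out) <- "raw_cohort"
  out
}

# return-lag mixture: mass inside the 14-180 day policy window in the
# empirically observed bins, small tails on either side
.sim_ioi_lag <- function(m) {
  bin <- sample.int(6L, m, replace = TRUE,
                    prob = c(0.96 * c(0.157, 0.540, 0.259, 0.045),
                             0.02, 0.02))
  lo <- c(14L, 31L, 61L, 121L, 0L, 181L)[bin]
  hi <- c(30L, 60L, 120L, 180L, 13L, 365L)[bin]
  lo + as.integer(floor(stats::runif(m) * (hi - lo + 1L)))
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat("Synthetic EHR cohort:", x$config$n_patients, "patients\n")
  for (nm in names(x$tables))
    cat(sprintf("  %-22s %8d rows\n", nm, nrow(x$tables[[nm]])))
  cat("  injected anomalies:", nrow(x$anomaly_log), "\n")
  invisible(x)
}

empty_anomaly_log <- function() {
  data.frame(anomaly = character(0), table = character(0),
             patient_id = character(0), key = character(0),
             old = character(0), new = character(0), stringsAsFactors = FALSE)
}

#' Inject data anomalies into a raw cohort
#'
#' Applies, at the given per-entry (audiometric) or per-patient
#' (demographic) rates, the anomaly classes the cleaning rules are designed
#' to handle: above-limit audiometer codes, ambiguous non-numeric entries,
#' threshold values not divisible by 5, inconsistent duplicate demographic
#' records, and implausible death dates. Anomalies are applied with
#' precedence in that order, each entry receiving at most one, so the
#' returned log is an exact account of every modification.
#'
#' @param tables a named list of raw cohort tables (the `tables` element of
#'   a [generate_cohort()] result), or a `raw_cohort` object.
#' @param rates named numeric vector; names must be drawn from
#'   `above_limit_code`, `ambiguous_nonnumeric`, `not_divisible_by_5`,
#'   `duplicate_demographic_inconsistency`, `implausible_death_date`.
#' @param seed integer seed for the injection draws.
#' @return list with `tables` (modified copy) and `log` (data.frame with one
#'   row per injected anomaly: anomaly, table, patient_id, key, old, new).
#' @export
inject_anomalies <- function(tables, rates, seed = 1L) {
  if (inherits(tables, "raw_cohort")) tables <- tables$tables
  bad <- setdiff(names(rates), ANOMALY_KEYS)
  if (length(bad))
    stop("unknown anomaly key: ", paste(bad, collapse = ", "))
  set.seed(seed)
  log <- list()
  aud <- tables$audiometry
  rate <- function(key) unname(rates[key])
  touched <- rep(FALSE, nrow(aud))

  r <- rate("above_limit_code")
  if (!is.na(r) && r > 0 && nrow(aud)) {
    pick <- which(!touched & stats::runif(nrow(aud)) < r)
    if (length(pick)) {
      log[[length(log) + 1L]] <- data.frame(
        anomaly = "above_limit_code", table = "audiometry",
        patient_id = aud$patient_id[pick],
        key = paste(aud$exam_day[pick], aud$ear[pick],
                    aud$frequency_hz[pick], sep = "|"),
        old = aud$entry[pick], new = "NR", stringsAsFactors = FALSE)
      aud$entry[pick] <- "NR"
      touched[pick] <- TRUE
    }
  }
  r <- rate("ambiguous_nonnumeric")
  if (!is.na(r) && r > 0 && nrow(aud)) {
    pick <- which(!touched & stats::runif(nrow(aud)) < r)
    if (length(pick)) {
      tok <- sample(c("DNT", "CNT", "--"), length(pick), replace = TRUE)
      log[[length(log) + 1L]] <- data.frame(
        anomaly = "ambiguous_nonnumeric", table = "audiometry",
        patient_id = aud$patient_id[pick],
        key = paste(aud$exam_day[pick], aud$ear[pick],
                    aud$frequency_hz[pick], sep = "|"),
        old = aud$entry[pick], new = tok, stringsAsFactors = FALSE)
      aud$entry[pick] <- tok
      touched[pick] <- TRUE
    }
  }
  r <- rate("not_divisible_by_5")
  if (!is.na(r) && r > 0 && nrow(aud)) {
    numeric_ok <- !is.na(suppressWarnings(as.numeric(aud$entry)))
    pick <- which(!touched & numeric_ok & stats::runif(nrow(aud)) < r)
    if (length(pick)) {
      newv <- as.character(as.numeric(aud$entry[pick]) +
                             sample(1:4, length(pick), replace = TRUE))
      log[[length(log) + 1L]] <- data.frame(
        anomaly = "not_divisible_by_5", table = "audiometry",
        patient_id = aud$patient_id[pick],
        key = paste(aud$exam_day[pick], aud$ear[pick],
                    aud$frequency_hz[pick], sep = "|"),
        old = aud$entry[pick], new = newv, stringsAsFactors = FALSE)
      aud$entry[pick] <- newv
    }
  }
  tables$audiometry <- aud

  demo <- tables$demographics
  pats <- unique(demo$patient_id)
  r <- rate("duplicate_demographic_inconsistency")
  if (!is.na(r) && r > 0 && length(pats)) {
    pick <- pats[stats::runif(length(pats)) < r]
    for (p in pick) {
      rows <- which(demo$patient_id == p)
      # ensure a duplicate record exists, then flip its gender
      if (length(rows) == 1L) {
        newrow <- demo[rows, , drop = FALSE]
        newrow$station_id <- "999"
        newrow$record_day <- newrow$record_day + 1L
        demo <- rbind(demo, newrow)
        rows <- which(demo$patient_id == p)
      }
      i <- rows[length(rows)]
      old <- demo$gender[i]
      demo$gender[i] <- if (identical(old, "M")) "F" else "M"
      log[[length(log) + 1L]] <- data.frame(
        anomaly = "duplicate_demographic_inconsistency",
        table = "demographics", patient_id = p, key = demo$station_id[i],
        old = old, new = demo$gender[i], stringsAsFactors = FALSE)
    }
  }
  r <- rate("implausible_death_date")
  if (!is.na(r) && r > 0 && length(pats)) {
    ha <- tables$ha_orders
    first_order <- tapply(ha$order_day, ha$patient_id, min)
    pick <- pats[stats::runif(length(pats)) < r]
    pick <- pick[pick %in% names(first_order)]
    for (p in pick) {
      rows <- which(demo$patient_id == p)
      old <- demo$death_day[rows[1L]]
      newd <- as.integer(first_order[[p]]) - sample(30:300, 1L)
      demo$death_day[rows] <- newd
      log[[length(log) + 1L]] <- data.frame(
        anomaly = "implausible_death_date", table = "demographics",
        patient_id = p, key = "death_day",
        old = as.character(old), new = as.character(newd),
        stringsAsFactors = FALSE)
    }
  }
  tables$demographics <- demo

  log <- if (length(log)) do.call(rbind, log) else empty_anomaly_log()
  rownames(log) <- NULL
  list(tables = tables, log = log)
}

#' Generator-implied true persistence probability
#'
#' Monte-Carlo oracle of the generator's own battery-ordering and
#' discontinuation process: the probability that a patient drawn from
#' `config` is persistent at `t_eval` days after fitting under the
#' refill-gap persistence definition (persistent at T iff
#' T < t_last + D_dose + G_acc). For `t_eval < dose_days + gap_days` the
#' value is exactly 1 (even a patient holding only the fitting-day order is
#' persistent), returned in closed form.
#'
#' @param config a [cohort_config()] object.
#' @param t_eval evaluation time in days after fitting (>= 0).
#' @param params a [persistence_params()] object.
#' @param n_sim number of Monte-Carlo replicates.
#' @param seed seed for the simulation.
#' @return the probability, with attributes `se` (Monte-Carlo standard
#'   error) and `n_sim`.
#' @export
true_persistence <- function(config, t_eval,
                             params = persistence_params(),
                             n_sim = 100000L, seed = 1L) {
  stopifnot(t_eval >= 0)
  horizon <- params$dose_days + params$gap_days
  if (t_eval < horizon) {
    out <- 1
    attr(out, "se") <- 0
    attr(out, "n_sim") <- 0L
    return(out)
  }
  set.seed(seed)
  never <- stats::runif(n_sim) < config$discontinuation$never_fraction
  h <- config$discontinuation$hazard_per_year / 365
  if (config$morbidity_coupling != 0) {
    sp <- config$chronic_prevalence$system_prob
    S <- rowSums(matrix(stats::runif(n_sim * 18L) <
                          matrix(sp, n_sim, 18L, byrow = TRUE), n_sim, 18L))
    h <- h * exp(config$morbidity_coupling * S)
  }
  tau <- ifelse(never | h <= 0, Inf, stats::rexp(n_sim, 1) / h)
  # orders at 0 and then log-normal gaps, strictly before tau;
  # t_last = latest order strictly before t_eval
  meanlog <- log(config$inter_battery_gap$median)
  sdlog <- config$inter_battery_gap$log_sd
  t_last <- numeric(n_sim)          # fitting-day order at t = 0
  cur <- numeric(n_sim)
  act <- seq_len(n_sim)
  while (length(act)) {
    gaps <- pmax(1, round(stats::rlnorm(length(act), meanlog, sdlog)))
    nxt <- cur[act] + gaps
    keep <- nxt < tau[act] & nxt < t_eval
    act <- act[keep]
    cur[act] <- nxt[keep]
    t_last[act] <- nxt[keep]
  }
  p <- mean(t_eval < t_last + params$dose_days + params$gap_days)
  out <- p
  attr(out, "se") <- sqrt(p * (1 - p) / n_sim)
  attr(out, "n_sim") <- as.integer(n_sim)
  out
}
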