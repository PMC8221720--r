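# End-to-end pipeline: demographics -> audiometry -> care pathway ->
# persistence -> IOI-HA -> morbidity -> descriptive and stratified
# summaries, with an exclusion log at every stage.

#' Pipeline configuration
#'
#' @param params a [persistence_params()] object.
#' @param ioi_min_days,ioi_max_days IOI-HA return-window bounds (days).
#' @param mm_window_days,mm_min_codes,mm_exclude_prefix multimorbidity
#'   settings (see [multimorbidity_index()]).
#' @param fitting_max_lag maximum hearing-aid-order to first-battery lag
#'   for the fitting-date proxy (days).
#' @param age_bands ascending age-band edges for stratified outputs.
#' @param min_stratum_n strata smaller than this are suppressed in
#'   stratified tables.
#' @param single_order_only restrict persistence analyses to patients with
#'   a single hearing-aid order.
#' @param asym_threshold asymmetry criterion in dB.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(params = persistence_params(),
                            ioi_min_days = 14L, ioi_max_days = 180L,
                            mm_window_days = 365L, mm_min_codes = 2L,
                            mm_exclude_prefix = "389",
                            fitting_max_lag = 180L,
                            age_bands = c(60, 70, 80, 90),
                            min_stratum_n = 200L,
                            single_order_only = FALSE,
                            asym_threshold = 15) {
  if (is.unsorted(age_bands, strictly = TRUE))
    stop_field("age_bands", "edges must be strictly increasing")
  out <- list(params = params, ioi_min_days = ioi_min_days,
              ioi_max_days = ioi_max_days, mm_window_days = mm_window_days,
              mm_min_codes = mm_min_codes,
              mm_exclude_prefix = mm_exclude_prefix,
              fitting_max_lag = fitting_max_lag, age_bands = age_bands,
              min_stratum_n = min_stratum_n,
              single_order_only = single_order_only,
              asym_threshold = asym_threshold)
  class(out) <- "pipeline_config"
  out
}

.age_band_label <- function(age, edges) {
  labs <- c(paste0("<", edges[1L]),
            paste0(edges[-length(edges)], "-", edges[-1L] - 1L),
            paste0(edges[length(edges)], "+"))
  labs[findInterval(age, edges) + 1L]
}

.require_cols <- function(df, cols, table) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("table '%s' is missing column(s): %s", table,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Run the full cohort pipeline
#'
#' Stages: (1) merge multi-station demographics and flag implausible
#' records; (2) clean audiometry and compute per-patient 4F-PTAs; (3)
#' assign the battery-order fitting-date proxy; (4) compute cohort
#' persistence at the configured evaluation time with death exclusion;
#' (5) assign, filter and score IOI-HA surveys; (6) compute the
#' multimorbidity index, condition flags and inpatient flag; (7) build the
#' patient-level analysis table and descriptive summaries.
#'
#' @param cohort a `raw_cohort` object ([generate_cohort()] /
#'   [read_cohort()]) or a named list of raw tables.
#' @param config a [pipeline_config()] object.
#' @param cci a [load_cci_map()] map.
#' @param conditions condition definitions ([condition_definitions()]).
#' @return object of class `cohort_report`: list with `patients` (one row
#'   per patient analysis table), `persistence`
#'   (a `persistence_estimate`), `pta`, `ioi`, `fitting`, `summary`
#'   (descriptives from [summarize_cohort()]), `stage_log` (per-stage
#'   included/excluded counts with reasons) and `cleaning_log`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         cci = load_cci_map(),
                         conditions = condition_definitions()) {
  tables <- if (inherits(cohort, "raw_cohort")) cohort$tables else cohort
  need <- names(empty_cohort_tables())
  miss <- setdiff(need, names(tables))
  if (length(miss))
    stop("missing table(s): ", paste(miss, collapse = ", "), call. = FALSE)
  .require_cols(tables$demographics,
                c("patient_id", "birth_day", "death_day", "gender"),
                "demographics")
  .require_cols(tables$battery_orders, c("patient_id", "order_day"),
                "battery_orders")
  .require_cols(tables$ha_orders, c("patient_id", "order_day"), "ha_orders")
  stage_log <- list()
  note <- function(stage, n_in, n_out, reason) {
    stage_log[[length(stage_log) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out,
      n_excluded = n_in - n_out, reason = reason, stringsAsFactors = FALSE)
  }

  # stage 1: demographics
  demo <- merge_demographics(tables$demographics)
  note("demographics_merge", length(unique(tables$demographics$patient_id)),
       nrow(demo), "none (merge only)")
  first_order <- tapply(tables$ha_orders$order_day,
                        tables$ha_orders$patient_id, min)
  fo <- as.integer(first_order[demo$patient_id])
  demo <- flag_implausible(demo, fo)
  demo$first_order_day <- fo
  note("implausible_flag", nrow(demo), sum(!demo$implausible),
       "death precedes birth or first order")

  # stage 2: audiometry
  auds <- summarize_audiometry(tables$audiometry,
                               asym_threshold = config$asym_threshold)
  n_aud_pat <- length(unique(tables$audiometry$patient_id))
  note("audiometry", n_aud_pat, nrow(auds$pta), "no valid audiogram")

  # stage 3: fitting-date proxy
  fitting <- assign_fitting_dates(tables$ha_orders, tables$battery_orders,
                                  config$fitting_max_lag)
  note("fitting_assignment", nrow(fitting),
       sum(!is.na(fitting$fitting_day)),
       sprintf("no battery order within %d days", config$fitting_max_lag))

  # optional restriction to single-order patients for persistence
  n_orders <- table(tables$ha_orders$patient_id)
  fitting$n_ha_orders <- as.integer(n_orders[fitting$patient_id])
  fit_for_persist <- if (config$single_order_only)
    fitting[fitting$n_ha_orders == 1L, , drop = FALSE] else fitting

  # stage 4: persistence
  persist <- if (sum(!is.na(fit_for_persist$fitting_day)) == 0L) {
    structure(list(proportion = NA_real_, n_included = 0L,
                   n_excluded_death = 0L, n_excluded_implausible = 0L,
                   params = config$params, se = NA_real_,
                   flags = data.frame(patient_id = character(0),
                                      persistent = logical(0),
                                      stringsAsFactors = FALSE)),
              class = "persistence_estimate")
  } else {
    cohort_persistence(fit_for_persist, tables$battery_orders, demo,
                       config$params)
  }
  note("persistence", sum(!is.na(fit_for_persist$fitting_day)),
       persist$n_included, "died within window or implausible")

  # stage 5: IOI-HA
  ioi <- process_ioi(tables$ioi, tables$ha_orders, fitting,
                     config$ioi_min_days, config$ioi_max_days)
  note("ioi", nrow(ioi), sum(ioi$included),
       "no preceding order / duplicate / no fitting / outside window")

  # stage 6: morbidity
  mm <- multimorbidity_table(tables$diagnoses_outpatient,
                             data.frame(patient_id = demo$patient_id,
                                        index_day = demo$first_order_day,
                                        stringsAsFactors = FALSE),
                             cci, config$mm_window_days,
                             config$mm_min_codes, config$mm_exclude_prefix)
  cond_flags <- data.frame(patient_id = demo$patient_id,
                           stringsAsFactors = FALSE)
  dx <- tables$diagnoses_outpatient
  dx$before <- demo$first_order_day[match(dx$patient_id, demo$patient_id)]
  dx_pre <- dx[!is.na(dx$before) & dx$day < dx$before, , drop = FALSE]
  for (cd in conditions) {
    hit <- unique(dx_pre$patient_id[.matches_condition(dx_pre$icd_code, cd)])
    cond_flags[[cd$name]] <- cond_flags$patient_id %in% hit
  }
  inp <- tables$inpatient
  inp$before <- demo$first_order_day[match(inp$patient_id, demo$patient_id)]
  inp_pat <- unique(inp$patient_id[!is.na(inp$before) &
                                     inp$admit_day < inp$before])
  cond_flags$inpatient_stay <- cond_flags$patient_id %in% inp_pat

  # stage 7: patient-level analysis table
  patients <- demo
  patients$age_at_order <- (patients$first_order_day -
                              patients$birth_day) / 365.25
  patients$age_band <- .age_band_label(patients$age_at_order,
                                       config$age_bands)
  ut <- tables$ha_orders[!duplicated(tables$ha_orders$patient_id), ,
                         drop = FALSE]
  patients$user_type <- ut$user_type[match(patients$patient_id,
                                           ut$patient_id)]
  patients <- merge(patients, fitting[, c("patient_id", "fitting_day",
                                          "lag", "n_ha_orders")],
                    by = "patient_id", all.x = TRUE)
  patients <- merge(patients, auds$pta, by = "patient_id", all.x = TRUE)
  patients <- merge(patients, mm, by = "patient_id", all.x = TRUE)
  patients <- merge(patients, cond_flags, by = "patient_id", all.x = TRUE)
  pf <- persist$flags
  patients$persistent <- pf$persistent[match(patients$patient_id,
                                             pf$patient_id)]
  ioi_inc <- ioi[ioi$included, , drop = FALSE]
  ioi_first <- ioi_inc[!duplicated(ioi_inc$patient_id), , drop = FALSE]
  patients$ioi_total <- ioi_first$total[match(patients$patient_id,
                                              ioi_first$patient_id)]
  patients$ioi_item8 <- ioi_first$item8[match(patients$patient_id,
                                              ioi_first$patient_id)]
  patients <- patients[order(patients$patient_id), , drop = FALSE]
  rownames(patients) <- NULL

  stage_log <- do.call(rbind, stage_log)
  out <- list(patients = patients, persistence = persist, pta = auds$pta,
              ioi = ioi, fitting = fitting,
              summary = summarize_cohort(list(patients = patients,
                                              ha_orders = tables$ha_orders,
                                              battery_orders =
                                                tables$battery_orders,
                                              fitting = fitting,
                                              ioi = ioi)),
              stage_log = stage_log, cleaning_log = auds$cleaning_log,
              config = config)
  class(out) <- "cohort_report"
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report:", nrow(x$patients), "patients\n")
  print(x$persistence)
  s <- x$summary
  cat(sprintf("  male fraction: %.3f; mean age %.1f y\n",
              s$male_fraction, s$age$mean))
  if (!is.null(s$pta$mean_left))
    cat(sprintf("  mean 4F-PTA L/R: %.1f/%.1f dB HL; asymmetric: %.1f%%\n",
                s$pta$mean_left, s$pta$mean_right,
                100 * s$pta$asymmetric_fraction))
  if (!is.null(s$ioi$mean_total))
    cat(sprintf("  IOI-HA total: mean %.1f (n = %d)\n", s$ioi$mean_total,
                s$ioi$n))
  cat(sprintf("  mean multimorbidity index: %.2f\n", s$mm_index$mean))
  invisible(x)
}

#' Descriptive summaries of a processed cohort
#'
#' Counts, means, SDs and medians for the descriptive tables of a
#' hearing-aid outcome study: age by user type, gender fraction,
#' hearing-aid order count distribution, laterality and style fractions,
#' battery-order counts and gaps, order-to-first-battery lag, PTA
#' distributions and asymmetry fraction, IOI-HA total distribution, and the
#' multimorbidity index.
#'
#' @param tables list with `patients` (patient-level analysis table; see
#'   [run_pipeline()]), `ha_orders`, `battery_orders`, `fitting`, `ioi`.
#' @return a nested list of summary statistics.
#' @export
summarize_cohort <- function(tables) {
  p <- tables$patients
  num <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(list(n = 0L, mean = NA_real_, sd = NA_real_,
                                median = NA_real_))
    list(n = length(x), mean = mean(x), sd = stats::sd(x),
         median = stats::median(x))
  }
  ha <- tables$ha_orders
  n_orders <- table(table(ha$patient_id))
  bo <- tables$battery_orders
  n_bat <- as.integer(table(factor(bo$patient_id,
                                   levels = unique(p$patient_id))))
  gaps <- {
    b <- bo[order(bo$patient_id, bo$order_day), , drop = FALSE]
    same <- b$patient_id[-1L] == b$patient_id[-nrow(b)]
    if (nrow(b) > 1L) diff(b$order_day)[same] else numeric(0)
  }
  ioi_inc <- tables$ioi[tables$ioi$included %in% TRUE, , drop = FALSE]
  first_ha <- ha[!duplicated(ha$patient_id), , drop = FALSE]
  list(
    n_patients = nrow(p),
    male_fraction = mean(p$gender == "M", na.rm = TRUE),
    age = num(p$age_at_order),
    age_by_user_type = lapply(split(p$age_at_order, p$user_type), num),
    ha_order_count = as.list(n_orders),
    laterality = as.list(prop.table(table(first_ha$laterality))),
    style = as.list(prop.table(table(first_ha$style))),
    battery_orders = num(n_bat),
    order_to_first_battery = num(tables$fitting$lag),
    inter_order_gap = num(gaps),
    pta = if (all(is.na(p$pta_bilateral))) list() else list(
      mean_left = mean(p$pta_left, na.rm = TRUE),
      mean_right = mean(p$pta_right, na.rm = TRUE),
      sd_left = stats::sd(p$pta_left, na.rm = TRUE),
      sd_right = stats::sd(p$pta_right, na.rm = TRUE),
      asymmetric_fraction = mean(p$asymmetric, na.rm = TRUE),
      left_worse_fraction_given_asym =
        mean(p$worse_ear[p$asymmetric %in% TRUE] == "left")),
    ioi = if (nrow(ioi_inc) == 0L) list(n = 0L) else list(
      n = nrow(ioi_inc), mean_total = mean(ioi_inc$total),
      sd_total = stats::sd(ioi_inc$total),
      frac_ge_28 = mean(ioi_inc$total >= 28),
      frac_le_21 = mean(ioi_inc$total <= 21)),
    mm_index = num(p$mm_index),
    ioi_response_fraction =
      mean(p$patient_id %in% ioi_inc$patient_id))
}

#' Stratified persistence table
#'
#' Cohort persistence computed within each cross-stratum of the given
#' patient-level variables; strata with fewer included patients than
#' `min_stratum_n` are suppressed (proportion set NA, `suppressed` = TRUE).
#'
#' @param report a `cohort_report` from [run_pipeline()], or a list with
#'   `patients` carrying `persistent` flags.
#' @param strata character vector of column names of the patient table
#'   (e.g. `"age_band"`, `"user_type"`, `"diabetes"`, `"mm_index"`).
#' @param min_stratum_n suppression floor (default 200).
#' @return data.frame of class `stratified_persistence`: one row per
#'   stratum with `n`, `proportion`, `suppressed`.
#' @export
stratified_persistence <- function(report, strata, min_stratum_n = 200L) {
  p <- if (inherits(report, "cohort_report")) report$patients else
    report$patients
  miss <- setdiff(strata, names(p))
  if (length(miss))
    stop("unknown stratifier(s): ", paste(miss, collapse = ", "))
  inc <- p[!is.na(p$persistent), , drop = FALSE]
  key <- interaction(inc[, strata, drop = FALSE], drop = TRUE, sep = "|")
  n <- tapply(inc$persistent, key, length)
  prop <- tapply(inc$persistent, key, mean)
  labs <- do.call(rbind, strsplit(names(n), "|", fixed = TRUE))
  out <- as.data.frame(labs, stringsAsFactors = FALSE)
  names(out) <- strata
  out$n <- as.integer(n)
  out$proportion <- as.numeric(prop)
  out$suppressed <- out$n < min_stratum_n
  out$proportion[out$suppressed] <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("stratified_persistence", "data.frame")
  out
}

#' Write a cohort report bundle to disk
#'
#' Emits `summary.json`, `patients.csv`, `stage_log.csv`, `ioi.csv` and
#' `fitting.csv` into a directory.
#'
#' @param report a `cohort_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(summary = report$summary,
         persistence = summary(report$persistence)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null", dataframe = "rows")
  utils::write.csv(report$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(report$stage_log, file.path(dir, "stage_log.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(report$ioi, file.path(dir, "ioi.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(report$fitting, file.path(dir, "fitting.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}
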