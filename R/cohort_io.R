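# Reading and writing raw cohorts as delimited text (RFC-4180 CSV with
# ISO-8601 dates). Day columns are integer days from the cohort epoch in
# memory and calendar dates on disk.

.DAY_COLS <- c("record_day", "birth_day", "death_day", "day", "admit_day",
               "discharge_day", "exam_day", "order_day", "completion_day",
               "entry_day")

.CHAR_COLS <- c("patient_id", "station_id", "gender", "ear", "entry",
                "icd_code", "proc_code", "diagnoses", "user_type", "style",
                "laterality")

.day_to_date_cols <- function(df, epoch) {
  for (cl in intersect(names(df), .DAY_COLS)) {
    new <- if (cl == "day") "date" else sub("_day$", "_date", cl)
    df[[new]] <- day_to_date(df[[cl]], epoch)
    df[[cl]] <- NULL
  }
  df
}

.date_to_day_cols <- function(df, epoch) {
  for (cl in grep("date$", names(df), value = TRUE)) {
    new <- if (cl == "date") "day" else sub("_date$", "_day", cl)
    df[[new]] <- date_to_day(df[[cl]], epoch)
    df[[cl]] <- NULL
  }
  df
}

#' Write a raw cohort to a directory of CSV files
#'
#' One RFC-4180 CSV per table (ISO-8601 dates), a `ground_truth.csv`
#' sidecar, an `anomaly_log.csv`, and a `manifest.json` holding the full
#' generator configuration and seed.
#'
#' @param cohort a `raw_cohort` object from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param epoch origin date for day-to-date conversion.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, epoch = COHORT_EPOCH) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$tables)) {
    utils::write.csv(.day_to_date_cols(cohort$tables[[nm]], epoch),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE,
                     na = "")
  }
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$anomaly_log, file.path(dir, "anomaly_log.csv"),
                   row.names = FALSE, na = "")
  manifest <- list(package = "audcohort",
                   epoch = format(epoch),
                   seed = cohort$config$seed,
                   config = unclass(cohort$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a raw cohort from a directory of CSV files
#'
#' @param dir directory written by [write_cohort()] (ground truth and
#'   manifest are optional for foreign data).
#' @param epoch origin date for date-to-day conversion.
#' @return a `raw_cohort` object (with `ground_truth`/`config` set to NULL
#'   when the sidecars are absent).
#' @export
read_cohort <- function(dir, epoch = COHORT_EPOCH) {
  tables <- empty_cohort_tables()
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) {
      hdr <- names(utils::read.csv(f, nrows = 1L))
      cc <- stats::setNames(rep(NA_character_, length(hdr)), hdr)
      cc[hdr %in% .CHAR_COLS] <- "character"
      df <- utils::read.csv(f, na.strings = "", colClasses = cc)
      tables[[nm]] <- .date_to_day_cols(df, epoch)
    }
  }
  gt_file <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_file))
    utils::read.csv(gt_file, colClasses = c(patient_id = "character"),
                    na.strings = "") else NULL
  log_file <- file.path(dir, "anomaly_log.csv")
  log <- if (file.exists(log_file))
    utils::read.csv(log_file, colClasses = "character", na.strings = "")
  else empty_anomaly_log()
  man_file <- file.path(dir, "manifest.json")
  config <- if (file.exists(man_file))
    jsonlite::fromJSON(man_file)$config else NULL
  out <- list(tables = tables, ground_truth = gt, anomaly_log = log,
              config = config)
  class(out) <- "raw_cohort"
  out
}
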