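# Hearing-care event detection, fitting-date proxy, and user-type
# classification.
#
# Hearing-care events are detected from configurable code lists (procedural
# and ICD diagnosis codes); all records of a patient on one date are one
# appointment. Because the record system has no single fitting code, the
# fitting date is proxied by the first battery order on or after the
# hearing-aid order, provided it occurs within `max_lag` (default 180) days.

#' Load a hearing-care code list
#'
#' @param path CSV file with columns `code`, `code_system` (one of
#'   `CPT/HCPCS`, `ICD9`, `ICD10`) and `fitting_flag` (0/1). The package
#'   ships a small synthetic list in
#'   `system.file("extdata", "hearing_codes_synthetic.csv", package =
#'   "audcohort")`; real analyses substitute the full curated list.
#' @return data.frame of class `code_list`.
#' @export
load_code_list <- function(path = system.file("extdata",
                                              "hearing_codes_synthetic.csv",
                                              package = "audcohort")) {
  cl <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("code", "code_system", "fitting_flag") %in% names(cl)))
  cl$fitting_flag <- as.integer(cl$fitting_flag)
  class(cl) <- c("code_list", "data.frame")
  cl
}

#' Detect hearing-care events from diagnosis and procedure records
#'
#' A hearing-care event is assumed on any date on which at least one code
#' from the code list is present; all matching records of a patient on one
#' date form a single event carrying the union of its codes.
#'
#' @param diagnoses data.frame with `patient_id`, `icd_code`, `day`.
#' @param procedures data.frame with `patient_id`, `proc_code`, `day`.
#' @param codes a [load_code_list()] data.frame.
#' @return data.frame with one row per (patient, day): `patient_id`, `day`,
#'   `n_codes`, `codes` (codes sorted, `;`-separated).
#' @export
detect_care_events <- function(diagnoses, procedures, codes) {
  recs <- rbind(
    data.frame(patient_id = diagnoses$patient_id, code = diagnoses$icd_code,
               day = diagnoses$day, stringsAsFactors = FALSE),
    data.frame(patient_id = procedures$patient_id,
               code = procedures$proc_code, day = procedures$day,
               stringsAsFactors = FALSE))
  recs <- recs[recs$code %in% codes$code, , drop = FALSE]
  if (nrow(recs) == 0L)
    return(data.frame(patient_id = character(0), day = integer(0),
                      n_codes = integer(0), codes = character(0),
                      stringsAsFactors = FALSE))
  recs <- unique(recs)
  key <- paste(recs$patient_id, recs$day, sep = "|")
  agg <- tapply(recs$code, key, function(cc) {
    cc <- sort(unique(cc))
    c(length(cc), paste(cc, collapse = ";"))
  })
  parts <- do.call(rbind, strsplit(names(agg), "|", fixed = TRUE))
  out <- data.frame(patient_id = parts[, 1L],
                    day = as.integer(parts[, 2L]),
                    n_codes = as.integer(vapply(agg, `[`, "", 1L)),
                    codes = vapply(agg, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign the battery-order fitting-date proxy for one order
#'
#' The fitting date is the first battery order on or after the hearing-aid
#' order, provided its lag does not exceed `max_lag` days; otherwise no
#' fitting date is assigned. Battery orders strictly before the hearing-aid
#' order are ignored (they belong to a prior device).
#'
#' @param ha_order_day day of the hearing-aid order.
#' @param battery_days sorted ascending battery-order days for the patient.
#' @param max_lag maximum allowed lag in days (default 180).
#' @return one-row data.frame: `ha_order_day`, `fitting_day` (NA if
#'   unassigned), `lag`.
#' @export
assign_fitting_date <- function(ha_order_day, battery_days, max_lag = 180L) {
  cand <- battery_days[battery_days >= ha_order_day]
  if (length(cand) && (cand[1L] - ha_order_day) <= max_lag) {
    data.frame(ha_order_day = ha_order_day, fitting_day = cand[1L],
               lag = as.integer(cand[1L] - ha_order_day))
  } else {
    data.frame(ha_order_day = ha_order_day, fitting_day = NA_integer_,
               lag = NA_integer_)
  }
}

#' Assign fitting dates for a whole cohort
#'
#' Vectorised application of [assign_fitting_date()] to each patient's
#' first hearing-aid order.
#'
#' @param ha_orders data.frame with `patient_id`, `order_day` (the first
#'   order per patient is used).
#' @param battery_orders data.frame with `patient_id`, `order_day`.
#' @param max_lag maximum allowed order-to-battery lag in days.
#' @return data.frame: `patient_id`, `ha_order_day`, `fitting_day`, `lag`.
#' @export
assign_fitting_dates <- function(ha_orders, battery_orders, max_lag = 180L) {
  if (nrow(ha_orders) == 0L)
    return(data.frame(patient_id = character(0), ha_order_day = integer(0),
                      fitting_day = integer(0), lag = integer(0),
                      stringsAsFactors = FALSE))
  first_order <- tapply(ha_orders$order_day, ha_orders$patient_id, min)
  pid <- names(first_order)
  fo <- as.integer(first_order)
  bo <- battery_orders[order(battery_orders$patient_id,
                             battery_orders$order_day), , drop = FALSE]
  bo$ha_day <- fo[match(bo$patient_id, pid)]
  bo <- bo[!is.na(bo$ha_day) & bo$order_day >= bo$ha_day, , drop = FALSE]
  first_bat <- tapply(bo$order_day, bo$patient_id, min)
  fb <- as.integer(first_bat[pid])
  lag <- fb - fo
  ok <- !is.na(lag) & lag <= max_lag
  data.frame(patient_id = pid, ha_order_day = fo,
             fitting_day = ifelse(ok, fb, NA_integer_),
             lag = ifelse(ok, lag, NA_integer_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a hearing-aid order as new or experienced
#'
#' A patient is an experienced user at an index order iff any hearing-aid
#' order strictly precedes it; two orders on the same day do not make each
#' other "prior".
#'
#' @param ha_order_days the patient's hearing-aid order days.
#' @param index_order_day the order being classified (must be among
#'   `ha_order_days`).
#' @return `"new"` or `"experienced"`.
#' @export
classify_user_type <- function(ha_order_days, index_order_day) {
  if (!index_order_day %in% ha_order_days)
    stop("index order day not found among the patient's orders")
  if (any(ha_order_days < index_order_day)) "experienced" else "new"
}
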