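# IOI-HA survey processing: assignment of surveys to hearing-aid orders,
# the 14-180 day return-window filter, and scoring.
#
# The record system does not link a survey to a specific order, so each
# survey is assumed to reflect the most recent preceding hearing-aid order.
# If two surveys of one patient resolve to the same order, both are
# excluded. The total score is the sum of items 1-7 (range 7-35); item 8
# (self-rated unaided hearing difficulty) is carried separately as an
# ordinal covariate and is never totalled.

IOI_ITEMS <- paste0("item", 1:7)

#' Total IOI-HA score
#'
#' Sum of items 1 to 7, each an integer in 1..5; range 7 to 35. A total of
#' 28 or more means an average rating of at least four on every item; 21 or
#' less means an average of three or less.
#'
#' @param survey a data.frame (one or more rows) with columns
#'   `item1`..`item7`, or a numeric vector of the seven item scores.
#' @return integer vector of total scores.
#' @export
ioi_total_score <- function(survey) {
  if (is.numeric(survey)) {
    stopifnot(length(survey) == 7L)
    items <- matrix(survey, 1L)
  } else {
    items <- as.matrix(survey[, IOI_ITEMS, drop = FALSE])
  }
  if (anyNA(items) || any(items < 1) || any(items > 5) ||
      any(items != round(items)))
    stop("IOI-HA items must all be integers in 1..5")
  as.integer(rowSums(items))
}

#' Assign IOI-HA surveys to hearing-aid orders
#'
#' Each survey maps to the patient's latest hearing-aid order on or before
#' its completion date. Surveys predating all orders are excluded
#' (`no_preceding_order`); if two surveys of one patient map to the same
#' order, both are excluded (`duplicate_same_order`).
#'
#' @param surveys data.frame with `patient_id`, `completion_day` (and any
#'   further survey columns, carried through).
#' @param ha_orders data.frame with `patient_id`, `order_day`.
#' @return `surveys` with columns `assigned_order_day` (NA when excluded),
#'   `assigned` (logical) and `exclusion_reason` (NA when assigned) added.
#' @export
assign_surveys <- function(surveys, ha_orders) {
  if (nrow(surveys) == 0L) {
    surveys$assigned_order_day <- integer(0)
    surveys$assigned <- logical(0)
    surveys$exclusion_reason <- character(0)
    return(surveys)
  }
  sidx <- data.frame(.sidx = seq_len(nrow(surveys)),
                     patient_id = surveys$patient_id,
                     .comp = surveys$completion_day,
                     stringsAsFactors = FALSE)
  m <- merge(sidx, ha_orders[, c("patient_id", "order_day")],
             by = "patient_id")
  m <- m[m$order_day <= m$.comp, , drop = FALSE]
  assigned <- rep(NA_real_, nrow(surveys))
  if (nrow(m)) {
    best <- tapply(m$order_day, m$.sidx, max)
    assigned[as.integer(names(best))] <- as.numeric(best)
  }
  surveys$assigned_order_day <- as.integer(assigned)
  surveys$exclusion_reason <- ifelse(is.na(assigned), "no_preceding_order",
                                     NA_character_)
  # duplicate detection: two surveys of one patient on the same order
  key <- paste(surveys$patient_id, surveys$assigned_order_day, sep = "|")
  dup <- !is.na(assigned) & key %in% key[duplicated(key) & !is.na(assigned)]
  surveys$assigned_order_day[dup] <- NA_integer_
  surveys$exclusion_reason[dup] <- "duplicate_same_order"
  surveys$assigned <- is.na(surveys$exclusion_reason)
  surveys
}

#' Apply the IOI-HA return-window filter and score surveys
#'
#' A survey is included iff its completion date falls between `min_days`
#' and `max_days` (inclusive at both ends) after the fitting date of its
#' assigned order. Surveys whose assigned order has no fitting date are
#' excluded (`no_fitting_date`). The completion (patient-reported) date
#' governs the window; the system entry date is used as a fallback when the
#' completion date is missing.
#'
#' @param assignments output of [assign_surveys()] (items 1-8 present).
#' @param fitting data.frame from [assign_fitting_dates()] (`patient_id`,
#'   `ha_order_day`, `fitting_day`).
#' @param min_days,max_days inclusive return-window bounds (14 and 180).
#' @return data.frame of IOI results: `patient_id`, `assigned_order_day`,
#'   `return_lag`, `total`, `item8`, `included`, `exclusion_reason`.
#' @export
filter_return_window <- function(assignments, fitting, min_days = 14L,
                                 max_days = 180L) {
  a <- assignments
  comp <- a$completion_day
  if (!is.null(a$entry_day)) comp[is.na(comp)] <- a$entry_day[is.na(comp)]
  fkey <- paste(fitting$patient_id, fitting$ha_order_day, sep = "|")
  akey <- paste(a$patient_id, a$assigned_order_day, sep = "|")
  fit_day <- fitting$fitting_day[match(akey, fkey)]
  lag <- comp - fit_day
  reason <- a$exclusion_reason
  unassigned <- !a$assigned
  no_fit <- !unassigned & is.na(fit_day)
  reason[no_fit] <- "no_fitting_date"
  out_window <- !unassigned & !no_fit & (lag < min_days | lag > max_days)
  reason[out_window] <- "outside_return_window"
  included <- is.na(reason)
  total <- rep(NA_integer_, nrow(a))
  if (any(!is.na(a$item1)))
    total <- ioi_total_score(a)
  data.frame(patient_id = a$patient_id,
             assigned_order_day = a$assigned_order_day,
             return_lag = as.integer(lag),
             total = total, item8 = a$item8,
             included = included, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

#' Process an IOI-HA table end to end
#'
#' Assigns surveys to orders, applies the return-window filter, and scores.
#'
#' @param ioi raw IOI-HA table (`patient_id`, `completion_day`,
#'   `entry_day`, `item1`..`item8`).
#' @param ha_orders hearing-aid order table.
#' @param fitting fitting table from [assign_fitting_dates()].
#' @param min_days,max_days return-window bounds.
#' @return see [filter_return_window()].
#' @export
process_ioi <- function(ioi, ha_orders, fitting, min_days = 14L,
                        max_days = 180L) {
  if (nrow(ioi) == 0L)
    return(data.frame(patient_id = character(0),
                      assigned_order_day = integer(0),
                      return_lag = integer(0), total = integer(0),
                      item8 = integer(0), included = logical(0),
                      exclusion_reason = character(0),
                      stringsAsFactors = FALSE))
  a <- assign_surveys(ioi, ha_orders)
  filter_return_window(a, fitting, min_days, max_days)
}
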