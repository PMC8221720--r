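# Demographic record merging and survival-based exclusion rules.
#
# Patients seen at several stations carry one demographic record per
# station. Records are merged to one row per patient by taking the modal
# value of each field; disagreement in any field sets an `inconsistent`
# flag. Records with a death date preceding the birth date or the first
# hearing-aid order are flagged implausible and excluded downstream from
# analyses requiring age or survival information.

DEMO_MERGE_FIELDS <- c("birth_day", "death_day", "gender")

# modal value with ties broken in favour of the value seen earliest
# (by record_day order of the source rows)
.modal_value <- function(values, record_order) {
  v <- values[record_order]
  tab <- table(factor(v, levels = unique(v)), useNA = "ifany")
  names(tab)[which.max(tab)]
}

#' Merge per-station demographic records for one patient
#'
#' Each merged field takes the most frequent value across the patient's
#' records; when any field disagrees across records the `inconsistent` flag
#' is set. Modal ties are broken in favour of the value carried by the
#' earliest-dated source record (`record_day`), falling back to input order
#' when record dates are absent.
#'
#' @param records data.frame of per-station rows for a single patient, with
#'   columns `patient_id`, `birth_day`, `death_day`, `gender` and optionally
#'   `record_day`, `station_id`.
#' @return a one-row data.frame of class `patient_demographics` with columns
#'   `patient_id`, `birth_day`, `death_day`, `gender`, `n_source_records`,
#'   `inconsistent`.
#' @export
merge_demographic_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  if (length(unique(records$patient_id)) != 1L)
    stop("records mix more than one patient id")
  ord <- if (!is.null(records$record_day))
    order(records$record_day) else seq_len(nrow(records))
  inconsistent <- FALSE
  out <- records[1L, c("patient_id", DEMO_MERGE_FIELDS), drop = FALSE]
  for (f in DEMO_MERGE_FIELDS) {
    vals <- records[[f]]
    key <- ifelse(is.na(vals), "<NA>", as.character(vals))
    if (length(unique(key)) > 1L) {
      inconsistent <- TRUE
      win <- .modal_value(key, ord)
      out[[f]] <- if (identical(win, "<NA>")) {
        vals[NA_integer_]
      } else {
        vals[match(win, key)]
      }
    }
  }
  out$n_source_records <- nrow(records)
  out$inconsistent <- inconsistent
  rownames(out) <- NULL
  class(out) <- c("patient_demographics", "data.frame")
  out
}

#' Merge a multi-station demographics table to one row per patient
#'
#' Vectorised wrapper around the modal-merge rule of
#' [merge_demographic_records()]: patients whose records agree on every
#' field are taken verbatim; the (rare) disagreeing patients are merged
#' record-set by record-set.
#'
#' @param demographics data.frame with columns `patient_id`, `birth_day`,
#'   `death_day`, `gender` and optionally `record_day`, `station_id`.
#' @return data.frame with one row per patient and columns `patient_id`,
#'   `birth_day`, `death_day`, `gender`, `n_source_records`, `inconsistent`.
#' @export
merge_demographics <- function(demographics) {
  if (nrow(demographics) == 0L)
    return(data.frame(patient_id = character(0), birth_day = integer(0),
                      death_day = integer(0), gender = character(0),
                      n_source_records = integer(0), inconsistent = logical(0),
                      stringsAsFactors = FALSE))
  key <- paste(ifelse(is.na(demographics$birth_day), "<NA>",
                      demographics$birth_day),
               ifelse(is.na(demographics$death_day), "<NA>",
                      demographics$death_day),
               demographics$gender)
  n_rec <- table(demographics$patient_id)
  n_key <- tapply(key, demographics$patient_id,
                  function(k) length(unique(k)))
  consistent_ids <- names(n_key)[n_key == 1L]
  first <- demographics[!duplicated(demographics$patient_id), , drop = FALSE]
  cons <- first[first$patient_id %in% consistent_ids,
                c("patient_id", DEMO_MERGE_FIELDS), drop = FALSE]
  cons$n_source_records <- as.integer(n_rec[cons$patient_id])
  cons$inconsistent <- FALSE
  bad_ids <- names(n_key)[n_key > 1L]
  if (length(bad_ids)) {
    merged <- lapply(bad_ids, function(p) {
      rec <- demographics[demographics$patient_id == p, , drop = FALSE]
      m <- merge_demographic_records(rec)
      class(m) <- "data.frame"
      m
    })
    out <- rbind(cons, do.call(rbind, merged))
  } else {
    out <- cons
  }
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag implausible demographic records
#'
#' A record is implausible when the date of death strictly precedes the
#' date of birth or the first hearing-aid order. A death on the same day as
#' the first order is allowed (the rule is strict precedence). Implausible
#' patients are excluded downstream from analyses requiring age or survival
#' information.
#'
#' @param demographics data.frame with columns `birth_day`, `death_day`
#'   (one row per patient, as from [merge_demographics()]).
#' @param first_order_day integer vector (recycled if length 1): day of the
#'   patient's first hearing-aid order.
#' @return `demographics` with a logical `implausible` column added.
#' @export
flag_implausible <- function(demographics, first_order_day) {
  d <- demographics$death_day
  demographics$implausible <- !is.na(d) &
    (d < demographics$birth_day | d < first_order_day)
  demographics
}

#' Did the patient survive an evaluation window after fitting?
#'
#' TRUE when the patient has no recorded death or died on or after
#' `fitting_day + t_eval`; "died within the window" is the half-open
#' interval `[fitting_day, fitting_day + t_eval)`.
#'
#' @param demographics data.frame with a `death_day` column (NA = alive).
#' @param fitting_day integer vector of fitting days.
#' @param t_eval window length in days.
#' @return logical vector.
#' @export
survives_through <- function(demographics, fitting_day, t_eval) {
  d <- demographics$death_day
  is.na(d) | d >= fitting_day + t_eval
}
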