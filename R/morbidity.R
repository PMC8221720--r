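# Chronic Condition Indicator (CCI) multimorbidity index and
# condition-presence flags from ICD-9 diagnosis streams.
#
# Each ICD-9 code maps to a chronic flag and one of 18 body systems. The
# multimorbidity index is the number of body systems with at least
# `min_codes` (default 2) chronic-condition codes dated within the 12
# months before the hearing-aid order, after removal of hearing-loss codes
# (ICD-9 group 389.XX) so that the index stays sensitive to other
# conditions of body system 6. The index ranges 0-18.

# normalise an ICD-9 code for matching: trim, upper-case, drop the dot
.norm_icd <- function(code) {
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

#' Load a Chronic Condition Indicator map
#'
#' @param path CSV with columns `icd_code`, `chronic` (0/1), `body_system`
#'   (integer 1-18). The package ships a small synthetic map
#'   (`cci_map_synthetic.csv`) spanning all 18 body systems; real analyses
#'   substitute the full AHRQ table, which is distributed separately.
#' @return data.frame of class `cci_map` with a normalised `norm` column.
#' @export
load_cci_map <- function(path = system.file("extdata",
                                            "cci_map_synthetic.csv",
                                            package = "audcohort")) {
  cci <- utils::read.csv(path, colClasses = c(icd_code = "character"))
  stopifnot(all(c("icd_code", "chronic", "body_system") %in% names(cci)))
  if (any(cci$body_system < 1 | cci$body_system > 18))
    stop("body_system must be in 1..18")
  cci$chronic <- as.integer(cci$chronic)
  cci$body_system <- as.integer(cci$body_system)
  cci$norm <- .norm_icd(cci$icd_code)
  class(cci) <- c("cci_map", "data.frame")
  cci
}

cci_map_synthetic <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- load_cci_map()
    cache
  }
})

# look codes up in a CCI map with prefix semantics: exact normalised match
# first, then 4-digit, then 3-digit category prefix. Unknown codes are
# non-chronic. Returns data.frame(chronic, body_system).
.cci_lookup <- function(codes, cci) {
  norm <- .norm_icd(codes)
  i <- match(norm, cci$norm)
  for (width in c(4L, 3L)) {
    miss <- is.na(i) & nchar(norm) > width
    if (any(miss))
      i[miss] <- match(substr(norm[miss], 1L, width), cci$norm)
  }
  data.frame(chronic = ifelse(is.na(i), 0L, cci$chronic[i]),
             body_system = ifelse(is.na(i), NA_integer_,
                                  cci$body_system[i]))
}

#' Multimorbidity index for one patient
#'
#' Counts chronic-flagged diagnosis codes dated in the half-open window
#' `[index_day - window_days, index_day)` (codes on the index day itself
#' are excluded), drops codes in the excluded prefix group (389.XX hearing
#' loss), and returns the number of body systems with at least `min_codes`
#' such codes.
#'
#' @param diagnoses data.frame with `icd_code`, `day` (one patient).
#' @param index_day the hearing-aid order day.
#' @param cci a [load_cci_map()] map.
#' @param window_days lookback window (default 365 = 12 months).
#' @param min_codes codes required per body system (default 2).
#' @param exclude_prefix normalised ICD-9 prefix to drop (default "389").
#' @return list of class `multimorbidity_result`: `index` (0-18),
#'   `system_counts` (named integer vector over systems 1-18), `window`.
#' @export
multimorbidity_index <- function(diagnoses, index_day, cci,
                                 window_days = 365L, min_codes = 2L,
                                 exclude_prefix = "389") {
  in_win <- diagnoses$day >= index_day - window_days &
    diagnoses$day < index_day
  d <- diagnoses[in_win, , drop = FALSE]
  norm <- .norm_icd(d$icd_code)
  d <- d[!startsWith(norm, exclude_prefix), , drop = FALSE]
  counts <- integer(18L)
  names(counts) <- as.character(1:18)
  if (nrow(d)) {
    lk <- .cci_lookup(d$icd_code, cci)
    ch <- lk$chronic == 1L & !is.na(lk$body_system)
    if (any(ch)) {
      tab <- table(factor(lk$body_system[ch], levels = 1:18))
      counts <- as.integer(tab)
      names(counts) <- as.character(1:18)
    }
  }
  out <- list(index = as.integer(sum(counts >= min_codes)),
              system_counts = counts,
              window = c(start = index_day - window_days, end = index_day))
  class(out) <- "multimorbidity_result"
  out
}

#' @export
print.multimorbidity_result <- function(x, ...) {
  cat("Multimorbidity index:", x$index, "of 18 body systems\n")
  nz <- x$system_counts[x$system_counts > 0L]
  if (length(nz))
    cat("  chronic codes by system:",
        paste(sprintf("%s:%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Multimorbidity index for a whole cohort
#'
#' Vectorised computation of [multimorbidity_index()] per patient.
#'
#' @param diagnoses cohort diagnosis table (`patient_id`, `icd_code`,
#'   `day`).
#' @param index_days named integer vector (names = patient ids) or
#'   data.frame with `patient_id` and `index_day`: the per-patient index
#'   (hearing-aid order) day.
#' @inheritParams multimorbidity_index
#' @return data.frame: `patient_id`, `mm_index`.
#' @export
multimorbidity_table <- function(diagnoses, index_days, cci,
                                 window_days = 365L, min_codes = 2L,
                                 exclude_prefix = "389") {
  if (is.data.frame(index_days)) {
    ids <- index_days$patient_id
    idx <- index_days$index_day
  } else {
    ids <- names(index_days)
    idx <- as.integer(index_days)
  }
  out <- data.frame(patient_id = ids, mm_index = integer(length(ids)),
                    stringsAsFactors = FALSE)
  if (nrow(diagnoses) == 0L || length(ids) == 0L) return(out)
  d <- diagnoses
  d$index_day <- idx[match(d$patient_id, ids)]
  d <- d[!is.na(d$index_day) & d$day >= d$index_day - window_days &
           d$day < d$index_day, , drop = FALSE]
  norm <- .norm_icd(d$icd_code)
  d <- d[!startsWith(norm, exclude_prefix), , drop = FALSE]
  if (nrow(d)) {
    lk <- .cci_lookup(d$icd_code, cci)
    keep <- lk$chronic == 1L & !is.na(lk$body_system)
    d <- d[keep, , drop = FALSE]
    sys <- lk$body_system[keep]
    if (nrow(d)) {
      key <- paste(d$patient_id, sys, sep = "|")
      cnt <- table(key)
      qual <- names(cnt)[cnt >= min_codes]
      qpat <- sub("\\|[0-9]+$", "", qual)
      idx_tab <- table(qpat)
      hit <- match(names(idx_tab), out$patient_id)
      out$mm_index[hit[!is.na(hit)]] <-
        as.integer(idx_tab)[!is.na(hit)]
    }
  }
  out
}

#' Condition definitions for illustrative comorbidities
#'
#' Shipped defaults follow the source conventions of the field verbatim:
#' Parkinson's disease (332.0, 332.1), diabetes (category 250), arthritis
#' (range 360-379) and vision impairment (range 710-739). Note: the latter
#' two ranges are transposed relative to standard ICD-9 chapter assignments
#' (360-379 is the eye chapter, 710-739 the musculoskeletal chapter); they
#' are kept as printed in the defining study and are configurable here.
#'
#' @param path optional JSON file with elements `name`, `prefixes`,
#'   `ranges` (each range `[lo, hi]` over 3-digit categories).
#' @return list of condition definitions.
#' @export
condition_definitions <- function(path = NULL) {
  if (!is.null(path)) {
    defs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    return(lapply(defs, function(d)
      list(name = d$name,
           prefixes = as.character(unlist(d$prefixes)),
           ranges = lapply(d$ranges, function(r) as.integer(unlist(r))))))
  }
  list(
    parkinsons = list(name = "parkinsons",
                      prefixes = c("332.0", "332.1"), ranges = list()),
    diabetes = list(name = "diabetes", prefixes = "250", ranges = list()),
    arthritis = list(name = "arthritis", prefixes = character(0),
                     ranges = list(c(360L, 379L))),
    vision_impairment = list(name = "vision_impairment",
                             prefixes = character(0),
                             ranges = list(c(710L, 739L))))
}

#' Does a patient have a condition before a given date?
#'
#' TRUE iff at least one diagnosis code strictly before `before_day`
#' matches the condition definition (prefix match on the normalised code,
#' or 3-digit category within one of the ranges).
#'
#' @param diagnoses data.frame with `icd_code`, `day` (one patient).
#' @param definition one element of [condition_definitions()].
#' @param before_day the reference (hearing-aid order) day.
#' @return logical flag.
#' @export
has_condition <- function(diagnoses, definition, before_day) {
  if (length(definition$prefixes) == 0L && length(definition$ranges) == 0L)
    stop("condition definition has an empty code set")
  d <- diagnoses[diagnoses$day < before_day, , drop = FALSE]
  if (nrow(d) == 0L) return(FALSE)
  any(.matches_condition(d$icd_code, definition))
}

.matches_condition <- function(codes, definition) {
  norm <- .norm_icd(codes)
  hit <- rep(FALSE, length(norm))
  for (p in definition$prefixes)
    hit <- hit | startsWith(norm, .norm_icd(p))
  for (r in definition$ranges) {
    cat3 <- suppressWarnings(as.integer(substr(norm, 1L, 3L)))
    hit <- hit | (!is.na(cat3) & cat3 >= r[1L] & cat3 <= r[2L])
  }
  hit
}

#' Any inpatient admission before a given date?
#'
#' @param inpatient data.frame with `admit_day` (one patient).
#' @param before_day reference day; admissions on the day itself do not
#'   count (strict precedence).
#' @return logical flag.
#' @export
had_inpatient_stay <- function(inpatient, before_day) {
  nrow(inpatient) > 0L && any(inpatient$admit_day < before_day)
}
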