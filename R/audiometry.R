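# Audiogram cleaning, validity, averaging, and pure-tone averages.
#
# Raw audiometric entries are free text. Cleaning maps each entry to a dB HL
# value or missing with a provenance tag: above-limit audiometer codes are
# replaced by 120 dB (`ceiling_substituted`), ambiguous non-numeric entries
# and numeric values that are not divisible by 5 (audiometry is conducted in
# 5 dB steps) or fall outside -10..120 dB are set missing (`set_missing`),
# everything else passes through (`as_entered`). An audiogram is valid when
# all four PTA frequencies (0.5, 1, 2, 4 kHz) are numeric in both ears.

PTA_FREQS <- c(500L, 1000L, 2000L, 4000L)

#' Token lists for audiometric entry cleaning
#'
#' @param above_limit entries indicating a threshold above the audiometer
#'   limit; replaced by 120 dB.
#' @param ambiguous entries that cannot be interpreted; set missing.
#' @return a named list used by [clean_audiogram()].
#' @export
audiogram_tokens <- function(above_limit = c("NR", "120+", ">120"),
                             ambiguous = c("DNT", "CNT", "--", "")) {
  list(above_limit = above_limit, ambiguous = ambiguous)
}

#' Clean raw audiometric entries
#'
#' @param audiogram data.frame with columns `ear`, `frequency_hz`, `entry`
#'   (character), and optionally `patient_id`, `exam_day`. May hold one
#'   audiogram or a whole audiometry table.
#' @param tokens token lists from [audiogram_tokens()].
#' @return the input with columns `threshold_db` (numeric or NA) and
#'   `provenance` (one of `as_entered`, `ceiling_substituted`,
#'   `set_missing`) added; cleaning never raises an error.
#' @export
clean_audiogram <- function(audiogram, tokens = audiogram_tokens()) {
  entry <- trimws(as.character(audiogram$entry))
  num <- suppressWarnings(as.numeric(entry))
  above <- entry %in% tokens$above_limit
  valid_num <- !is.na(num) & num %% 5 == 0 & num >= -10 & num <= 120
  thr <- ifelse(above, 120, ifelse(valid_num, num, NA_real_))
  prov <- ifelse(above, "ceiling_substituted",
                 ifelse(valid_num, "as_entered", "set_missing"))
  audiogram$threshold_db <- thr
  audiogram$provenance <- prov
  audiogram
}

#' Is a cleaned audiogram valid for analysis?
#'
#' Valid audiograms have numeric thresholds (120 dB substitutions included)
#' at 0.5, 1, 2, and 4 kHz in both ears; other frequencies do not affect
#' validity.
#'
#' @param clean a cleaned audiogram (one exam) from [clean_audiogram()].
#' @return logical flag.
#' @export
is_valid_audiogram <- function(clean) {
  need <- expand.grid(ear = c("L", "R"), frequency_hz = PTA_FREQS,
                      stringsAsFactors = FALSE)
  ok <- !is.na(clean$threshold_db)
  have <- paste(clean$ear[ok], clean$frequency_hz[ok])
  all(paste(need$ear, need$frequency_hz) %in% have)
}

#' Average several cleaned audiograms of one patient
#'
#' Cell-wise arithmetic mean over the audiograms in which that (ear,
#' frequency) cell is numeric; a cell is missing only when it is missing in
#' every audiogram. Averages need not be multiples of 5: divisibility is a
#' property of raw entries, not of derived values.
#'
#' @param cleans a cleaned audiometry data.frame covering one patient
#'   (several `exam_day` values), or a list of cleaned audiograms.
#' @return data.frame with columns `ear`, `frequency_hz`, `threshold_db`,
#'   `n_exams`.
#' @export
average_audiograms <- function(cleans) {
  if (is.data.frame(cleans)) {
    df <- cleans
  } else if (is.list(cleans) && length(cleans)) {
    df <- do.call(rbind, cleans)
  } else {
    stop("need at least one audiogram")
  }
  if (nrow(df) == 0L) stop("need at least one audiogram")
  key <- paste(df$ear, df$frequency_hz)
  ok <- !is.na(df$threshold_db)
  cells <- unique(data.frame(ear = df$ear, frequency_hz = df$frequency_hz,
                             stringsAsFactors = FALSE))
  m <- tapply(df$threshold_db[ok], key[ok], mean)
  n <- tapply(df$threshold_db[ok], key[ok], length)
  ckey <- paste(cells$ear, cells$frequency_hz)
  cells$threshold_db <- as.numeric(m[ckey])
  cells$n_exams <- ifelse(is.na(cells$threshold_db), 0L,
                          as.integer(n[ckey]))
  cells <- cells[order(cells$ear, cells$frequency_hz), , drop = FALSE]
  rownames(cells) <- NULL
  cells
}

#' Four-frequency pure-tone averages and asymmetry classification
#'
#' Per-ear mean threshold at 0.5, 1, 2, and 4 kHz; the bilateral 4F-PTA is
#' the mean of the two ear PTAs. A clinically relevant asymmetry is an
#' absolute left-right difference of at least `asym_threshold` dB (a
#' difference of exactly the threshold qualifies); `worse_ear` is `"none"`
#' below the threshold.
#'
#' @param clean a cleaned (or averaged) audiogram with columns `ear`,
#'   `frequency_hz`, `threshold_db`.
#' @param asym_threshold asymmetry criterion in dB (default 15).
#' @return a one-row data.frame: `pta_left`, `pta_right`, `pta_bilateral`,
#'   `asymmetric`, `worse_ear`.
#' @export
compute_4f_pta <- function(clean, asym_threshold = 15) {
  sel <- clean$frequency_hz %in% PTA_FREQS
  l <- clean$threshold_db[sel & clean$ear == "L"]
  r <- clean$threshold_db[sel & clean$ear == "R"]
  if (length(l) != 4L || length(r) != 4L || anyNA(l) || anyNA(r))
    stop("audiogram is not valid: all four PTA frequencies must be numeric ",
         "in both ears")
  pl <- mean(l); pr <- mean(r)
  diff <- pl - pr
  asym <- abs(diff) >= asym_threshold
  data.frame(pta_left = pl, pta_right = pr, pta_bilateral = (pl + pr) / 2,
             asymmetric = asym,
             worse_ear = if (!asym) "none" else if (diff > 0) "left"
                         else "right",
             stringsAsFactors = FALSE)
}

#' Per-patient audiometric summary table
#'
#' Cleans a raw audiometry table, determines exam validity, averages each
#' patient's valid audiograms into a single audiogram, and computes 4F-PTAs
#' and asymmetry. Patients without any valid audiogram are omitted.
#'
#' @param audiometry raw audiometry table (`patient_id`, `exam_day`, `ear`,
#'   `frequency_hz`, `entry`).
#' @param tokens see [audiogram_tokens()].
#' @param asym_threshold see [compute_4f_pta()].
#' @return list with `pta` (data.frame: `patient_id`, `pta_left`,
#'   `pta_right`, `pta_bilateral`, `asymmetric`, `worse_ear`,
#'   `n_audiograms`) and `cleaning_log` (counts of cleaning actions by
#'   provenance).
#' @export
summarize_audiometry <- function(audiometry, tokens = audiogram_tokens(),
                                 asym_threshold = 15) {
  clean <- clean_audiogram(audiometry, tokens)
  prov_levels <- c("as_entered", "ceiling_substituted", "set_missing")
  log <- data.frame(provenance = prov_levels,
                    n = as.integer(table(factor(clean$provenance,
                                                levels = prov_levels))),
                    stringsAsFactors = FALSE)
  if (nrow(clean) == 0L)
    return(list(pta = data.frame(patient_id = character(0),
                                 pta_left = numeric(0), pta_right = numeric(0),
                                 pta_bilateral = numeric(0),
                                 asymmetric = logical(0),
                                 worse_ear = character(0),
                                 n_audiograms = integer(0),
                                 stringsAsFactors = FALSE),
                cleaning_log = log))

  # exam-level validity on the four PTA frequencies, both ears, vectorised
  exam_key <- paste(clean$patient_id, clean$exam_day, sep = "|")
  pta_cell <- clean$frequency_hz %in% PTA_FREQS & !is.na(clean$threshold_db)
  n_pta_cells <- tapply(pta_cell, exam_key, sum)
  valid_exams <- names(n_pta_cells)[n_pta_cells == 8L]
  cl <- clean[exam_key %in% valid_exams &
                clean$frequency_hz %in% PTA_FREQS &
                !is.na(clean$threshold_db), , drop = FALSE]
  if (nrow(cl) == 0L)
    return(list(pta = data.frame(patient_id = character(0),
                                 pta_left = numeric(0), pta_right = numeric(0),
                                 pta_bilateral = numeric(0),
                                 asymmetric = logical(0),
                                 worse_ear = character(0),
                                 n_audiograms = integer(0),
                                 stringsAsFactors = FALSE),
                cleaning_log = log))

  # average across each patient's valid exams, then per-ear PTA
  cell_key <- paste(cl$patient_id, cl$ear, cl$frequency_hz, sep = "|")
  cell_mean <- tapply(cl$threshold_db, cell_key, mean)
  parts <- do.call(rbind, strsplit(names(cell_mean), "|", fixed = TRUE))
  cellDF <- data.frame(patient_id = parts[, 1L], ear = parts[, 2L],
                       threshold_db = as.numeric(cell_mean),
                       stringsAsFactors = FALSE)
  ear_key <- paste(cellDF$patient_id, cellDF$ear, sep = "|")
  ear_pta <- tapply(cellDF$threshold_db, ear_key, mean)
  eparts <- do.call(rbind, strsplit(names(ear_pta), "|", fixed = TRUE))
  wide <- data.frame(patient_id = eparts[, 1L], ear = eparts[, 2L],
                     pta = as.numeric(ear_pta), stringsAsFactors = FALSE)
  left <- wide[wide$ear == "L", c("patient_id", "pta")]
  right <- wide[wide$ear == "R", c("patient_id", "pta")]
  names(left)[2L] <- "pta_left"; names(right)[2L] <- "pta_right"
  pta <- merge(left, right, by = "patient_id")
  n_aud <- tapply(clean$exam_day[exam_key %in% valid_exams],
                  clean$patient_id[exam_key %in% valid_exams],
                  function(d) length(unique(d)))
  pta$pta_bilateral <- (pta$pta_left + pta$pta_right) / 2
  d <- pta$pta_left - pta$pta_right
  pta$asymmetric <- abs(d) >= asym_threshold
  pta$worse_ear <- ifelse(!pta$asymmetric, "none",
                          ifelse(d > 0, "left", "right"))
  pta$n_audiograms <- as.integer(n_aud[pta$patient_id])
  pta <- pta[order(pta$patient_id), , drop = FALSE]
  rownames(pta) <- NULL
  list(pta = pta, cleaning_log = log)
}
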