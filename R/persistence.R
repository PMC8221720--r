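# Hearing-aid use persistence from battery-order (refill) histories.
#
# Battery orders are treated like prescription refills. With a dose supply
# D_dose (a battery order is projected to last 6 months) and an acceptable
# gap G_acc (12 months), a patient is persistent at time T after fitting iff
# T < t_last + D_dose + G_acc, where t_last is the most recent battery order
# strictly before T (the fitting-day order sits at t = 0). Consequently the
# smallest T at which any patient can be non-persistent is
# D_dose + G_acc = 18 months. Cohort persistence at T is the proportion of
# persistent patients among those who survived through [fitting,
# fitting + T).

#' Persistence parameters
#'
#' @param dose_days nominal supply duration of one battery order
#'   (D_dose, default 183 days = 6 months).
#' @param gap_days acceptable gap beyond supply exhaustion before a patient
#'   is deemed to have discontinued (G_acc, default 365 days = 12 months).
#' @param eval_days evaluation time after fitting (T, default 730 days =
#'   24 months).
#' @return a validated list of class `persistence_params`.
#' @export
persistence_params <- function(dose_days = 183L, gap_days = 365L,
                               eval_days = 730L) {
  for (f in c("dose_days", "gap_days", "eval_days")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop_field(f, "must be a strictly positive number of days")
  }
  out <- list(dose_days = dose_days, gap_days = gap_days,
              eval_days = eval_days)
  class(out) <- "persistence_params"
  out
}

#' Battery-order history of one patient
#'
#' @param patient_id patient identifier.
#' @param fitting_day fitting day (the fitting-day battery order itself).
#' @param order_days battery-order days, all `>= fitting_day`; the
#'   fitting-day order is included, duplicates are dropped.
#' @return list of class `battery_history`.
#' @export
battery_history <- function(patient_id, fitting_day, order_days) {
  order_days <- sort(unique(as.numeric(order_days)))
  if (length(order_days) == 0L || order_days[1L] != fitting_day)
    order_days <- sort(unique(c(fitting_day, order_days)))
  if (any(order_days < fitting_day))
    stop("order_days must not precede fitting_day")
  structure(list(patient_id = patient_id, fitting_day = fitting_day,
                 order_days = order_days), class = "battery_history")
}

#' Is a patient persistent at the evaluation time?
#'
#' Applies the refill-gap criterion `T < t_last + D_dose + G_acc` with
#' `t_last` the most recent order strictly before `T` (days measured from
#' fitting; an order on day `T` itself does not count).
#'
#' @param history a [battery_history()] object.
#' @param params a [persistence_params()] object; `eval_days` is `T`.
#' @return logical flag.
#' @seealso [is_persistent_brute()] for the day-stepping oracle.
#' @export
is_persistent <- function(history, params = persistence_params()) {
  t <- history$order_days - history$fitting_day
  t_before <- t[t < params$eval_days]
  if (length(t_before) == 0L)
    stop("no battery order at or before the evaluation time; a valid ",
         "history includes the fitting-day order")
  t_last <- max(t_before)
  params$eval_days < t_last + params$dose_days + params$gap_days
}

#' Day-stepping persistence oracle
#'
#' Brute-force check of the refill-gap criterion: walks every day from
#' fitting to `T`, marking days covered by a dose supply, and deems the
#' patient non-persistent iff the run of uncovered days immediately before
#' `T` reaches the acceptable gap. Exists as an independent validation
#' oracle for [is_persistent()]; never use it for cohort-scale computation.
#'
#' @inheritParams is_persistent
#' @return logical flag.
#' @export
is_persistent_brute <- function(history, params = persistence_params()) {
  t <- history$order_days - history$fitting_day
  t_eval <- params$eval_days
  if (t_eval < 1) return(TRUE)
  covered <- rep(FALSE, t_eval)            # days 0 .. t_eval-1
  for (o in t[t < t_eval]) {
    lo <- o + 1L
    hi <- min(o + params$dose_days, t_eval)
    if (lo <= hi) covered[lo:hi] <- TRUE
  }
  gap_run <- 0L
  for (d in seq_len(t_eval)) {
    if (covered[d]) gap_run <- 0L else gap_run <- gap_run + 1L
  }
  gap_run < params$gap_days
}

#' Medication possession ratio over an observation window
#'
#' Days with a battery supply on hand (union of per-order supply intervals
#' `[t, t + dose_days)` intersected with `[0, window_days)`, overlapping
#' supplies not double-counted) divided by the window length.
#'
#' @param history a [battery_history()] object.
#' @param window_days observation window in days (> 0).
#' @param params a [persistence_params()] object (supplies `dose_days`).
#' @return ratio in `[0, 1]`.
#' @export
medication_possession_ratio <- function(history, window_days,
                                        params = persistence_params()) {
  stopifnot(window_days > 0)
  t <- history$order_days - history$fitting_day
  lo <- pmax(t, 0)
  hi <- pmin(t + params$dose_days, window_days)
  keep <- lo < hi
  lo <- lo[keep]; hi <- hi[keep]
  if (length(lo) == 0L) return(0)
  # union of sorted intervals
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  covered <- 0
  cur_lo <- lo[1L]; cur_hi <- hi[1L]
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      covered <- covered + (cur_hi - cur_lo)
      cur_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  covered <- covered + (cur_hi - cur_lo)
  covered / window_days
}

#' Cohort-level persistence at the evaluation time
#'
#' Computes per-patient persistence flags from a fitting table and a
#' battery-order table and aggregates them over the patients who survived
#' the evaluation window; patients who died within `[fitting, fitting + T)`
#' are excluded, as are patients flagged implausible.
#'
#' @param fitting data.frame from [assign_fitting_dates()] (`patient_id`,
#'   `fitting_day`; rows with `NA` fitting are dropped).
#' @param battery_orders data.frame with `patient_id`, `order_day`.
#' @param demographics one row per patient with `patient_id`, `death_day`
#'   and optionally `implausible`.
#' @param params a [persistence_params()] object.
#' @return object of class `persistence_estimate`: list with `proportion`,
#'   `n_included`, `n_excluded_death`, `n_excluded_implausible`, `params`,
#'   `se` (binomial standard error) and `flags` (per-patient data.frame
#'   `patient_id`, `persistent`).
#' @export
cohort_persistence <- function(fitting, battery_orders, demographics,
                               params = persistence_params()) {
  fit <- fitting[!is.na(fitting$fitting_day), , drop = FALSE]
  T <- params$eval_days
  dem <- demographics[match(fit$patient_id, demographics$patient_id), ,
                      drop = FALSE]
  implaus <- if (is.null(dem$implausible)) rep(FALSE, nrow(fit)) else
    dem$implausible %in% TRUE
  surv <- survives_through(dem, fit$fitting_day, T)
  inc <- fit[!implaus & surv, , drop = FALSE]
  n_excl_death <- sum(!surv & !implaus)
  n_excl_implaus <- sum(implaus)
  if (nrow(inc) == 0L) stop("no patients eligible for persistence at T = ",
                            T, " days")
  bo <- battery_orders
  bo$fitting_day <- inc$fitting_day[match(bo$patient_id, inc$patient_id)]
  bo <- bo[!is.na(bo$fitting_day), , drop = FALSE]
  rel <- bo$order_day - bo$fitting_day
  ok <- rel >= 0 & rel < T
  t_last <- tapply(rel[ok], bo$patient_id[ok], max)
  tl <- as.numeric(t_last[inc$patient_id])
  tl[is.na(tl)] <- 0          # fitting-day order always exists at t = 0
  persistent <- T < tl + params$dose_days + params$gap_days
  p <- mean(persistent)
  out <- list(proportion = p, n_included = nrow(inc),
              n_excluded_death = n_excl_death,
              n_excluded_implausible = n_excl_implaus,
              params = params,
              se = sqrt(p * (1 - p) / nrow(inc)),
              flags = data.frame(patient_id = inc$patient_id,
                                 persistent = persistent,
                                 stringsAsFactors = FALSE))
  class(out) <- "persistence_estimate"
  out
}

#' @export
print.persistence_estimate <- function(x, ...) {
  cat(sprintf(
    "Hearing-aid use persistence at %d days: %.1f%% (n = %d, SE = %.2f%%)\n",
    as.integer(x$params$eval_days), 100 * x$proportion, x$n_included,
    100 * x$se))
  cat(sprintf("  excluded: %d died within the window, %d implausible\n",
              x$n_excluded_death, x$n_excluded_implausible))
  invisible(x)
}

#' @export
summary.persistence_estimate <- function(object, ...) {
  data.frame(eval_days = object$params$eval_days,
             proportion = object$proportion, se = object$se,
             n_included = object$n_included,
             n_excluded_death = object$n_excluded_death,
             n_excluded_implausible = object$n_excluded_implausible)
}

#' Persistence curve over a grid of evaluation times
#'
#' [cohort_persistence()] evaluated at each time of `t_grid`, with the
#' death-exclusion window equal to that time. In a death-free cohort the
#' curve is non-increasing; with death exclusion the included set changes
#' with `t`.
#'
#' @inheritParams cohort_persistence
#' @param t_grid ascending evaluation times in days.
#' @return data.frame of class `persistence_curve`: `t`, `proportion`, `n`.
#' @export
persistence_curve <- function(fitting, battery_orders, demographics,
                              params = persistence_params(),
                              t_grid = seq(183L, 1095L, by = 91L)) {
  if (is.unsorted(t_grid)) stop("t_grid must be ascending")
  rows <- lapply(t_grid, function(tt) {
    pp <- persistence_params(params$dose_days, params$gap_days, tt)
    est <- cohort_persistence(fitting, battery_orders, demographics, pp)
    data.frame(t = tt, proportion = est$proportion, n = est$n_included)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("persistence_curve", "data.frame")
  out
}

#' @export
plot.persistence_curve <- function(x, ...) {
  graphics::plot(x$t, 100 * x$proportion, type = "b", pch = 16,
                 xlab = "days after fitting", ylab = "persistence (%)",
                 ylim = c(0, 100), ...)
  graphics::abline(h = 100, lty = 3)
  invisible(x)
}
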