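#' Calibration constants for an open-flow respirometry channel
#'
#' @param fio2_reference fractional O2 concentration of incurrent (ambient)
#'   air; default 0.2095.
#' @param flow_rate_stp excurrent flow rate in ml/h at STP; default 80 l/h.
#' @param rq respiratory quotient assumed for the substrate mix (CO2
#'   produced per O2 consumed); default 0.85 (50% fat / 50% carbohydrate).
#' @param energy_equivalent J per ml O2; default 20.37.
#' @param barometric_pressure_kpa chamber pressure, kPa.
#' @param flow_at_stp logical; `TRUE` if `flow_rate_stp` is already a
#'   volume rate at standard temperature and pressure (the meter reads STP
#'   volumes); if `FALSE` the flow is corrected with [stp_correct()] using
#'   the concurrent logged temperature before the VO2 equation is applied.
#' @return a list of class `calibration_info`.
#' @export
calibration_info <- function(fio2_reference = 0.2095,
                             flow_rate_stp = 80000,
                             rq = 0.85,
                             energy_equivalent = 20.37,
                             barometric_pressure_kpa = 101.325,
                             flow_at_stp = TRUE) {
  stopifnot(flow_rate_stp > 0, energy_equivalent > 0,
            fio2_reference > 0, fio2_reference < 1,
            rq >= 0.7, rq <= 1.0, barometric_pressure_kpa > 0)
  structure(list(fio2_reference = fio2_reference,
                 flow_rate_stp = flow_rate_stp,
                 rq = rq,
                 energy_equivalent = energy_equivalent,
                 barometric_pressure_kpa = barometric_pressure_kpa,
                 flow_at_stp = flow_at_stp),
            class = "calibration_info")
}

#' Correct analyser baseline drift using hourly zero checks
#'
#' During a zero check the analyser samples ambient air, whose fractional O2
#' content is known (`fio2_reference`). The deviation of each zero-check
#' reading from the reference estimates the instantaneous analyser drift;
#' drift between checks is interpolated linearly (constant extrapolation
#' beyond the first/last check) and subtracted from the animal samples.
#'
#' The first `washout_s` seconds of each zero-check window are discarded
#' (analyser washout after switching inlets) and the median of the remaining
#' readings is used as the window's reference reading.
#'
#' @param trace data.frame with columns `timestamp` (POSIXct),
#'   `o2_fraction`, `is_zero_check` (logical).
#' @param fio2_reference known ambient O2 fraction (default 0.2095).
#' @param washout_s seconds discarded at the start of each zero window.
#' @param calib_warn_dev absolute deviation of a window median from the
#'   reference beyond which a calibration warning is flagged (default 0.005).
#' @return the trace restricted to animal samples (zero-check rows removed),
#'   with `o2_fraction` drift-corrected and an added `drift` column;
#'   attribute `calibration_warning` is TRUE if any window median deviated
#'   by more than `calib_warn_dev` from the reference.
#' @export
correct_baseline <- function(trace, fio2_reference = 0.2095,
                             washout_s = 60, calib_warn_dev = 0.005) {
  stopifnot(all(c("timestamp", "o2_fraction", "is_zero_check") %in% names(trace)))
  if (!any(trace$is_zero_check)) {
    stop("trace has no zero-check windows; baseline drift cannot be estimated",
         call. = FALSE)
  }
  r <- rle(trace$is_zero_check)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  zc <- which(r$values)
  t_num <- as.numeric(trace$timestamp)
  mids <- numeric(length(zc))
  meds <- numeric(length(zc))
  for (i in seq_along(zc)) {
    idx <- starts[zc[i]]:ends[zc[i]]
    mids[i] <- mean(range(t_num[idx]))
    keep <- t_num[idx] - t_num[idx[1]] >= washout_s
    if (!any(keep)) keep <- rep(TRUE, length(idx))  # short window: use all
    meds[i] <- stats::median(trace$o2_fraction[idx][keep])
  }
  warn <- any(abs(meds - fio2_reference) > calib_warn_dev)
  if (warn) {
    warning("zero-check reference deviates > ", calib_warn_dev,
            " from fio2_reference; check calibration", call. = FALSE)
  }
  offsets <- meds - fio2_reference
  drift <- if (length(zc) == 1L) {
    rep(offsets, length(t_num))
  } else {
    stats::approx(mids, offsets, xout = t_num, rule = 2)$y
  }
  out <- trace
  out$o2_fraction <- out$o2_fraction - drift
  out$drift <- drift
  out <- out[!out$is_zero_check, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "calibration_warning") <- warn
  attr(out, "n_zero_windows") <- length(zc)
  out
}

#' Correct a gas volume rate to standard temperature and pressure
#'
#' @param volume_rate rate in ml/h at ambient conditions.
#' @param temperature_c ambient temperature, degrees Celsius.
#' @param pressure_kpa ambient pressure, kPa.
#' @return rate in ml/h at STP (0 degrees C, 101.325 kPa).
#' @export
stp_correct <- function(volume_rate, temperature_c, pressure_kpa = 101.325) {
  stopifnot(all(temperature_c > -273.15), all(pressure_kpa > 0))
  volume_rate * (273.15 / (273.15 + temperature_c)) * (pressure_kpa / 101.325)
}

#' Compute oxygen consumption from a drift-corrected trace
#'
#' Applies the open-flow respirometry equation
#' \deqn{V'O_2 = FR_e (FiO_2 - F'eO_2) / [1 - FiO_2 (1 - RQ)]}
#' per sample, where \eqn{FR_e} is the excurrent flow rate at STP,
#' \eqn{FiO_2} the incurrent and \eqn{F'eO_2} the excurrent fractional O2
#' concentration, and RQ the respiratory quotient. Oxygen consumption is
#' converted to energy with the calibration's energy equivalent.
#'
#' Small negative VO2 values (analyser noise) are clipped to zero when they
#' lie within `2 * noise_sd_vo2`; larger negatives are kept but flagged.
#'
#' @param trace drift-corrected trace (output of [correct_baseline()]).
#' @param calib a [calibration_info()] object.
#' @param temperature_c optional per-sample chamber temperature used to
#'   STP-correct the flow when `calib$flow_at_stp` is FALSE.
#' @param noise_sd_vo2 expected VO2 noise SD (ml/h) used for the clipping
#'   tolerance; default 0 (no clipping, all negatives flagged).
#' @return data.frame: `timestamp`, `vo2_ml_h`, `energy_j_h`, `flag_negative`.
#' @export
compute_vo2 <- function(trace, calib, temperature_c = NULL, noise_sd_vo2 = 0) {
  stopifnot(inherits(calib, "calibration_info"))
  denom <- 1 - calib$fio2_reference * (1 - calib$rq)
  if (denom <= 0) {
    stop("degenerate denominator: FiO2 * (1 - RQ) >= 1; check calibration",
         call. = FALSE)
  }
  flow <- calib$flow_rate_stp
  if (!calib$flow_at_stp) {
    if (is.null(temperature_c)) {
      stop("flow is not at STP: supply concurrent temperature_c", call. = FALSE)
    }
    flow <- stp_correct(flow, temperature_c, calib$barometric_pressure_kpa)
  }
  vo2 <- flow * (calib$fio2_reference - trace$o2_fraction) / denom
  flag <- vo2 < -2 * noise_sd_vo2
  vo2[vo2 < 0 & !flag] <- 0
  data.frame(timestamp = trace$timestamp,
             vo2_ml_h = vo2,
             energy_j_h = vo2 * calib$energy_equivalent,
             flag_negative = flag)
}

#' Convert oxygen consumption to energy expenditure
#'
#' @param vo2_ml_h oxygen consumption, ml O2 per hour.
#' @param energy_equivalent J per ml O2 (default 20.37).
#' @return energy expenditure in kJ per hour.
#' @export
vo2_to_kj <- function(vo2_ml_h, energy_equivalent = 20.37) {
  vo2_ml_h * energy_equivalent / 1000
}

#' Detect out-of-box absence intervals in a VO2 series
#'
#' When the animal leaves the nest box the oxygen depletion collapses
#' towards zero. A sample is provisionally "low" when its VO2 falls below
#' `threshold_fraction` times the series' rolling median; maximal low runs
#' lasting at least `min_bout_min` minutes are marked absent. An externally
#' supplied occupancy mask (from a generator ledger or camera traps)
#' overrides detection entirely.
#'
#' @param vo2 data.frame with `timestamp` and `vo2_ml_h` (one individual-day).
#' @param threshold_fraction fraction of the rolling median below which a
#'   sample counts as low (default 0.25).
#' @param min_bout_min minimum bout duration in minutes (default 30).
#' @param rolling_window_min width of the rolling-median window in minutes
#'   (default 180).
#' @param override_mask optional logical vector (TRUE = present) aligned to
#'   `vo2`; returned unchanged when supplied.
#' @return logical vector, TRUE where the animal is present. If every sample
#'   is absent, attribute `empty_day` is set (day excluded downstream).
#' @export
detect_absence <- function(vo2, threshold_fraction = 0.25, min_bout_min = 30,
                           rolling_window_min = 180, override_mask = NULL) {
  n <- nrow(vo2)
  stopifnot(n > 0)
  if (!is.null(override_mask)) {
    stopifnot(length(override_mask) == n)
    return(override_mask)
  }
  if (stats::median(vo2$vo2_ml_h) <= 0) {
    # at least half the day at zero consumption: no usable resting data
    mask <- rep(FALSE, n)
    attr(mask, "empty_day") <- TRUE
    return(mask)
  }
  dt <- if (n > 1) stats::median(diff(as.numeric(vo2$timestamp))) else 10
  k <- max(3, round(rolling_window_min * 60 / dt))
  if (k %% 2 == 0) k <- k + 1
  k <- min(k, if (n %% 2 == 1) n else n - 1)
  med <- if (n >= 3) stats::runmed(vo2$vo2_ml_h, k, endrule = "median")
         else rep(stats::median(vo2$vo2_ml_h), n)
  # floor the rolling median at half the day's overall median, so bouts
  # longer than the window (rolling median ~ 0 inside them) are still low
  med <- pmax(med, 0.5 * stats::median(vo2$vo2_ml_h))
  low <- vo2$vo2_ml_h < threshold_fraction * med
  mask <- rep(TRUE, n)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  min_len <- min_bout_min * 60 / dt
  for (i in which(r$values)) {
    if (r$lengths[i] >= min_len) mask[starts[i]:ends[i]] <- FALSE
  }
  if (!any(mask)) attr(mask, "empty_day") <- TRUE
  mask
}
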