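#' Replace animal-on-logger outliers in nest temperature series
#'
#' A nest temperature more than `threshold_c` above the concurrent enclosure
#' temperature indicates the animal sitting on or near the logger rather
#' than a warm nest. Such readings are replaced by the median of the other
#' nest boxes' concurrent (within `align_window_min`) non-outlying nest
#' temperatures; if no other box has a concurrent reading the record is
#' dropped (set `NA`) with a warning.
#'
#' @param env named list (by individual id) of logger data.frames with
#'   `timestamp`, `t_nest_c`, `t_a_c`.
#' @param threshold_c outlier threshold, degrees C above T_a (default 3).
#' @param align_window_min nearest-neighbour alignment window, minutes.
#' @return the list with outlying `t_nest_c` replaced (or `NA` when
#'   irreplaceable) and a logical `t_nest_replaced` column added; attribute
#'   `n_replaced`/`n_dropped` on each element.
#' @export
clean_tnest <- function(env, threshold_c = 3, align_window_min = 5) {
  stopifnot(is.list(env), length(env) >= 1)
  ids <- names(env)
  is_out <- lapply(env, function(e) (e$t_nest_c - e$t_a_c) > threshold_c)
  out <- env
  for (id in ids) {
    e <- env[[id]]
    repl <- rep(FALSE, nrow(e))
    flag <- is_out[[id]]
    n_drop <- 0L
    for (j in which(flag)) {
      tj <- as.numeric(e$timestamp[j])
      others <- numeric(0)
      for (oid in setdiff(ids, id)) {
        eo <- env[[oid]]
        k <- which.min(abs(as.numeric(eo$timestamp) - tj))
        if (length(k) == 1 &&
            abs(as.numeric(eo$timestamp[k]) - tj) <= align_window_min * 60 &&
            !is_out[[oid]][k]) {
          others <- c(others, eo$t_nest_c[k])
        }
      }
      if (length(others) > 0) {
        out[[id]]$t_nest_c[j] <- stats::median(others)
        repl[j] <- TRUE
      } else {
        out[[id]]$t_nest_c[j] <- NA_real_
        n_drop <- n_drop + 1L
      }
    }
    if (n_drop > 0) {
      warning("dropped ", n_drop, " t_nest reading(s) for ", id,
              ": outlying with no concurrent box available", call. = FALSE)
    }
    out[[id]]$t_nest_replaced <- repl
    attr(out[[id]], "n_replaced") <- sum(repl)
    attr(out[[id]], "n_dropped") <- n_drop
  }
  out
}

#' Retain the lowest 30% of VO2 values within an hour
#'
#' Activity raises oxygen consumption above the resting level, so resting
#' metabolism within an hour is estimated from the lowest fraction of the
#' occupied samples. The retained count is `ceiling(fraction * n)` (never
#' empty for n >= 1); ties at the cutoff are broken by earlier timestamp.
#'
#' @param values numeric VO2 values for one individual x day x clock hour.
#' @param timestamps optional ordering key for tie-breaks; defaults to the
#'   input order.
#' @param fraction retained fraction (default 0.30).
#' @return the retained values, in ascending order.
#' @export
lowest30_filter <- function(values, timestamps = seq_along(values),
                            fraction = 0.30) {
  n <- length(values)
  if (n == 0) return(values)
  stopifnot(fraction > 0, fraction <= 1, length(timestamps) == n)
  k <- ceiling(fraction * n)
  ord <- order(values, timestamps)
  values[ord[seq_len(k)]]
}

#' Interpolate body mass within the housing period
#'
#' Assumes steady (linear-in-time) mass change between the weighing at
#' housing start and the weighing at release.
#'
#' @param mass_start_g,mass_end_g masses at `date_in`/`date_out`, g.
#' @param date_in,date_out housing dates (`Date`).
#' @param date measurement date(s) (`Date`).
#' @return interpolated mass in g.
#' @export
interpolate_mass <- function(mass_start_g, mass_end_g, date_in, date_out, date) {
  stopifnot(mass_start_g > 0, mass_end_g > 0, date_in < date_out)
  if (any(date < date_in) || any(date > date_out)) {
    stop("date outside the housing period [", format(date_in), ", ",
         format(date_out), "]", call. = FALSE)
  }
  frac <- as.numeric(date - date_in) / as.numeric(date_out - date_in)
  mass_start_g + frac * (mass_end_g - mass_start_g)
}

# round half-up to the nearest integer (positive temperatures)
round_half_up <- function(x) floor(x + 0.5)

#' Reduce VO2 series to the hourly resting-metabolic-rate analysis table
#'
#' Applies, per (individual, measurement day, clock hour): occupancy
#' masking, diel classification with twilight-transition exclusion, the
#' lowest-30% resting filter, hourly nest-temperature averaging (rounded
#' half-up to the integer degree), the 8-29 degree C restriction, and
#' mass-specific conversion with linearly interpolated body mass.
#'
#' @param vo2 named list (`"<id>_<day>"`) of VO2 data.frames
#'   (`timestamp`, `vo2_ml_h`, `flag_negative`).
#' @param masks named list aligned to `vo2`; logical, TRUE = present.
#' @param env cleaned logger series per individual (see [clean_tnest()]).
#' @param metadata metadata table (`id`, `habitat`, `run`, `mass_start_g`,
#'   `mass_end_g`, `date_in`, `date_out`).
#' @param lat,lon site coordinates for diel classification.
#' @param lowest_fraction resting filter fraction (default 0.30).
#' @param t_range admissible integer nest-temperature range (default 8-29).
#' @param min_samples minimum usable samples per hour (default 6 = 1 min).
#' @param transition_h twilight exclusion half-width, hours.
#' @return list with `records` (the hourly table) and `audit` (hour-level
#'   exclusion counts per filter and environment-cleaning counts).
#' @export
extract_hourly_rmr <- function(vo2, masks, env, metadata, lat, lon,
                               lowest_fraction = 0.30, t_range = c(8, 29),
                               min_samples = 6, transition_h = 1) {
  stopifnot(length(vo2) >= 1, identical(names(vo2), names(masks)))
  audit <- c(hours_total = 0L, absence = 0L, transition = 0L,
             too_few_samples = 0L, t_out_of_range = 0L, t_missing = 0L,
             records = 0L)
  audit_env <- c(t_nest_replaced = 0L, t_nest_dropped = 0L)
  for (id in names(env)) {
    audit_env["t_nest_replaced"] <- audit_env["t_nest_replaced"] +
      as.integer(sum(env[[id]]$t_nest_replaced %||% 0))
    audit_env["t_nest_dropped"] <- audit_env["t_nest_dropped"] +
      as.integer(sum(is.na(env[[id]]$t_nest_c)))
  }
  rows <- list()
  for (key in names(vo2)) {
    parts <- regmatches(key, regexec("^(.*)_(\\d{4}-\\d{2}-\\d{2})$", key))[[1]]
    id <- parts[2]
    day <- as.Date(parts[3])
    md <- metadata[metadata$id == id, ]
    stopifnot(nrow(md) == 1)
    v <- vo2[[key]]
    present <- masks[[key]]
    diel <- classify_diel(v$timestamp, lat, lon, transition_h)
    flag_neg <- if ("flag_negative" %in% names(v)) v$flag_negative else FALSE
    tz <- attr(v$timestamp, "tzone")
    hour <- as.integer(format(v$timestamp, "%H"))
    cal_day <- as.Date(v$timestamp, tz = tz)
    ei <- env[[id]]
    e_hour <- as.integer(format(ei$timestamp, "%H"))
    e_day <- as.Date(ei$timestamp, tz = tz)

    for (hb in split(seq_len(nrow(v)), paste(cal_day, hour))) {
      audit["hours_total"] <- audit["hours_total"] + 1L
      occ <- present[hb]
      if (!any(occ)) { audit["absence"] <- audit["absence"] + 1L; next }
      usable <- occ & diel[hb] != "excluded" & !flag_neg[hb]
      if (!any(occ & diel[hb] != "excluded")) {
        audit["transition"] <- audit["transition"] + 1L; next
      }
      if (sum(usable) < min_samples) {
        audit["too_few_samples"] <- audit["too_few_samples"] + 1L; next
      }
      idx <- hb[usable]
      kept <- lowest30_filter(v$vo2_ml_h[idx], v$timestamp[idx],
                              lowest_fraction)
      rmr_total <- mean(kept)
      h0 <- hour[hb[1]]
      d0 <- cal_day[hb[1]]
      et <- ei$t_nest_c[e_hour == h0 & e_day == d0]
      et <- et[!is.na(et)]
      if (length(et) == 0) { audit["t_missing"] <- audit["t_missing"] + 1L; next }
      t_int <- round_half_up(mean(et))
      if (t_int < t_range[1] || t_int > t_range[2]) {
        audit["t_out_of_range"] <- audit["t_out_of_range"] + 1L; next
      }
      mass <- interpolate_mass(md$mass_start_g, md$mass_end_g,
                               md$date_in, md$date_out, day)
      dfrac <- as.numeric(day - md$date_in) /
        as.numeric(md$date_out - md$date_in)
      dl <- diel[idx]
      diel_rec <- names(which.max(table(droplevels(dl))))
      audit["records"] <- audit["records"] + 1L
      rows[[length(rows) + 1]] <- data.frame(
        id = id, habitat = md$habitat, run = md$run,
        housing_half = if (dfrac <= 0.5) "first" else "second",
        day = day, hour = h0, diel = diel_rec, t_nest_int = t_int,
        rmr_total = rmr_total, rmr_mass_specific = rmr_total / mass,
        n_samples_used = length(kept)
      )
    }
  }
  if (length(rows) == 0) {
    stop("no records survive filtering; exclusion counts: ",
         paste(names(audit), audit, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records,
       audit = list(hours = as.list(audit), environment = as.list(audit_env)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
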