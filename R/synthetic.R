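#' Generating parameters of the mass-specific RMR model
#'
#' Holds the coefficients of the linear mixed model that the simulator
#' inverts: mass-specific resting metabolic rate (ml O2 h-1 g-1) as a linear
#' function of nest temperature, habitat of origin, diel phase and sampling
#' run, with individual random intercepts and random temperature slopes.
#' Defaults are the fitted coefficients of the study system the package
#' models: a forest-animal intercept of 0.612 ml O2 h-1 g-1, RMR falling by
#' 0.010 per degree C of nest temperature, urban animals offset by -0.103
#' with a flattened slope (+0.005 per degree C), and a nocturnal elevation
#' of 0.051.
#'
#' Variance-component defaults are anchored to the study's reported variance
#' decomposition (ICC about 0.42, marginal/conditional R2 about 0.30/0.60).
#'
#' @param intercept forest, daytime, run-1 intercept (ml O2 h-1 g-1).
#' @param beta_t slope on nest temperature (per degree C).
#' @param beta_habitat urban offset (ml O2 h-1 g-1).
#' @param beta_interaction urban offset to the temperature slope (per degree C).
#' @param beta_night nocturnal offset (ml O2 h-1 g-1).
#' @param run_effects offsets of sampling runs 1-4 relative to run 1.
#' @param sd_individual_intercept,sd_individual_slope SDs of the individual
#'   random intercept and random temperature slope.
#' @param sd_residual residual SD at the hourly-record level.
#' @param rq respiratory quotient used when inverting the gas equation.
#' @return list of class `true_model_params`.
#' @export
true_model_params <- function(intercept = 0.612,
                              beta_t = -0.010,
                              beta_habitat = -0.103,
                              beta_interaction = 0.005,
                              beta_night = 0.051,
                              run_effects = c(0, 0.050, 0.075, -0.091),
                              sd_individual_intercept = 0.07,
                              sd_individual_slope = 0.002,
                              sd_residual = 0.08,
                              rq = 0.85) {
  stopifnot(intercept > 0, length(run_effects) == 4,
            sd_individual_intercept >= 0, sd_individual_slope >= 0,
            sd_residual >= 0, rq >= 0.7, rq <= 1.0)
  structure(list(intercept = intercept, beta_t = beta_t,
                 beta_habitat = beta_habitat,
                 beta_interaction = beta_interaction,
                 beta_night = beta_night, run_effects = run_effects,
                 sd_individual_intercept = sd_individual_intercept,
                 sd_individual_slope = sd_individual_slope,
                 sd_residual = sd_residual, rq = rq),
            class = "true_model_params")
}

#' Configuration of the raw-trace simulator
#'
#' Defines cohort sizes, respirometry hardware settings, environment
#' dynamics, activity/absence behaviour and body-mass dynamics for
#' [simulate_cohort()]. Defaults reproduce the study conditions the package
#' emulates: 7 forest and 13 urban adult males housed about 15 days across
#' four spring sampling runs at a north-German site, measured over 24-h
#' sessions with an 80 l/h open-flow system sampling every 10 s with hourly
#' 5-min zero checks, and nest temperatures fluctuating over roughly
#' 8-29 degrees C.
#'
#' @param n_forest,n_urban number of individuals per habitat.
#' @param days_per_individual 24-h measurement days per individual.
#' @param housing_days days each individual is housed.
#' @param flow_rate excurrent flow, ml/h at STP (default 80 l/h).
#' @param fio2_ambient incurrent fractional O2 (default 0.2095).
#' @param sample_interval_s analyser cadence, seconds (default 10).
#' @param temp_logger_interval_min logger cadence, minutes (default 10).
#' @param zero_period_min,zero_duration_min zero-check schedule (default
#'   hourly for 5 min).
#' @param drift_rate analyser baseline drift scale, O2-fraction random-walk
#'   step SD per hour.
#' @param noise_sd analyser noise SD, O2-fraction units.
#' @param env environment dynamics: list with `mean_c`, `amplitude_c`,
#'   `day_sd_c`, `noise_sd_c`, `peak_hour`, `insulation_offset_c`,
#'   `spike_rate_per_day` (animal-on-logger spikes exceeding T_a + 3),
#'   `rh_mean`, `rh_sd`.
#' @param activity activity/absence behaviour: list with `burst_rate_h`,
#'   `mult_range`, `duration_min_range`, `absence_mean_h` (named vector,
#'   forest/urban), `absence_sd_h`, `max_bouts`.
#' @param mass body-mass model: list with `start_mean_g`, `start_sd_g`
#'   (named forest/urban), `gain_mean_g` (total over housing, named),
#'   `gain_sd_g`, `length_mean_cm`, `length_sd_cm`.
#' @param lat,lon,tz site coordinates and time zone.
#' @param start_date first run's housing start (Date or string).
#' @param pressure_kpa barometric pressure constant.
#' @param seed integer seed fixing all randomness.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_forest = 7, n_urban = 13,
                              days_per_individual = 3,
                              housing_days = 15,
                              flow_rate = 80000,
                              fio2_ambient = 0.2095,
                              sample_interval_s = 10,
                              temp_logger_interval_min = 10,
                              zero_period_min = 60,
                              zero_duration_min = 5,
                              drift_rate = 2e-4,
                              noise_sd = 1e-5,
                              env = list(),
                              activity = list(),
                              mass = list(),
                              lat = 53.5511, lon = 9.9937,
                              tz = "Europe/Berlin",
                              start_date = "2018-04-02",
                              pressure_kpa = 101.325,
                              seed = 1L) {
  stopifnot(n_forest >= 1, n_urban >= 1, days_per_individual >= 1,
            flow_rate > 0, fio2_ambient > 0, fio2_ambient < 1,
            sample_interval_s > 0, zero_duration_min < zero_period_min)
  env_def <- list(mean_c = 16, amplitude_c = 5, day_sd_c = 2.5,
                  noise_sd_c = 0.5, peak_hour = 15,
                  insulation_offset_c = 1.0, spike_rate_per_day = 0.5,
                  rh_mean = 75, rh_sd = 8)
  act_def <- list(burst_rate_h = 1.5, mult_range = c(2, 4),
                  duration_min_range = c(3, 10),
                  absence_mean_h = c(forest = 3.1, urban = 4.7),
                  absence_sd_h = 2.0, max_bouts = 3)
  mass_def <- list(start_mean_g = c(forest = 371.4, urban = 334.2),
                   start_sd_g = c(forest = 27.0, urban = 19.0),
                   gain_mean_g = c(forest = 4.9, urban = 9.6),
                   gain_sd_g = 13.7,
                   length_mean_cm = 22, length_sd_cm = 0.8)
  structure(list(n_forest = n_forest, n_urban = n_urban,
                 days_per_individual = days_per_individual,
                 housing_days = housing_days,
                 flow_rate = flow_rate, fio2_ambient = fio2_ambient,
                 sample_interval_s = sample_interval_s,
                 temp_logger_interval_min = temp_logger_interval_min,
                 zero_period_min = zero_period_min,
                 zero_duration_min = zero_duration_min,
                 drift_rate = drift_rate, noise_sd = noise_sd,
                 env = utils::modifyList(env_def, env),
                 activity = utils::modifyList(act_def, activity),
                 mass = utils::modifyList(mass_def, mass),
                 lat = lat, lon = lon, tz = tz,
                 start_date = as.Date(start_date),
                 pressure_kpa = pressure_kpa,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' True mass-specific resting metabolic rate under the generating model
#'
#' Evaluates the linear predictor of the generating mixed model for given
#' conditions and (optionally) individual random effects. Values driven
#' below zero by extreme inputs are clipped at zero with a warning: a
#' negative metabolic rate is unphysical.
#'
#' @param params a [true_model_params()] object.
#' @param t_nest nest temperature, degrees C (vectorised).
#' @param habitat `"forest"` or `"urban"`.
#' @param diel `"day"` or `"night"`.
#' @param run sampling run, 1-4.
#' @param rand_int,rand_slope individual random intercept/slope offsets.
#' @return mass-specific RMR, ml O2 h-1 g-1.
#' @export
true_rmr <- function(params, t_nest, habitat, diel, run = 1,
                     rand_int = 0, rand_slope = 0) {
  stopifnot(inherits(params, "true_model_params"), all(is.finite(t_nest)))
  if (!all(habitat %in% c("forest", "urban"))) {
    stop("invalid habitat level: ", paste(setdiff(habitat, c("forest", "urban")),
                                          collapse = ", "), call. = FALSE)
  }
  if (!all(diel %in% c("day", "night"))) {
    stop("invalid diel level: ", paste(setdiff(diel, c("day", "night")),
                                       collapse = ", "), call. = FALSE)
  }
  stopifnot(all(run %in% 1:4))
  urban <- as.numeric(habitat == "urban")
  night <- as.numeric(diel == "night")
  out <- params$intercept + params$beta_t * t_nest +
    urban * (params$beta_habitat + params$beta_interaction * t_nest) +
    night * params$beta_night + params$run_effects[run] +
    rand_int + rand_slope * t_nest
  if (any(out < 0)) {
    warning("true RMR clipped at 0 for ", sum(out < 0), " value(s)",
            call. = FALSE)
    out[out < 0] <- 0
  }
  out
}

# run assignment, housing dates and measurement-day schedule for a cohort
cohort_schedule <- function(config) {
  n <- config$n_forest + config$n_urban
  id <- sprintf("sq%02d", seq_len(n))
  habitat <- c(rep("forest", config$n_forest), rep("urban", config$n_urban))
  # cycling runs over the forest-then-urban id order interleaves habitats,
  # so every sampling run holds animals from both groups
  run <- rep(1:4, length.out = n)
  date_in <- config$start_date + (run - 1) * (config$housing_days + 6)
  date_out <- date_in + config$housing_days
  meas_offsets <- unique(round(seq(3, config$housing_days - 1,
                                   length.out = config$days_per_individual)))
  sched <- data.frame(id = id, habitat = habitat, run = run,
                      date_in = date_in, date_out = date_out)
  attr(sched, "meas_offsets") <- meas_offsets
  sched
}

# diurnal nest-temperature curve (deg C) at fractional hour-of-day h
diurnal_temp <- function(h, mean_c, amplitude_c, peak_hour) {
  mean_c + amplitude_c * cos(2 * pi * (h - peak_hour) / 24)
}

#' Simulate nest and enclosure temperature/humidity logger series
#'
#' Generates, for every individual and measurement day of the cohort
#' schedule, 10-min logger series of nest temperature (diurnal sinusoid +
#' day-to-day variation + noise), enclosure temperature (nest temperature
#' minus a configurable insulation offset) and relative humidity. Occasional
#' "animal-on-logger" spikes exceeding T_a + 3 degrees C are injected to
#' exercise the downstream outlier rule.
#'
#' @param config a [simulation_config()] object.
#' @param schedule internal cohort schedule; computed from `config` when
#'   omitted.
#' @return named list (by individual id) of data.frames with `timestamp`,
#'   `t_nest_c`, `t_a_c`, `rh_pct`, `spike` (logical ground truth).
#' @export
simulate_environment <- function(config, schedule = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(schedule)) {
    set.seed(config$seed)
    schedule <- cohort_schedule(config)
  }
  offs <- attr(schedule, "meas_offsets")
  e <- config$env
  step <- config$temp_logger_interval_min * 60
  out <- list()
  for (i in seq_len(nrow(schedule))) {
    rows <- list()
    for (d in offs) {
      t0 <- as.POSIXct(paste(schedule$date_in[i] + d, "14:00:00"),
                       tz = config$tz)
      ts <- t0 + seq(0, 24 * 3600 - step, by = step)
      h <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
      day_eff <- stats::rnorm(1, 0, e$day_sd_c)
      base <- diurnal_temp(h, e$mean_c + day_eff, e$amplitude_c, e$peak_hour) +
        stats::rnorm(length(ts), 0, e$noise_sd_c)
      t_a <- base - e$insulation_offset_c
      t_nest <- base
      spike <- rep(FALSE, length(ts))
      n_spike <- stats::rpois(1, e$spike_rate_per_day)
      if (n_spike > 0) {
        at <- sample(length(ts), n_spike)
        t_nest[at] <- t_a[at] + 3 + stats::runif(n_spike, 1, 4)
        spike[at] <- TRUE
      }
      rh <- pmin(100, pmax(20, stats::rnorm(length(ts), e$rh_mean, e$rh_sd)))
      rows[[length(rows) + 1]] <-
        data.frame(timestamp = ts, t_nest_c = t_nest, t_a_c = t_a,
                   rh_pct = rh, spike = spike)
    }
    out[[schedule$id[i]]] <- do.call(rbind, rows)
  }
  out
}

# absence bouts for one measurement day: matrix of (start_s, end_s) offsets
draw_absence_bouts <- function(total_h, max_bouts, day_window_s) {
  if (total_h <= 0) return(matrix(numeric(0), ncol = 2))
  n_bouts <- sample(seq_len(max_bouts), 1)
  w <- stats::runif(n_bouts)
  dur <- total_h * 3600 * w / sum(w)
  starts <- sort(stats::runif(n_bouts, day_window_s[1],
                              pmax(day_window_s[1] + 1, day_window_s[2] - dur)))
  cbind(starts, pmin(starts + dur, day_window_s[2]))
}

#' Simulate a full respirometry cohort with ground truth
#'
#' Forward-simulates raw analyser traces, environment logs and a metadata
#' table for a cohort, together with a truth ledger (per-sample true VO2,
#' occupancy mask, drift, and the individual random effects) for recovery
#' tests. Per 10-s sample the instantaneous oxygen consumption is
#' `true_rmr * mass * activity multiplier` (zero when the animal is out of
#' the box); the excurrent O2 fraction is the exact algebraic inverse of the
#' open-flow VO2 equation,
#' \deqn{F'eO_2 = FiO_2 - V'O_2 [1 - FiO_2 (1 - RQ)] / FR_e,}
#' and the analyser signal adds piecewise-linear baseline drift (anchored at
#' the zero-check windows, so hourly zero-check correction is exact) plus
#' Gaussian noise. Zero-check windows read ambient air (FiO2 + drift +
#' noise).
#'
#' @param config a [simulation_config()].
#' @param params a [true_model_params()].
#' @return list with `traces` (named list of raw-trace data.frames,
#'   `"<id>_<day>"`), `env` (per-individual logger series), `metadata`
#'   (one row per individual) and `truth` (ledger: per-trace sample truth,
#'   `random_effects`, the generating `params` and `config`).
#' @export
simulate_cohort <- function(config, params) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(params, "true_model_params"))
  set.seed(config$seed)
  sched <- cohort_schedule(config)
  offs <- attr(sched, "meas_offsets")
  n <- nrow(sched)

  re <- data.frame(
    id = sched$id,
    rand_int = stats::rnorm(n, 0, params$sd_individual_intercept),
    rand_slope = stats::rnorm(n, 0, params$sd_individual_slope)
  )
  m <- config$mass
  mass_start <- stats::rnorm(n, m$start_mean_g[sched$habitat],
                             m$start_sd_g[sched$habitat])
  mass_end <- mass_start + stats::rnorm(n, m$gain_mean_g[sched$habitat],
                                        m$gain_sd_g)
  metadata <- data.frame(
    id = sched$id, habitat = sched$habitat, run = sched$run,
    mass_start_g = round(mass_start, 1), mass_end_g = round(mass_end, 1),
    length_cm = round(stats::rnorm(n, m$length_mean_cm, m$length_sd_cm), 1),
    date_in = sched$date_in, date_out = sched$date_out
  )

  env <- simulate_environment(config, schedule = sched)

  step <- config$sample_interval_s
  denom <- 1 - config$fio2_ambient * (1 - params$rq)
  act <- config$activity
  traces <- list()
  truth_samples <- list()

  for (i in seq_len(n)) {
    id <- sched$id[i]
    for (d in offs) {
      day_date <- sched$date_in[i] + d
      t0 <- as.POSIXct(paste(day_date, "14:00:00"), tz = config$tz)
      ts <- t0 + seq(0, 24 * 3600 - step, by = step)
      nsamp <- length(ts)
      sec <- as.numeric(ts) - as.numeric(t0)

      # nest temperature at sample cadence, interpolated from the logger
      ei <- env[[id]]
      in_day <- ei$timestamp >= t0 & ei$timestamp < t0 + 24 * 3600
      t_nest <- stats::approx(as.numeric(ei$timestamp[in_day]),
                              ei$t_nest_c[in_day], xout = as.numeric(ts),
                              rule = 2)$y

      # diel phase by civil twilight (generating model knows day/night only)
      dts <- sort(unique(as.Date(ts, tz = config$tz)))
      evs <- solar_events(dts, config$lat, config$lon, config$tz)
      di <- match(as.Date(ts, tz = config$tz), evs$date)
      is_day <- ts >= evs$civil_dawn[di] & ts <= evs$civil_dusk[di]
      diel <- ifelse(is_day, "day", "night")

      # body mass on this day (steady change over housing)
      frac <- d / config$housing_days
      mass_g <- mass_start[i] + frac * (mass_end[i] - mass_start[i])

      rmr_g <- true_rmr(params, t_nest, sched$habitat[i], diel,
                        sched$run[i], re$rand_int[i], re$rand_slope[i])

      # absence bouts, placed in the daylight window (animals forage by day)
      occupied <- rep(TRUE, nsamp)
      day_sec <- range(sec[is_day])
      if (!any(is_day)) day_sec <- c(0, 24 * 3600)
      total_h <- max(0, stats::rnorm(1, act$absence_mean_h[sched$habitat[i]],
                                     act$absence_sd_h))
      bouts <- draw_absence_bouts(total_h, act$max_bouts, day_sec)
      for (b in seq_len(nrow(bouts))) {
        occupied[sec >= bouts[b, 1] & sec < bouts[b, 2]] <- FALSE
      }

      # activity bursts while present
      mult <- rep(1, nsamp)
      n_burst <- stats::rpois(1, act$burst_rate_h * 24)
      if (n_burst > 0) {
        bs <- stats::runif(n_burst, 0, 24 * 3600)
        bd <- stats::runif(n_burst, act$duration_min_range[1],
                           act$duration_min_range[2]) * 60
        bm <- stats::runif(n_burst, act$mult_range[1], act$mult_range[2])
        for (b in seq_len(n_burst)) {
          sel <- sec >= bs[b] & sec < bs[b] + bd[b]
          mult[sel] <- pmax(mult[sel], bm[b])
        }
      }
      mult[!occupied] <- 1

      vo2_true <- rmr_g * mass_g * mult
      vo2_true[!occupied] <- 0

      feo2 <- config$fio2_ambient - vo2_true * denom / config$flow_rate
      if (any(feo2 <= 0) || any(feo2 > config$fio2_ambient)) {
        stop("simulated excurrent O2 fraction outside (0, FiO2]: ",
             "flow too low for simulated VO2", call. = FALSE)
      }

      # zero-check schedule: first zero_duration_min of each period
      period_s <- config$zero_period_min * 60
      is_zero <- (sec %% period_s) < config$zero_duration_min * 60

      # piecewise-linear drift anchored at zero-window midpoints; constant
      # within each window so the window median reads the knot exactly
      hours <- unique(sec[is_zero] %/% period_s)
      knot_t <- vapply(hours, function(hh) {
        mean(range(sec[is_zero & sec %/% period_s == hh]))
      }, numeric(1))
      knot_d <- cumsum(stats::rnorm(length(knot_t), 0, config$drift_rate))
      drift <- stats::approx(knot_t, knot_d, xout = sec, rule = 2)$y
      for (k in seq_along(hours)) {
        w <- is_zero & sec %/% period_s == hours[k]
        drift[w] <- knot_d[k]
      }

      signal <- ifelse(is_zero, config$fio2_ambient, feo2) + drift +
        stats::rnorm(nsamp, 0, config$noise_sd)

      key <- paste0(id, "_", format(day_date))
      traces[[key]] <- data.frame(timestamp = ts, o2_fraction = signal,
                                  is_zero_check = is_zero)
      truth_samples[[key]] <- data.frame(
        timestamp = ts, vo2_true_ml_h = vo2_true, occupied = occupied,
        drift = drift, multiplier = mult, t_nest_c = t_nest, diel = diel,
        rmr_true_g = rmr_g, mass_g = mass_g
      )
    }
  }

  list(traces = traces, env = env, metadata = metadata,
       truth = list(samples = truth_samples, random_effects = re,
                    params = params, config = config))
}

#' Simulate hourly RMR records directly from the generating model
#'
#' Draws the analysis table (one mass-specific RMR record per individual,
#' measurement day and clock hour) straight from the linear mixed model,
#' bypassing trace synthesis and extraction. This is the fast generator used
#' for parameter-recovery studies at study-like sample sizes; the raw-trace
#' chain is exercised by [simulate_cohort()].
#'
#' @param params a [true_model_params()].
#' @param n_forest,n_urban individuals per habitat.
#' @param days_per_individual measurement days each.
#' @param seed integer seed.
#' @param t_mean,t_amplitude,t_sd diurnal nest-temperature cycle (deg C).
#' @return data.frame with the hourly-record schema (`id`, `habitat`, `run`,
#'   `housing_half`, `day`, `hour`, `diel`, `t_nest_int`,
#'   `rmr_mass_specific`).
#' @export
simulate_rmr_records <- function(params, n_forest = 7, n_urban = 13,
                                 days_per_individual = 3, seed = 1L,
                                 t_mean = 16, t_amplitude = 5, t_sd = 2.5) {
  stopifnot(inherits(params, "true_model_params"))
  set.seed(as.integer(seed))
  n <- n_forest + n_urban
  habitat <- c(rep("forest", n_forest), rep("urban", n_urban))
  run <- rep(1:4, length.out = n)
  re_int <- stats::rnorm(n, 0, params$sd_individual_intercept)
  re_slope <- stats::rnorm(n, 0, params$sd_individual_slope)
  # clock hours kept after transition exclusion around twilight
  night_hours <- c(22, 23, 0:4)
  day_hours <- 7:19
  hours <- c(day_hours, night_hours)
  diel_of <- ifelse(hours %in% day_hours, "day", "night")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    per_day <- lapply(seq_len(days_per_individual), function(d) {
      day_eff <- stats::rnorm(1, 0, t_sd)
      t_raw <- diurnal_temp(hours, t_mean + day_eff, t_amplitude, 15) +
        stats::rnorm(length(hours), 0, 0.5)
      t_int <- pmin(29, pmax(8, floor(t_raw + 0.5)))
      mu <- true_rmr(params, t_int, habitat[i], diel_of, run[i],
                     re_int[i], re_slope[i])
      data.frame(id = sprintf("sq%02d", i), habitat = habitat[i],
                 run = run[i],
                 housing_half = if (d <= days_per_individual / 2) "first" else "second",
                 day = d, hour = hours, diel = diel_of, t_nest_int = t_int,
                 rmr_mass_specific = mu + stats::rnorm(length(hours), 0,
                                                       params$sd_residual))
    })
    rows[[i]] <- do.call(rbind, per_day)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated cohort to CSV/JSON files
#'
#' Writes `trace_<id>_<day>.csv`, `env_<id>.csv`, `metadata.csv` and
#' `truth.json` under `dir`, the on-disk schema consumed by the processing
#' stage.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%S%z")
  for (key in names(cohort$traces)) {
    tr <- cohort$traces[[key]]
    tr$timestamp <- iso(tr$timestamp)
    utils::write.csv(tr, file.path(dir, paste0("trace_", key, ".csv")),
                     row.names = FALSE)
  }
  for (id in names(cohort$env)) {
    ev <- cohort$env[[id]]
    ev$timestamp <- iso(ev$timestamp)
    utils::write.csv(ev, file.path(dir, paste0("env_", id, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  truth <- list(
    random_effects = cohort$truth$random_effects,
    params = unclass(cohort$truth$params),
    occupancy = lapply(cohort$truth$samples, function(s) s$occupied)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
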