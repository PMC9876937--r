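# Shared fixtures and independent oracles, built in code at test time.

# A clean cohort: no analyser noise, no drift randomness beyond what the
# config requests, no activity bursts, no absence. Used for exactness tests.
quiet_sim_config <- function(seed = 3, noise_sd = 0, drift_rate = 0,
                             n_forest = 1, n_urban = 1,
                             days_per_individual = 1, spikes = 0.5) {
  simulation_config(
    n_forest = n_forest, n_urban = n_urban,
    days_per_individual = days_per_individual,
    noise_sd = noise_sd, drift_rate = drift_rate,
    activity = list(burst_rate_h = 0,
                    absence_mean_h = c(forest = 0, urban = 0),
                    absence_sd_h = 0),
    env = list(spike_rate_per_day = spikes),
    seed = seed
  )
}

# Build a small raw trace by hand: `hours` hours at 10-s cadence starting at
# a fixed instant, with a 5-min zero-check window at the top of each hour.
# `drift_fun(sec)` gives the analyser drift added to every reading;
# `feo2` is the true (drift-free) excurrent O2 fraction per sample.
make_trace <- function(hours = 2, feo2 = 0.2085, fio2 = 0.2095,
                       drift_fun = function(s) rep(0, length(s))) {
  t0 <- as.POSIXct("2018-05-01 14:00:00", tz = "Europe/Berlin")
  sec <- seq(0, hours * 3600 - 10, by = 10)
  is_zero <- (sec %% 3600) < 300
  feo2 <- rep_len(feo2, length(sec))
  raw <- ifelse(is_zero, fio2, feo2) + drift_fun(sec)
  data.frame(timestamp = t0 + sec,
             o2_fraction = raw,
             is_zero_check = is_zero)
}

# Independent low-precision solar altitude (Astronomical Almanac form),
# deliberately a different algorithm from the package's NOAA equations.
# Returns the sun's altitude in degrees at a POSIXct instant.
solar_altitude_indep <- function(time, lat, lon) {
  rad <- pi / 180
  n <- as.numeric(time) / 86400 - 10957.5  # days since J2000.0 (2000-01-01 12 UTC)
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lambda <- L + 1.915 * sin(g * rad) + 0.020 * sin(2 * g * rad)
  eps <- 23.439 - 0.0000004 * n
  delta <- asin(sin(eps * rad) * sin(lambda * rad)) / rad
  ra <- atan2(cos(eps * rad) * sin(lambda * rad), cos(lambda * rad)) / rad
  gmst <- (280.46061837 + 360.98564736629 * n) %% 360
  ha <- ((gmst + lon - ra + 180) %% 360) - 180
  asin(sin(lat * rad) * sin(delta * rad) +
         cos(lat * rad) * cos(delta * rad) * cos(ha * rad)) / rad
}

hamburg <- list(lat = 53.5511, lon = 9.9937, tz = "Europe/Berlin")

extdata <- function(f) system.file("extdata", f, package = "rmrflow")
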