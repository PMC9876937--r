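#' Solar event times for a date and location
#'
#' Computes civil dawn, official sunrise, solar noon, official sunset and
#' civil dusk for one or more dates at a given latitude/longitude, using the
#' NOAA solar-position equations. Official sunrise/sunset use a solar zenith
#' of 90.833 degrees (atmospheric refraction plus solar radius); civil
#' twilight uses 96 degrees (sun 6 degrees below the horizon).
#'
#' @param date a `Date` vector (interpreted as the local calendar date).
#' @param lat latitude in decimal degrees (north positive).
#' @param lon longitude in decimal degrees (east positive).
#' @param tz Olson time zone of the site, e.g. `"Europe/Berlin"`.
#' @return a data.frame with one row per date and `POSIXct` columns
#'   `civil_dawn`, `sunrise`, `solar_noon`, `sunset`, `civil_dusk` in `tz`.
#' @details At latitudes/dates where the sun does not cross a required
#'   zenith (polar day or night, or absent civil twilight) the event is
#'   undefined and an error is raised, since day/night classification is
#'   then meaningless for this pipeline.
#' @export
solar_events <- function(date, lat, lon, tz) {
  stopifnot(inherits(date, "Date"), abs(lat) <= 90, abs(lon) <= 180)
  # minutes after 00:00 UTC of each event, via NOAA hour-angle equations
  noon_utc <- vapply(as.numeric(date), function(d) {
    solar_noon_minutes(d, lon)
  }, numeric(1))
  ha_official <- solar_hour_angle(date, lat, lon, zenith = 90.833)
  ha_civil <- solar_hour_angle(date, lat, lon, zenith = 96)
  day0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  mk <- function(minutes) {
    t_utc <- day0 + minutes * 60
    as.POSIXct(format(t_utc, tz = tz, usetz = FALSE), tz = tz)
  }
  data.frame(
    date = date,
    civil_dawn = mk(noon_utc - 4 * ha_civil),
    sunrise = mk(noon_utc - 4 * ha_official),
    solar_noon = mk(noon_utc),
    sunset = mk(noon_utc + 4 * ha_official),
    civil_dusk = mk(noon_utc + 4 * ha_civil)
  )
}

# Julian century from a Date (at local noon-ish; precision is minutes)
julian_century <- function(date_num, frac_day = 0.5) {
  jd <- date_num + 2440587.5 + frac_day
  (jd - 2451545) / 36525
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# solar declination (deg) and equation of time (minutes)
solar_decl_eot <- function(t) {
  l0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  m <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ecc <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  ceq <- sin(deg2rad(m)) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(deg2rad(2 * m)) * (0.019993 - 0.000101 * t) +
    sin(deg2rad(3 * m)) * 0.000289
  true_long <- l0 + ceq
  omega <- 125.04 - 1934.136 * t
  app_long <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- rad2deg(asin(sin(deg2rad(eps)) * sin(deg2rad(app_long))))
  y <- tan(deg2rad(eps / 2))^2
  eot <- 4 * rad2deg(
    y * sin(2 * deg2rad(l0)) - 2 * ecc * sin(deg2rad(m)) +
      4 * ecc * y * sin(deg2rad(m)) * cos(2 * deg2rad(l0)) -
      0.5 * y^2 * sin(4 * deg2rad(l0)) - 1.25 * ecc^2 * sin(2 * deg2rad(m))
  )
  list(decl = decl, eot = eot)
}

solar_noon_minutes <- function(date_num, lon) {
  se <- solar_decl_eot(julian_century(date_num))
  720 - 4 * lon - se$eot
}

# hour angle (deg) at which the sun reaches the given zenith
solar_hour_angle <- function(date, lat, lon, zenith) {
  t <- julian_century(as.numeric(date))
  decl <- solar_decl_eot(t)$decl
  cos_ha <- cos(deg2rad(zenith)) / (cos(deg2rad(lat)) * cos(deg2rad(decl))) -
    tan(deg2rad(lat)) * tan(deg2rad(decl))
  if (any(abs(cos_ha) > 1)) {
    stop("sun never crosses zenith ", zenith,
         " deg at this latitude/date (polar day or night); ",
         "day/night classification unsupported", call. = FALSE)
  }
  rad2deg(acos(cos_ha))
}

#' Classify timestamps as day, night or twilight-transition
#'
#' Day is the interval between civil dawn and civil dusk; everything else is
#' night. Independently, any timestamp within one hour of official sunrise
#' or official sunset is marked `excluded`: those hours hold the switch
#' between diurnal and nocturnal metabolism and are dropped from resting
#' metabolic rate analyses.
#'
#' @param time `POSIXct` vector carrying the site's time zone.
#' @param lat,lon site coordinates in decimal degrees.
#' @param transition_h half-width of the exclusion window around official
#'   sunrise/sunset, in hours (default 1).
#' @return factor with levels `day`, `night`, `excluded`.
#' @export
classify_diel <- function(time, lat, lon, transition_h = 1) {
  stopifnot(inherits(time, "POSIXct"))
  tz <- attr(time, "tzone")
  if (is.null(tz) || tz == "") tz <- Sys.timezone()
  dates <- sort(unique(as.Date(time, tz = tz)))
  # events for each date plus neighbours, so windows spanning midnight work
  all_dates <- sort(unique(c(dates - 1, dates, dates + 1)))
  ev <- solar_events(all_dates, lat, lon, tz)
  out <- rep("night", length(time))
  day_of <- match(as.Date(time, tz = tz), ev$date)
  is_day <- time >= ev$civil_dawn[day_of] & time <= ev$civil_dusk[day_of]
  out[is_day] <- "day"
  near <- rep(FALSE, length(time))
  for (col in c("sunrise", "sunset")) {
    for (k in seq_len(nrow(ev))) {
      near <- near | abs(as.numeric(time) - as.numeric(ev[[col]][k])) <= transition_h * 3600
    }
  }
  out[near] <- "excluded"
  factor(out, levels = c("day", "night", "excluded"))
}
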