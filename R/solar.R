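#' Light-regime configuration
#'
#' Nautical twilight bounds the dawn/dusk regimes: the sun between the
#' horizon (0 deg) and -12 deg altitude. Solar altitude is sampled at 1-min
#' intervals when locating sunrise, sunset and twilight crossings.
#'
#' @param twilight_altitude_deg Twilight threshold altitude, degrees
#'   (default -12, nautical twilight).
#' @param horizon_altitude_deg Horizon altitude, degrees (default 0).
#' @param sampling_interval_min Scan step in minutes.
#' @return A `regime_config` list.
#' @export
regime_config <- function(twilight_altitude_deg = -12,
                          horizon_altitude_deg = 0,
                          sampling_interval_min = 1) {
  if (twilight_altitude_deg >= horizon_altitude_deg) {
    abort("twilight_altitude_deg must be below horizon_altitude_deg")
  }
  structure(list(twilight_altitude_deg = twilight_altitude_deg,
                 horizon_altitude_deg = horizon_altitude_deg,
                 sampling_interval_min = sampling_interval_min),
            class = "regime_config")
}

check_location <- function(lat, lon) {
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    abort("invalid coordinates: need |latitude| <= 90 and |longitude| <= 180")
  }
}

#' Geometric solar altitude
#'
#' Low-precision solar ephemeris (NOAA/Meeus solar position algorithm):
#' geometric altitude of the sun's centre, no atmospheric refraction.
#' Accurate to a few hundredths of a degree over 1900-2100, well within the
#' 0.2 degree contract needed for 1-min twilight scanning.
#'
#' @param lat,lon Site latitude (deg, +N) and longitude (deg, +E).
#' @param time `POSIXct` UTC instants (vectorized).
#' @return Solar altitude in degrees.
#' @export
solar_altitude <- function(lat, lon, time) {
  check_location(lat, lon)
  time <- as.POSIXct(time, tz = "UTC")
  yr <- as.numeric(format(time[1], "%Y", tz = "UTC"))
  if (yr < 1900 || yr > 2100) {
    abort("solar_altitude supports years 1900-2100")
  }
  rad <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525

  gmls <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sin(rad * gmas) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(rad * 2 * gmas) * (0.019993 - 0.000101 * jc) +
    sin(rad * 3 * gmas) * 0.000289
  true_long <- gmls + eqctr
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(rad * omega)
  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  obliq <- mean_obliq + 0.00256 * cos(rad * omega)
  declin <- asin(sin(rad * obliq) * sin(rad * app_long)) / rad

  var_y <- tan(rad * obliq / 2)^2
  eq_time <- 4 / rad * (var_y * sin(2 * rad * gmls) -
    2 * eeo * sin(rad * gmas) +
    4 * eeo * var_y * sin(rad * gmas) * cos(2 * rad * gmls) -
    0.5 * var_y^2 * sin(4 * rad * gmls) -
    1.25 * eeo^2 * sin(2 * rad * gmas))

  mins_utc <- (as.numeric(time) %% 86400) / 60
  tst <- (mins_utc + eq_time + 4 * lon) %% 1440
  ha <- ifelse(tst / 4 < 0, tst / 4 + 180, tst / 4 - 180)
  cos_zen <- sin(rad * lat) * sin(rad * declin) +
    cos(rad * lat) * cos(rad * declin) * cos(rad * ha)
  90 - acos(pmin(pmax(cos_zen, -1), 1)) / rad
}

#' Solar event times for one UTC day
#'
#' Scans the UTC day at 1-min steps (configurable) and reports, when they
#' exist: `twilight_start` (first upward crossing of the twilight altitude),
#' `sunrise` (first upward crossing of the horizon), `sunset` (last downward
#' horizon crossing) and `twilight_end` (last downward twilight crossing).
#' Any event may be absent at polar latitudes (polar day/night); absent
#' events are `NA`.
#'
#' @param lat,lon Site coordinates (deg, +N / +E).
#' @param date A `Date` (UTC calendar day), vectorized.
#' @param cfg A [regime_config()].
#' @return Tibble with one row per date: `date`, `twilight_start`,
#'   `sunrise`, `sunset`, `twilight_end` (`POSIXct` UTC or `NA`).
#' @export
day_events <- function(lat, lon, date, cfg = regime_config()) {
  check_location(lat, lon)
  date <- as.Date(date)
  one <- function(d) {
    step <- cfg$sampling_interval_min * 60
    t0 <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
    tt <- t0 + seq(0, 86400, by = step)
    alt <- solar_altitude(lat, lon, tt)
    cross <- function(level, dir, last = FALSE) {
      if (dir > 0) {
        i <- which(alt[-length(alt)] < level & alt[-1] >= level)
      } else {
        i <- which(alt[-length(alt)] >= level & alt[-1] < level)
      }
      if (!length(i)) return(as.POSIXct(NA))
      tt[(if (last) max(i) else min(i)) + 1L]
    }
    tibble(
      date = d,
      twilight_start = cross(cfg$twilight_altitude_deg, +1),
      sunrise = cross(cfg$horizon_altitude_deg, +1),
      sunset = cross(cfg$horizon_altitude_deg, -1, last = TRUE),
      twilight_end = cross(cfg$twilight_altitude_deg, -1, last = TRUE)
    )
  }
  list_rbind(map(seq_along(date), function(i) one(date[i])))
}

#' Classify UTC hours into light regimes
#'
#' Partitions hours into `dawn`, `day`, `dusk`, `night` following the
#' nautical-twilight rules: dawn spans the hours of and between nautical
#' twilight start and sunrise; day the hours after sunrise but before
#' sunset; dusk from sunset to nautical twilight end; night the rest. The
#' entire hour containing a sun-condition change (sunrise, sunset) is
#' promoted to the twilight class, so each hour is labelled from its 1-min
#' solar-altitude profile: any minute with the sun in the twilight band and
#' rising makes the hour eligible for dawn, falling for dusk, with
#' precedence dawn > dusk > day > night. Polar days with no crossings fall
#' out naturally (all-day, all-night, or dawn-before / dusk-after solar
#' noon when the sun stays inside the twilight band).
#'
#' @param hours `POSIXct` UTC hour starts (sorted).
#' @param lat,lon Site coordinates (deg, +N / +E).
#' @param cfg A [regime_config()].
#' @return Tibble: `utc_hour`, `regime` (factor with levels dawn, day,
#'   dusk, night), `sun_altitude_midhour_deg`.
#' @export
classify_series <- function(hours, lat, lon, cfg = regime_config()) {
  if (!length(hours)) {
    return(tibble(utc_hour = as.POSIXct(character(), tz = "UTC"),
                  regime = factor(character(),
                                  levels = c("dawn", "day", "dusk", "night")),
                  sun_altitude_midhour_deg = numeric()))
  }
  check_location(lat, lon)
  hours <- as.POSIXct(hours, tz = "UTC")
  step <- cfg$sampling_interval_min * 60
  n_per_hour <- as.integer(3600 / step)
  # minute grid: each hour's minutes plus one extra sample for the slope
  offs <- seq(0, 3600, by = step)
  tt <- as.POSIXct(rep(as.numeric(hours), each = length(offs)) +
                     rep(offs, times = length(hours)),
                   tz = "UTC", origin = "1970-01-01")
  alt <- solar_altitude(lat, lon, tt)
  m <- matrix(alt, nrow = length(offs))
  a <- m[seq_len(n_per_hour), , drop = FALSE]         # minute altitudes
  rising <- m[-1, , drop = FALSE] > m[-nrow(m), , drop = FALSE]

  is_day <- a >= cfg$horizon_altitude_deg
  in_twi <- a >= cfg$twilight_altitude_deg & !is_day
  has_dawn <- colSums(in_twi & rising) > 0
  has_dusk <- colSums(in_twi & !rising) > 0
  has_day <- colSums(is_day) > 0
  regime <- ifelse(has_dawn, "dawn",
                   ifelse(has_dusk, "dusk", ifelse(has_day, "day", "night")))
  mid <- solar_altitude(lat, lon, hours + 1800)
  tibble(utc_hour = hours,
         regime = factor(regime, levels = c("dawn", "day", "dusk", "night")),
         sun_altitude_midhour_deg = mid)
}

#' @rdname classify_series
#' @param hour_start A single UTC hour start.
#' @return `classify_hour()` returns a single regime label (character).
#' @export
classify_hour <- function(hour_start, lat, lon, cfg = regime_config()) {
  as.character(classify_series(hour_start, lat, lon, cfg)$regime[1])
}
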