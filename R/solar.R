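# Angles cross the public interface in degrees; trigonometry is done in
# radians internally.
DEG2RAD <- pi / 180

.deg2rad <- function(x) x * DEG2RAD
.rad2deg <- function(x) x / DEG2RAD

# Guard against |x| marginally exceeding 1 at sunrise/sunset before asin/acos.
.clamp_unit <- function(x, tol = 1e-9) {
  bad <- abs(x) > 1 + tol
  if (any(bad, na.rm = TRUE)) {
    stop("inverse-trig argument outside [-1, 1] beyond tolerance: ",
         format(x[which(bad)[1]]), call. = FALSE)
  }
  pmin(1, pmax(-1, x))
}

.check_doy <- function(day_of_year) {
  if (!is.numeric(day_of_year) || any(is.na(day_of_year)) ||
      any(day_of_year < 1) || any(day_of_year > 366)) {
    stop("`day_of_year` must be in [1, 366]", call. = FALSE)
  }
  invisible(day_of_year)
}

#' Solar declination
#'
#' Cooper's approximation for the declination of the sun, the angle between
#' the sun's rays and the equatorial plane. The argument of the sine is in
#' degrees.
#'
#' @param day_of_year Day of the year `N` (1 = January 1st), 1--366.
#' @return Declination in degrees, in `[-23.45, 23.45]`.
#' @examples
#' solar_declination(172) # near the June solstice, ~23.45
#' @export
solar_declination <- function(day_of_year) {
  .check_doy(day_of_year)
  23.45 * sin(.deg2rad(360 * (284 + day_of_year) / 365))
}

#' Solar hour angle from local solar time
#'
#' The hour angle advances 15 degrees per hour and is zero at solar noon
#' (negative in the morning, positive in the afternoon).
#'
#' @param lst Local solar time in hours, 0--24.
#' @return Hour angle in degrees, in `[-180, 180]`.
#' @export
hour_angle <- function(lst) {
  if (!is.numeric(lst) || any(is.na(lst)) || any(lst < 0) || any(lst > 24)) {
    stop("`lst` must be in [0, 24] hours", call. = FALSE)
  }
  15 * (lst - 12)
}

#' Solar elevation angle
#'
#' @param declination Solar declination (degrees).
#' @param latitude Site latitude (degrees, positive north).
#' @param hour_angle_deg Hour angle (degrees).
#' @return Elevation above the horizon in degrees, in `[-90, 90]`.
#' @export
solar_elevation <- function(declination, latitude, hour_angle_deg) {
  sin_a <- sin(.deg2rad(declination)) * sin(.deg2rad(latitude)) +
    cos(.deg2rad(declination)) * cos(.deg2rad(latitude)) *
      cos(.deg2rad(hour_angle_deg))
  .rad2deg(asin(.clamp_unit(sin_a)))
}

#' Solar azimuth angle
#'
#' Azimuth measured clockwise from north, 0--360 degrees, using the
#' piecewise arccos convention: the arccos branch before solar noon
#' (negative hour angle) and its reflection `360 - arccos(.)` after noon.
#' At exactly zero hour angle the morning-branch limit is returned.
#'
#' @inheritParams solar_elevation
#' @param elevation Solar elevation (degrees); must satisfy `|elevation| < 90`.
#' @return Azimuth in degrees, `[0, 360)`.
#' @export
solar_azimuth <- function(declination, latitude, hour_angle_deg, elevation) {
  if (any(abs(elevation) >= 90 - 1e-9)) {
    stop("azimuth is degenerate at the zenith (|elevation| = 90)",
         call. = FALSE)
  }
  arg <- (sin(.deg2rad(declination)) * cos(.deg2rad(latitude)) -
            cos(.deg2rad(declination)) * sin(.deg2rad(latitude)) *
              cos(.deg2rad(hour_angle_deg))) / cos(.deg2rad(elevation))
  base <- .rad2deg(acos(.clamp_unit(arg)))
  ifelse(hour_angle_deg > 0, 360 - base, base) %% 360
}

#' Sunrise hour angle
#'
#' @inheritParams solar_elevation
#' @return Sunrise hour angle in degrees, `[0, 180]`. Errors on polar day or
#'   polar night (no sunrise/sunset at that latitude and declination).
#' @export
sunrise_hour_angle <- function(latitude, declination) {
  arg <- -tan(.deg2rad(latitude)) * tan(.deg2rad(declination))
  if (any(abs(arg) > 1 + 1e-9)) {
    stop("polar day or polar night: no sunrise at latitude ",
         paste(unique(latitude[abs(arg) > 1 + 1e-9]), collapse = ", "),
         " with declination ", format(declination[1]), call. = FALSE)
  }
  .rad2deg(acos(.clamp_unit(arg)))
}

#' Sun-earth distance factor
#'
#' Dimensionless correction for the annual variation of the earth-sun
#' distance, multiplying the solar constant.
#'
#' @inheritParams solar_declination
#' @return Factor in roughly `[0.967, 1.033]`.
#' @export
earth_sun_factor <- function(day_of_year) {
  .check_doy(day_of_year)
  1 + 0.033 * cos(2 * pi * day_of_year / 365)
}

#' Maximum possible sunshine duration
#'
#' Astronomical day length, i.e. the time between sunrise and sunset.
#'
#' @param sunrise_hour_angle_deg Sunrise hour angle (degrees).
#' @return Hours, `[0, 24]`.
#' @export
max_sunshine_duration <- function(sunrise_hour_angle_deg) {
  if (any(sunrise_hour_angle_deg < 0) || any(sunrise_hour_angle_deg > 180)) {
    stop("sunrise hour angle must be in [0, 180] degrees", call. = FALSE)
  }
  2 * sunrise_hour_angle_deg / 15
}

#' Everything solar that is fixed for one date at one site
#'
#' Bundles day-of-year, latitude, declination, sunrise hour angle, maximum
#' elevation, day length and the earth-sun distance factor, so downstream
#' code computes them once per day.
#'
#' @inheritParams solar_declination
#' @param latitude Site latitude in decimal degrees.
#' @return An object of class `day_context`: a list with elements
#'   `day_of_year`, `latitude`, `declination`, `sunrise_hour_angle`,
#'   `sunrise_lst`, `sunset_lst`, `max_elevation`, `max_sunshine_duration`
#'   and `earth_sun_factor`.
#' @examples
#' ctx <- day_context(172, 43.267)
#' ctx$max_elevation # 90 - |latitude - declination|
#' @export
day_context <- function(day_of_year, latitude) {
  .check_doy(day_of_year)
  if (!is.numeric(latitude) || abs(latitude) > 90) {
    stop("`latitude` must be in [-90, 90] degrees", call. = FALSE)
  }
  delta <- solar_declination(day_of_year)
  ws <- sunrise_hour_angle(latitude, delta)
  structure(
    list(
      day_of_year = day_of_year,
      latitude = latitude,
      declination = delta,
      sunrise_hour_angle = ws,
      sunrise_lst = 12 - ws / 15,
      sunset_lst = 12 + ws / 15,
      max_elevation = 90 - abs(latitude - delta),
      max_sunshine_duration = max_sunshine_duration(ws),
      earth_sun_factor = earth_sun_factor(day_of_year)
    ),
    class = "day_context"
  )
}

#' @export
print.day_context <- function(x, ...) {
  cat(sprintf(
    "<day_context> N = %d, lat = %.3f deg\n  declination %.2f deg, sunrise %05.2f LST, sunset %05.2f LST\n  max elevation %.2f deg, day length %.2f h\n",
    as.integer(x$day_of_year), x$latitude, x$declination,
    x$sunrise_lst, x$sunset_lst, x$max_elevation, x$max_sunshine_duration
  ))
  invisible(x)
}

#' Elevation and azimuth at local solar times
#'
#' Convenience wrapper evaluating the solar position for a vector of local
#' solar times within one day context.
#'
#' @param ctx A [day_context()].
#' @param lst Local solar times (hours).
#' @return A data frame with columns `lst`, `hour_angle`, `elevation`,
#'   `azimuth`.
#' @export
solar_position <- function(ctx, lst) {
  stopifnot(inherits(ctx, "day_context"))
  w <- hour_angle(lst)
  alpha <- solar_elevation(ctx$declination, ctx$latitude, w)
  beta <- solar_azimuth(ctx$declination, ctx$latitude, w, alpha)
  data.frame(lst = lst, hour_angle = w, elevation = alpha, azimuth = beta)
}

#' Optional longitude offset between clock time and local solar time
#'
#' The shading model works in local solar time throughout. When inputs are
#' recorded in zone clock time, this helper gives the offset (4 minutes per
#' degree of longitude) from the zone's reference meridian. It is not
#' applied anywhere by default.
#'
#' @param longitude Site longitude (degrees, positive east).
#' @param reference_meridian Longitude of the time-zone reference meridian.
#' @return Offset in hours to add to clock time to obtain local solar time.
#' @export
longitude_time_offset <- function(longitude, reference_meridian) {
  (longitude - reference_meridian) * 4 / 60
}
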