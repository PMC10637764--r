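# Solar constant, W m^-2
SOLAR_CONSTANT <- 1367

#' Daily extraterrestrial radiation on a horizontal surface
#'
#' Energy that would reach a horizontal surface at the top of the
#' atmosphere over one day. The additive sunrise-hour-angle term inside the
#' bracket must be in radians; mixing degrees into that term is the classic
#' implementation error for this formula, so the conversion is done in one
#' visible place here.
#'
#' @inheritParams day_context
#' @param solar_constant Solar constant in W m^-2.
#' @return Extraterrestrial radiation in MJ m^-2 day^-1.
#' @examples
#' extraterrestrial_radiation(172, 43.267) # ~41.9 in midsummer
#' @export
extraterrestrial_radiation <- function(day_of_year, latitude,
                                       solar_constant = SOLAR_CONSTANT) {
  ctx <- day_context(day_of_year, latitude)
  ws_rad <- .deg2rad(ctx$sunrise_hour_angle)
  phi <- .deg2rad(latitude)
  delta <- .deg2rad(ctx$declination)
  joules <- (24 * 3600 / pi) * solar_constant * ctx$earth_sun_factor *
    (cos(phi) * cos(delta) * sin(ws_rad) + ws_rad * sin(phi) * sin(delta))
  joules / 1e6
}

#' Diffuse fraction from clearness index and sunshine fraction
#'
#' Empirical regression of the ratio of diffuse to global radiation on the
#' clearness index (global over extraterrestrial) and the sunshine fraction
#' (measured over astronomical sunshine duration). The raw polynomial can
#' leave `[0, 1]` at the edges of its calibration range and is clamped by
#' default.
#'
#' @param clearness_index `Rg / R0`, dimensionless, >= 0.
#' @param sunshine_fraction `S / S0`, dimensionless, >= 0.
#' @param clamp Clamp the result into `[0, 1]` (default `TRUE`).
#' @return Diffuse fraction `Rd / Rg`.
#' @export
diffuse_fraction <- function(clearness_index, sunshine_fraction,
                             clamp = TRUE) {
  if (any(clearness_index < 0) || any(sunshine_fraction < 0)) {
    stop("clearness index and sunshine fraction must be non-negative",
         call. = FALSE)
  }
  f <- 1.06 - 0.56 * clearness_index - 0.11 * clearness_index^2 -
    0.26 * sunshine_fraction - 1.6 * sunshine_fraction^2
  if (clamp) f <- pmin(1, pmax(0, f))
  f
}

#' Partition daily global radiation into direct and diffuse components
#'
#' For each day, computes extraterrestrial radiation from the date and
#' latitude, the diffuse fraction from the clearness index and sunshine
#' fraction, and splits global radiation as `Ra = Rg - Rd`. Weather is
#' assumed uniform within a day. Sunshine durations marginally above the
#' astronomical maximum (recorder overshoot) are clipped with a warning.
#'
#' @param weather Data frame with columns `date` (`Date`), `Rg`
#'   (MJ m^-2 day^-1) and `S` (hours).
#' @param latitude Site latitude in decimal degrees.
#' @return The input with added columns `doy`, `R0`, `S0`,
#'   `clearness_index`, `sunshine_fraction`, `Rd`, `Ra`.
#' @export
partition_radiation <- function(weather, latitude) {
  req <- c("date", "Rg", "S")
  if (!all(req %in% names(weather))) {
    stop("`weather` needs columns date, Rg, S", call. = FALSE)
  }
  if (any(weather$Rg < 0)) stop("negative global radiation", call. = FALSE)
  if (any(weather$S < 0) || any(weather$S > 24)) {
    stop("sunshine duration must be in [0, 24] h", call. = FALSE)
  }
  doy <- as.integer(strftime(weather$date, "%j"))
  out <- weather
  out$doy <- doy
  out$R0 <- vapply(doy, extraterrestrial_radiation, numeric(1),
                   latitude = latitude)
  out$S0 <- vapply(doy, function(n) {
    ctx <- day_context(n, latitude)
    ctx$max_sunshine_duration
  }, numeric(1))
  over <- out$S > out$S0 + 1e-9
  if (any(over)) {
    warning(sum(over), " day(s) with sunshine duration above the ",
            "astronomical maximum; clipped to S0", call. = FALSE)
    out$S[over] <- out$S0[over]
  }
  out$clearness_index <- out$Rg / out$R0
  out$sunshine_fraction <- out$S / out$S0
  out$Rd <- out$Rg * diffuse_fraction(out$clearness_index,
                                      out$sunshine_fraction)
  out$Ra <- out$Rg - out$Rd
  out
}

#' Read a daily weather table
#'
#' CSV with header `date,Rg,S`: ISO-8601 dates, global radiation in
#' MJ m^-2 day^-1, sunshine duration in hours. Rows with missing or
#' unparseable values are dropped with a message naming the reason.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `date`, `Rg`, `S`.
#' @export
read_weather <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "Rg", "S") %in% names(raw))) {
    stop("weather CSV must have header date,Rg,S", call. = FALSE)
  }
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  Rg <- suppressWarnings(as.numeric(raw$Rg))
  S <- suppressWarnings(as.numeric(raw$S))
  bad <- is.na(date) | is.na(Rg) | is.na(S)
  if (any(bad)) {
    message("dropping ", sum(bad), " weather row(s) with missing or ",
            "unparseable date/Rg/S (rows ",
            paste(which(bad), collapse = ", "), ")")
  }
  data.frame(date = date[!bad], Rg = Rg[!bad], S = S[!bad])
}
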