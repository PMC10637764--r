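# Rasters are plain numeric matrices carrying a `pixel_size` attribute
# (metres per pixel). Heights are metres above the reference ground.

#' Construct a raster grid
#'
#' Lightweight container for single-band surface rasters: a numeric matrix
#' with a pixel size in metres.
#'
#' @param values Numeric matrix.
#' @param pixel_size Edge length of one pixel (m), > 0.
#' @return A matrix of class `raster_grid` with attribute `pixel_size`.
#' @export
raster_grid <- function(values, pixel_size) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  structure(values, pixel_size = pixel_size,
            class = c("raster_grid", class(values)))
}

#' Excess green vegetation index
#'
#' `EXG = 2g - r - b` per pixel, computed on raw digital numbers. Green
#' vegetation scores high; soil and grey surfaces score near or below zero.
#'
#' @param r,g,b Red, green and blue digital numbers (matrices or vectors of
#'   identical shape, >= 0).
#' @return The index, same shape as the inputs.
#' @export
exg <- function(r, g, b) {
  if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b)) ||
      length(r) != length(g) || length(r) != length(b)) {
    stop("r, g, b bands must have identical shape", call. = FALSE)
  }
  if (any(r < 0) || any(g < 0) || any(b < 0)) {
    stop("digital numbers must be >= 0", call. = FALSE)
  }
  2 * g - r - b
}

#' Threshold at the valley of a bimodal distribution
#'
#' Finds the local minimum of a kernel-smoothed histogram between its two
#' largest modes. Used twice in the pipeline: on the excess-green index to
#' split soil from vegetation, and on canopy heights to split maize from
#' soybean pixels.
#'
#' @param values Numeric vector with a two-mode distribution.
#' @param bw Kernel bandwidth passed to [stats::density()]; default
#'   `"nrd0"`.
#' @param n Number of density grid points (default 512).
#' @return The threshold value at the density minimum between the modes.
#'   Errors if fewer than two modes are found (supply a manual threshold in
#'   that case).
#' @export
bimodal_threshold <- function(values, bw = "nrd0", n = 512) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 3) {
    stop("distribution is degenerate; supply a manual threshold",
         call. = FALSE)
  }
  d <- stats::density(values, bw = bw, n = n)
  y <- d$y
  # interior local maxima of the smoothed density
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (length(peaks) < 2) {
    stop("histogram is unimodal; supply a manual threshold", call. = FALSE)
  }
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1
  d$x[valley]
}

#' Canopy height model from a surface raster and reference ground
#'
#' Per-pixel difference between a digital surface model and the reference
#' ground surface (the pre-emergence flight). Negative differences are
#' photogrammetric noise below ground and are clipped to zero.
#'
#' @param dsm,reference Co-registered [raster_grid()]s (or plain matrices)
#'   of identical shape and pixel size.
#' @return A `raster_grid` of canopy heights (m).
#' @export
chm <- function(dsm, reference) {
  if (!identical(dim(dsm), dim(reference))) {
    stop("DSM and reference grids must have identical shape", call. = FALSE)
  }
  ps_d <- attr(dsm, "pixel_size")
  ps_r <- attr(reference, "pixel_size")
  if (!is.null(ps_d) && !is.null(ps_r) && !isTRUE(all.equal(ps_d, ps_r))) {
    stop("DSM and reference pixel sizes differ", call. = FALSE)
  }
  out <- pmax(unclass(dsm) - unclass(reference), 0)
  raster_grid(out, if (is.null(ps_d)) 1 else ps_d)
}

#' Split soil-masked canopy heights into maize and soybean pixels
#'
#' @param chm_values Canopy heights (m) after soil masking.
#' @param height_threshold Height separating the species (m); pixels above
#'   are maize, at or below are soybean. Use [bimodal_threshold()] on the
#'   heights, or a stage-specific manual value.
#' @return List with numeric vectors `maize` and `soybean`. Warns when a
#'   class is empty.
#' @export
separate_species <- function(chm_values, height_threshold) {
  chm_values <- chm_values[is.finite(chm_values)]
  maize <- chm_values[chm_values > height_threshold]
  soybean <- chm_values[chm_values <= height_threshold]
  if (length(maize) == 0 || length(soybean) == 0) {
    warning("species separation produced an empty class at threshold ",
            format(height_threshold), call. = FALSE)
  }
  list(maize = maize, soybean = soybean)
}

#' Canopy height of one strip from its pixel heights
#'
#' The strip height is a high percentile of the soil-masked pixel heights:
#' the 99.9th for maize (an open canopy whose tallest organs define the
#' shading top) and the 90th for soybean (a closed canopy where the extreme
#' pixels are outliers). Percentiles interpolate linearly between order
#' statistics.
#'
#' @param chm_values Canopy heights (m) within the strip, soil-masked.
#' @param crop `"maize"` or `"soybean"`.
#' @return Strip canopy height (m).
#' @export
strip_height <- function(chm_values, crop = c("maize", "soybean")) {
  crop <- match.arg(crop)
  chm_values <- chm_values[is.finite(chm_values)]
  if (length(chm_values) == 0) {
    stop("no pixels left after masking; cannot extract a strip height",
         call. = FALSE)
  }
  p <- if (crop == "maize") 0.999 else 0.90
  unname(stats::quantile(chm_values, p, type = 7))
}

#' Interpolate sparse height measurements to a daily series
#'
#' Natural cubic spline through the measurements, evaluated at every day
#' between the first and last date. The spline passes exactly through the
#' measured values; no smoothing is applied and no extrapolation beyond the
#' measured range is allowed.
#'
#' @param dates Measurement dates (`Date`), strictly increasing, >= 3.
#' @param heights Measured heights (m), same length.
#' @param out_dates Optional target dates; default every day in
#'   `[min(dates), max(dates)]`. Requests outside the measured range error.
#' @return Data frame `date, height`.
#' @export
interpolate_daily <- function(dates, heights, out_dates = NULL) {
  dates <- as.Date(dates)
  if (length(dates) < 3) stop("need at least 3 measurement dates",
                              call. = FALSE)
  if (length(heights) != length(dates)) {
    stop("`dates` and `heights` lengths differ", call. = FALSE)
  }
  if (any(diff(as.numeric(dates)) <= 0)) {
    stop("`dates` must be strictly increasing", call. = FALSE)
  }
  if (is.null(out_dates)) {
    out_dates <- seq(min(dates), max(dates), by = "day")
  }
  out_dates <- as.Date(out_dates)
  if (any(out_dates < min(dates)) || any(out_dates > max(dates))) {
    stop("requested dates outside the measured range; the spline does not ",
         "extrapolate", call. = FALSE)
  }
  fit <- stats::spline(as.numeric(dates), heights, method = "natural",
                       xout = as.numeric(out_dates))
  data.frame(date = out_dates, height = fit$y)
}

#' Daily canopy height differences from daily strip heights
#'
#' Subtracts the soybean strip's daily canopy height from each adjacent
#' maize strip's, giving the side-specific driver of the shading model.
#' Negative differences (soybean taller) are clipped to zero with a
#' warning.
#'
#' @param maize_north,maize_south Data frames `date, height` for the
#'   northern and southern adjacent maize strip (from
#'   [interpolate_daily()]).
#' @param soybean Data frame `date, height` for the soybean strip, on the
#'   same dates.
#' @return Data frame `date, h_north, h_south` (m).
#' @export
height_difference <- function(maize_north, maize_south, soybean) {
  if (!identical(as.character(maize_north$date),
                 as.character(soybean$date)) ||
      !identical(as.character(maize_south$date),
                 as.character(soybean$date))) {
    stop("maize and soybean daily series must cover identical dates",
         call. = FALSE)
  }
  hn <- maize_north$height - soybean$height
  hs <- maize_south$height - soybean$height
  if (any(hn < 0) || any(hs < 0)) {
    warning("negative height differences clipped to 0 (soybean taller ",
            "than maize on some days)", call. = FALSE)
  }
  data.frame(date = as.Date(soybean$date),
             h_north = pmax(hn, 0), h_south = pmax(hs, 0))
}

#' Coefficient of determination (regression sum-of-squares form)
#'
#' `R2 = sum((est - mean(meas))^2) / sum((meas - mean(meas))^2)`: the
#' ratio of the estimated values' spread about the measured mean to the
#' measured spread. Note this is the regression-sum-of-squares form, not
#' `1 - SS_res / SS_tot`; the two agree for an ordinary least-squares fit
#' with intercept but can exceed 1 for biased estimates.
#'
#' @param estimated,measured Paired numeric vectors, length >= 2.
#' @return R-squared (dimensionless).
#' @export
r_squared <- function(estimated, measured) {
  if (length(estimated) != length(measured) || length(measured) < 2) {
    stop("need paired vectors of length >= 2", call. = FALSE)
  }
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) {
    stop("measured values have zero variance; R^2 undefined", call. = FALSE)
  }
  sum((estimated - mean(measured))^2) / ss_tot
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(estimated, measured) {
  if (length(estimated) != length(measured) || length(measured) < 2) {
    stop("need paired vectors of length >= 2", call. = FALSE)
  }
  sqrt(mean((estimated - measured)^2))
}

#' Strip canopy heights from a raster scene
#'
#' The full canopy-height stage on one acquisition: excess-green soil
#' masking (threshold found at the histogram valley unless supplied), a
#' canopy height model from the surface raster and reference ground, an
#' optional maize/soybean height split within each strip footprint, and
#' percentile height extraction per strip.
#'
#' @param dsm,reference Co-registered [raster_grid()]s.
#' @param ortho List with `r`, `g`, `b` digital-number matrices matching
#'   the raster shape.
#' @param strips Data frame `strip_id, crop, col_start, col_end`: each
#'   strip's footprint as a column band of the rasters.
#' @param exg_threshold Optional manual excess-green threshold; default
#'   [bimodal_threshold()] on the scene's EXG values.
#' @param height_threshold Optional height (m) separating maize from
#'   soybean pixels inside a footprint (stage-specific values may be
#'   supplied); `NULL` skips the species split.
#' @return Data frame `strip_id, crop, height_m, n_pixels`.
#' @export
scene_strip_heights <- function(dsm, reference, ortho, strips,
                                exg_threshold = NULL,
                                height_threshold = NULL) {
  index <- exg(ortho$r, ortho$g, ortho$b)
  if (is.null(exg_threshold)) exg_threshold <- bimodal_threshold(index)
  veg_mask <- index > exg_threshold
  heights <- chm(dsm, reference)
  out <- strips
  out$height_m <- NA_real_
  out$n_pixels <- NA_integer_
  for (k in seq_len(nrow(strips))) {
    cols <- strips$col_start[k]:strips$col_end[k]
    vals <- unclass(heights)[, cols][veg_mask[, cols]]
    if (!is.null(height_threshold)) {
      split <- separate_species(vals, height_threshold)
      vals <- split[[strips$crop[k]]]
    }
    out$height_m[k] <- strip_height(vals, strips$crop[k])
    out$n_pixels[k] <- length(vals)
  }
  out
}
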