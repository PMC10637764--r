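# Input-sensitivity sweeps: mean daily strip shading proportion as one
# input varies while everything else is held fixed. Shading proportion
# does not involve measured radiation, so the sweeps need no weather.

# SP_strip for one day given a precomputed solar track.
.sp_strip_day <- function(ctx, track, geom, h_north, h_south, direction) {
  sp <- vapply(seq_len(nrow(geom)), function(i) {
    iv <- daily_intervals(ctx, geom$d_north_source[i],
                          geom$d_south_source[i], h_north, h_south,
                          direction, track = track,
                          step_minutes = track$step_hours[1] * 60)
    shading_proportion(iv, ctx)
  }, numeric(1))
  aggregate_strip(sp, geom$width)
}

# Mean over days of SP_strip; tracks may be supplied to reuse solar paths.
.mean_sp_strip <- function(layout, hms, direction, latitude,
                           step_minutes, tracks = NULL) {
  geom <- row_distances(layout)
  doy <- as.integer(strftime(as.Date(hms$date), "%j"))
  vals <- vapply(seq_len(nrow(hms)), function(k) {
    ctx <- day_context(doy[k], latitude)
    track <- if (is.null(tracks)) solar_track(ctx, step_minutes)
             else tracks[[k]]
    .sp_strip_day(ctx, track, geom, hms$h_north[k], hms$h_south[k],
                  direction)
  }, numeric(1))
  mean(vals)
}

#' Sensitivity of strip shading proportion to one model input
#'
#' Recomputes the mean daily strip shading proportion over a period for
#' every value of a grid over one input -- canopy height difference,
#' planting direction, or latitude -- holding the other inputs fixed. The
#' same growth series is reused at every latitude (crop growth assumed
#' consistent across sites); all solar geometry is recomputed per latitude.
#'
#' @param variable One of `"height_difference"`, `"direction"`,
#'   `"latitude"`.
#' @param grid Numeric grid of values: metres for height difference,
#'   degrees for direction (0--180) or latitude.
#' @param layout A [strip_layout()]; supplies the direction and latitude
#'   not being swept.
#' @param hms Daily height-difference series `date, h_north, h_south`
#'   (required for the direction and latitude sweeps; for the
#'   height-difference sweep it supplies the dates and is overridden by
#'   each grid value on both sides).
#' @param dates For the height-difference sweep only, an alternative to
#'   `hms`: the period's dates.
#' @param step_minutes Time-scan resolution (minutes). Default 1.
#' @return Data frame `variable, value, SP_strip, flagged`; `flagged` marks
#'   grid points where solar geometry was undefined on some day (polar
#'   day/night), whose `SP_strip` is `NA` rather than silently dropped.
#' @export
sweep_shading <- function(variable = c("height_difference", "direction",
                                       "latitude"),
                          grid, layout, hms = NULL, dates = NULL,
                          step_minutes = 1) {
  variable <- match.arg(variable)
  stopifnot(inherits(layout, "strip_layout"), length(grid) >= 1)
  if (variable == "height_difference") {
    if (is.null(dates)) {
      if (is.null(hms)) stop("supply `hms` or `dates`", call. = FALSE)
      dates <- as.Date(hms$date)
    }
    base <- data.frame(date = as.Date(dates))
  } else if (is.null(hms)) {
    stop("`hms` is required for the ", variable, " sweep", call. = FALSE)
  }
  if (variable == "direction" &&
      (any(grid < 0) || any(grid > 180))) {
    stop("direction grid must lie in [0, 180] degrees", call. = FALSE)
  }

  eval_point <- function(value) {
    switch(variable,
      height_difference = {
        h <- base
        h$h_north <- value
        h$h_south <- value
        .mean_sp_strip(layout, h, layout$planting_direction,
                       layout$latitude, step_minutes)
      },
      direction = .mean_sp_strip(layout, hms, value, layout$latitude,
                                 step_minutes, tracks = .direction_tracks),
      latitude = .mean_sp_strip(layout, hms, layout$planting_direction,
                                value, step_minutes)
    )
  }

  # the solar path is identical for every direction grid point: cache it
  .direction_tracks <- NULL
  if (variable == "direction") {
    doy <- as.integer(strftime(as.Date(hms$date), "%j"))
    .direction_tracks <- lapply(doy, function(n) {
      solar_track(day_context(n, layout$latitude), step_minutes)
    })
  }

  vals <- lapply(grid, function(v) {
    tryCatch(list(sp = eval_point(v), flagged = FALSE),
             error = function(e) list(sp = NA_real_, flagged = TRUE))
  })
  data.frame(
    variable = variable,
    value = grid,
    SP_strip = vapply(vals, `[[`, numeric(1), "sp"),
    flagged = vapply(vals, `[[`, logical(1), "flagged")
  )
}
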