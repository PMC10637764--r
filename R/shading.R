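#' Signed shading distance of a maize strip at one instant
#'
#' Horizontal reach of the shadow cast by the height difference `h_ms`
#' across the inter-row axis, for sun elevation `alpha`, azimuth `beta` and
#' planting direction `gamma`:
#' `Ds = h_ms / tan(alpha) * cos(beta + gamma - 90)`.
#' Positive values mean the shadow falls southward (the soybean strip is
#' shaded by its northern adjacent maize strip); negative values mean
#' shading from the southern strip. With north-south rows (`gamma = 0`) and
#' the sun due south (`beta = 180`), the cosine vanishes: the shadow runs
#' along the row axis and reaches no other row.
#'
#' @param h_ms Canopy height difference (m), >= 0.
#' @param elevation Solar elevation (degrees); values <= 0 yield `NA`
#'   (no defined daytime shadow).
#' @param azimuth Solar azimuth (degrees, clockwise from north).
#' @param direction Planting direction `gamma` (degrees CCW from north).
#' @return Signed shadow reach in metres.
#' @export
shading_distance <- function(h_ms, elevation, azimuth, direction) {
  if (any(h_ms < 0)) stop("`h_ms` must be >= 0", call. = FALSE)
  ds <- h_ms / tan(.deg2rad(elevation)) *
    cos(.deg2rad(azimuth + direction - 90))
  ds[elevation <= 0] <- NA_real_
  ds
}

#' Solar track over one day at the model's working time step
#'
#' Solar position sampled at the midpoints of `step_minutes` bins spanning
#' daylight. Sweeps precompute this once per day and reuse it across
#' layout variants, since the track depends only on date, latitude and
#' step.
#'
#' @param ctx A [day_context()].
#' @param step_minutes Bin width in minutes.
#' @return A [solar_position()] data frame with an extra `step_hours`
#'   column.
#' @export
solar_track <- function(ctx, step_minutes = 1) {
  stopifnot(inherits(ctx, "day_context"))
  step_h <- step_minutes / 60
  n <- max(1L, floor((ctx$sunset_lst - ctx$sunrise_lst) / step_h))
  lst <- ctx$sunrise_lst + (seq_len(n) - 0.5) * step_h
  pos <- solar_position(ctx, lst)
  pos$step_hours <- step_h
  pos
}

#' Daily shading intervals for one soybean row
#'
#' Scans local solar time from sunrise to sunset in `step_minutes` bins.
#' At each step the cross-row shadow displacement per metre of height
#' difference, `cos(beta + gamma - 90) / tan(alpha)`, decides which maize
#' strip is the shading source (southward shadow: northern strip;
#' northward: southern strip); the source side's height difference and
#' origin distance are then applied, and the step is shaded iff
#' `|Ds| > d_mr` for that source. Contiguous shaded steps merge into
#' intervals whose endpoints are the outer bin edges (clipped to daylight),
#' so cumulative shading time is exactly the number of shaded steps times
#' the step length.
#'
#' @param ctx A [day_context()].
#' @param d_north,d_south Row distances to the north-source / south-source
#'   origin (m).
#' @param h_north,h_south Height differences to the northern / southern
#'   adjacent maize strip (m).
#' @param direction Planting direction (degrees CCW from north).
#' @param step_minutes Scan resolution (minutes), default 1.
#' @param track Optional precomputed [solar_track()] for `ctx` and
#'   `step_minutes` (used by sweeps to avoid recomputing the solar path).
#' @return Data frame of intervals: `start`, `end` (LST hours), `source`
#'   (`"north"` or `"south"`), plus attribute `shading_time` (hours).
#' @export
daily_intervals <- function(ctx, d_north, d_south, h_north, h_south,
                            direction, step_minutes = 1, track = NULL) {
  stopifnot(h_north >= 0, h_south >= 0, d_north >= 0, d_south >= 0)
  if (is.null(track)) track <- solar_track(ctx, step_minutes)
  # displacement per metre of height difference; sign picks the source
  disp <- cos(.deg2rad(track$azimuth + direction - 90)) /
    tan(.deg2rad(track$elevation))
  from_north <- disp > 0 & h_north * disp > d_north
  from_south <- disp < 0 & h_south * (-disp) > d_south
  shaded <- from_north | from_south
  source <- ifelse(from_north, "north", ifelse(from_south, "south", NA))

  step_h <- track$step_hours[1]
  runs <- rle(paste0(shaded, ".", source))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- grepl("^TRUE", runs$values)
  out <- data.frame(
    start = pmax(ctx$sunrise_lst, track$lst[starts[keep]] - step_h / 2),
    end = pmin(ctx$sunset_lst, track$lst[ends[keep]] + step_h / 2),
    source = sub("^TRUE\\.", "", runs$values[keep]),
    stringsAsFactors = FALSE
  )
  attr(out, "shading_time") <- sum(shaded) * step_h
  out
}

#' Daily shading proportion from shaded intervals
#'
#' Fraction of the day's direct-beam energy proxy falling inside the shaded
#' intervals. Instantaneous intensity is taken proportional to
#' `sin(alpha)`, so the energy within an interval is the integral of
#' `sin(alpha) d(alpha)` along the solar-elevation branches. The full-day
#' denominator is `2 * (1 - cos(alpha_max))`: elevation rises from 0 at
#' sunrise to `alpha_max` at solar noon and falls back to 0. An interval
#' lying wholly on one monotone branch contributes
#' `|cos(alpha(t1)) - cos(alpha(t2))|`; one spanning solar noon contributes
#' `(cos(alpha(t1)) - cos(alpha_max)) + (cos(alpha(t2)) - cos(alpha_max))`.
#' Disjoint intervals sum; the result is clamped to `[0, 1]`.
#'
#' @param intervals Data frame with `start` and `end` in LST hours (e.g.
#'   from [daily_intervals()]); may be empty.
#' @param ctx A [day_context()].
#' @return Shading proportion in `[0, 1]`.
#' @export
shading_proportion <- function(intervals, ctx) {
  stopifnot(inherits(ctx, "day_context"))
  if (NROW(intervals) == 0) return(0)
  iv <- intervals[order(intervals$start), , drop = FALSE]
  if (any(iv$end < iv$start) ||
      (NROW(iv) > 1 && any(iv$start[-1] < iv$end[-NROW(iv)] - 1e-12))) {
    stop("intervals must be non-degenerate and pairwise disjoint",
         call. = FALSE)
  }
  if (any(iv$start < ctx$sunrise_lst - 1e-9) ||
      any(iv$end > ctx$sunset_lst + 1e-9)) {
    stop("intervals must lie within daylight", call. = FALSE)
  }
  elev_at <- function(t) {
    solar_elevation(ctx$declination, ctx$latitude, hour_angle(t))
  }
  cos_amax <- cos(.deg2rad(ctx$max_elevation))
  contrib <- function(t1, t2) {
    c1 <- cos(.deg2rad(elev_at(t1)))
    c2 <- cos(.deg2rad(elev_at(t2)))
    if (t2 <= 12 || t1 >= 12) {        # single monotone branch
      abs(c1 - c2)
    } else {                            # spans solar noon
      (c1 - cos_amax) + (c2 - cos_amax)
    }
  }
  num <- sum(mapply(contrib, iv$start, iv$end))
  den <- 2 * (1 - cos_amax)
  min(1, max(0, num / den))
}

#' Daily shading capacity
#'
#' Direct radiation blocked on a row in one day: the product of the day's
#' direct radiation and the row's shading proportion.
#'
#' @param sp Shading proportion in `[0, 1]`.
#' @param ra Direct radiation (MJ m^-2 day^-1), >= 0.
#' @return Shading capacity in MJ m^-2.
#' @export
shading_capacity <- function(sp, ra) {
  if (any(sp < 0 | sp > 1, na.rm = TRUE)) {
    stop("`sp` must be in [0, 1]", call. = FALSE)
  }
  if (any(ra < 0, na.rm = TRUE)) stop("`ra` must be >= 0", call. = FALSE)
  sp * ra
}

#' Width-weighted strip aggregate of per-row values
#'
#' @param values Per-row values (e.g. SP or SC).
#' @param widths Row widths (m), same length, > 0.
#' @return Weighted mean.
#' @export
aggregate_strip <- function(values, widths) {
  if (length(values) != length(widths)) {
    stop("`values` and `widths` must have the same length", call. = FALSE)
  }
  if (any(widths <= 0)) stop("`widths` must be > 0", call. = FALSE)
  sum(values * widths) / sum(widths)
}

#' Simulate per-row daily shading over a period
#'
#' Runs the full shading-capacity model: for each day, builds the solar
#' context, partitions measured global radiation into direct and diffuse,
#' scans the shadow of both adjacent maize strips across every soybean row,
#' and converts shaded intervals into shading proportion and capacity.
#'
#' @param layout A [strip_layout()].
#' @param weather Data frame `date, Rg, S` covering the simulated period
#'   (see [read_weather()]).
#' @param hms Data frame `date, h_north, h_south`: daily canopy height
#'   differences (m) to the northern and southern adjacent maize strip
#'   (see [height_difference()] for the UAV-derived route).
#' @param step_minutes Time-scan resolution in minutes (default 1).
#' @return List of class `shading_simulation`:
#'   \describe{
#'     \item{rows}{per-row per-day data frame `date, row, shading_time_h,
#'       SP, SC`}
#'     \item{strips}{per-day strip aggregates `date, SP_strip, SC_strip`}
#'     \item{summary}{per-row cumulative shading capacity `row, CSC` plus
#'       attribute `overall_csc`}
#'   }
#' @export
simulate_shading <- function(layout, weather, hms, step_minutes = 1) {
  stopifnot(inherits(layout, "strip_layout"))
  req <- c("date", "h_north", "h_south")
  if (!all(req %in% names(hms))) {
    stop("`hms` needs columns date, h_north, h_south", call. = FALSE)
  }
  dates <- sort(unique(as.Date(weather$date)))
  missing_hms <- setdiff(as.character(dates), as.character(hms$date))
  if (length(missing_hms)) {
    stop("no height difference for date(s): ",
         paste(missing_hms, collapse = ", "), call. = FALSE)
  }
  gaps <- diff(dates)
  if (length(gaps) && any(gaps != 1)) {
    stop("weather series has gaps at: ",
         paste(dates[which(gaps != 1)] + 1, collapse = ", "), call. = FALSE)
  }
  rad <- partition_radiation(weather[order(as.Date(weather$date)), ],
                             layout$latitude)
  geom <- row_distances(layout)
  hms_idx <- match(as.character(dates), as.character(hms$date))

  rows_list <- vector("list", length(dates))
  strips_list <- vector("list", length(dates))
  for (k in seq_along(dates)) {
    ctx <- day_context(rad$doy[k], layout$latitude)
    track <- solar_track(ctx, step_minutes)
    hn <- hms$h_north[hms_idx[k]]
    hs <- hms$h_south[hms_idx[k]]
    sp <- numeric(nrow(geom))
    st <- numeric(nrow(geom))
    for (i in seq_len(nrow(geom))) {
      iv <- daily_intervals(ctx, geom$d_north_source[i],
                            geom$d_south_source[i], hn, hs,
                            layout$planting_direction,
                            step_minutes, track = track)
      sp[i] <- shading_proportion(iv, ctx)
      st[i] <- attr(iv, "shading_time")
    }
    sc <- shading_capacity(sp, rad$Ra[k])
    rows_list[[k]] <- data.frame(date = dates[k], row = geom$row,
                                 shading_time_h = st, SP = sp, SC = sc)
    strips_list[[k]] <- data.frame(
      date = dates[k],
      SP_strip = aggregate_strip(sp, geom$width),
      SC_strip = aggregate_strip(sc, geom$width)
    )
  }
  rows <- do.call(rbind, rows_list)
  strips <- do.call(rbind, strips_list)
  csc <- tapply(rows$SC, rows$row, sum)
  summary <- data.frame(row = as.integer(names(csc)), CSC = as.numeric(csc))
  attr(summary, "overall_csc") <- sum(strips$SC_strip)
  structure(list(rows = rows, strips = strips, summary = summary),
            class = "shading_simulation")
}

#' @export
print.shading_simulation <- function(x, ...) {
  cat(sprintf("<shading_simulation> %d day(s), %d row(s)\n",
              length(unique(x$rows$date)), max(x$rows$row)))
  cat("Per-row cumulative shading capacity (MJ m^-2):\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("Overall strip CSC: %.2f MJ m^-2\n",
              attr(x$summary, "overall_csc")))
  invisible(x)
}
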