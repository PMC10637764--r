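# Synthetic inputs for exercising every pipeline stage without field data:
# surface-raster scenes with known block heights, seeded weather series,
# and logistic growth curves sampled at the measurement dates.

#' Synthetic field scene: reference ground, crop DSM, ortho bands
#'
#' Builds a strip-intercropping scene as co-registered rasters. The
#' reference ground is flat (plus noise); the crop surface raster adds
#' rectangular strip blocks at the true canopy heights; the ortho-mosaic
#' bands colour vegetation green-dominant and soil brown so that
#' excess-green masking is exercised. Strips run as vertical bands
#' (columns) across the scene; matrix row 1 is the north edge. The
#' emitted truth table and label matrix allow pixel-exact validation.
#'
#' @param layout A [strip_layout()]; strip widths in pixels follow
#'   `row_spacing`, `strip_distance` and the row counts.
#' @param maize_height,soybean_height True block heights (m).
#' @param noise_sd Surface noise standard deviation (m). Noise is bounded
#'   (uniform), emulating photogrammetric residuals after ground-control
#'   correction, so extreme height percentiles stay within a few
#'   `noise_sd` of the truth; the bare-ground reference flight carries a
#'   tenth of this noise.
#' @param pixel_size Pixel edge (m); default 0.05 keeps scenes small while
#'   leaving hundreds of pixels per strip.
#' @param n_rows_px Number of raster rows (along-strip extent in pixels).
#' @param seed Integer seed; the same seed reproduces the scene exactly.
#' @return List with elements `reference`, `dsm` ([raster_grid()]s),
#'   `ortho` (list of `r`, `g`, `b` matrices), `strips` (data frame
#'   `strip_id, crop, col_start, col_end`), `truth` (data frame
#'   `strip_id, crop, height`), and `labels` (character matrix,
#'   `"soil"`/`"vegetation"`).
#' @export
make_scene <- function(layout, maize_height = 1.8, soybean_height = 0.7,
                       noise_sd = 0.02, pixel_size = 0.05,
                       n_rows_px = 40, seed = 1) {
  stopifnot(inherits(layout, "strip_layout"),
            maize_height > 0, soybean_height > 0, noise_sd >= 0)
  px <- function(metres) max(1L, as.integer(round(metres / pixel_size)))
  maize_w <- px(layout$n_maize_rows * layout$row_spacing)
  soy_w <- px(layout$n_soybean_rows * layout$row_spacing)
  gap_w <- px(layout$strip_distance)
  margin <- px(0.5)
  # south-to-north unit: maize, gap, soybean, gap, maize
  widths <- c(margin, maize_w, gap_w, soy_w, gap_w, maize_w, margin)
  kinds <- c("soil", "maize", "soil", "soybean", "soil", "maize", "soil")
  ncols <- sum(widths)
  if (ncols < 4 || n_rows_px < 4) stop("degenerate scene layout",
                                       call. = FALSE)
  set.seed(seed)
  # bounded (uniform) surface noise with standard deviation `noise_sd`;
  # the pre-emergence bare-ground reference reconstructs an order of
  # magnitude more accurately than vegetated surfaces
  half_range <- sqrt(3) * noise_sd
  unif_noise <- function(a) {
    matrix(stats::runif(n_rows_px * ncols, -a, a), n_rows_px, ncols)
  }
  reference <- unif_noise(half_range / 10)
  heights <- c(soil = 0, maize = maize_height, soybean = soybean_height)
  col_kind <- rep(kinds, widths)
  block <- matrix(heights[col_kind], n_rows_px, ncols, byrow = TRUE)
  dsm <- block + unif_noise(half_range)
  veg <- matrix(col_kind != "soil", n_rows_px, ncols, byrow = TRUE)
  dn_noise <- function() matrix(stats::rnorm(n_rows_px * ncols, 0, 5),
                                n_rows_px, ncols)
  clip_dn <- function(x) {
    x <- round(x)
    x[x < 0] <- 0
    x[x > 255] <- 255
    x
  }
  ortho <- list(
    r = clip_dn(ifelse(veg, 60, 120) + dn_noise()),
    g = clip_dn(ifelse(veg, 170, 100) + dn_noise()),
    b = clip_dn(ifelse(veg, 60, 70) + dn_noise())
  )
  edges <- cumsum(widths)
  starts <- edges - widths + 1
  strip_rows <- which(kinds %in% c("maize", "soybean"))
  strips <- data.frame(
    strip_id = paste0(ifelse(kinds[strip_rows] == "maize", "M", "S"),
                      seq_along(strip_rows)),
    crop = kinds[strip_rows],
    col_start = starts[strip_rows],
    col_end = edges[strip_rows],
    stringsAsFactors = FALSE
  )
  truth <- data.frame(strip_id = strips$strip_id, crop = strips$crop,
                      height = unname(heights[strips$crop]),
                      stringsAsFactors = FALSE)
  labels <- matrix(ifelse(veg, "vegetation", "soil"), n_rows_px, ncols)
  list(reference = raster_grid(reference, pixel_size),
       dsm = raster_grid(dsm, pixel_size),
       ortho = ortho, strips = strips, truth = truth, labels = labels)
}

#' Synthetic daily weather series
#'
#' Draws daily global radiation as a uniform fraction (0.30--0.75) of the
#' date's extraterrestrial radiation and sunshine duration as a uniform
#' fraction (0.25--0.95) of the astronomical day length, which spans
#' overcast to clear days at the site.
#'
#' @param start_date First date (`Date` or ISO string).
#' @param n_days Number of consecutive days, >= 1.
#' @param latitude Site latitude (decimal degrees).
#' @param seed Integer seed.
#' @return Data frame `date, Rg, S` suitable for [partition_radiation()].
#' @export
make_weather <- function(start_date, n_days, latitude = 43.267, seed = 1) {
  stopifnot(n_days >= 1)
  dates <- seq(as.Date(start_date), by = "day", length.out = n_days)
  doy <- as.integer(strftime(dates, "%j"))
  set.seed(seed)
  r0 <- vapply(doy, extraterrestrial_radiation, numeric(1),
               latitude = latitude)
  s0 <- vapply(doy, function(n) day_context(n, latitude)$max_sunshine_duration,
               numeric(1))
  data.frame(
    date = dates,
    Rg = stats::runif(n_days, 0.30, 0.75) * r0,
    S = stats::runif(n_days, 0.25, 0.95) * s0
  )
}

#' Logistic growth curves sampled at the measurement dates
#'
#' Emulates UAV measurement campaigns: canopy heights of the two adjacent
#' maize strips and the soybean strip follow logistic curves
#' `K / (1 + exp(-rate * (das - inflection)))` sampled at the measurement
#' days after sowing. The default parameters give a maize--soybean height
#' difference rising steeply early, then slowing -- the shape observed
#' over the vegetative window in this system. A small offset between the
#' north and south maize strips emulates microclimate asymmetry.
#'
#' @param measurement_das Days after sowing of the campaigns (default the
#'   four vegetative-stage campaigns at 41, 48, 56 and 64 DAS).
#' @param maize,soybean Named lists `list(K=, rate=, inflection=)`:
#'   asymptote (m), growth rate (1/day) and inflection DAS.
#' @param north_south_offset Height offset (m) added to the northern and
#'   subtracted from the southern maize strip, halved each side.
#' @param noise_sd Measurement noise standard deviation (m).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Data frame `das, maize_north, maize_south, soybean` (m).
#' @export
make_growth <- function(measurement_das = c(41, 48, 56, 64),
                        maize = list(K = 2.6, rate = 0.15, inflection = 44),
                        soybean = list(K = 0.95, rate = 0.18,
                                       inflection = 45),
                        north_south_offset = 0.01, noise_sd = 0, seed = 1) {
  logistic <- function(p, t) p$K / (1 + exp(-p$rate * (t - p$inflection)))
  mz <- logistic(maize, measurement_das)
  sb <- logistic(soybean, measurement_das)
  out <- data.frame(
    das = measurement_das,
    maize_north = mz + north_south_offset / 2,
    maize_south = mz - north_south_offset / 2,
    soybean = sb
  )
  if (noise_sd > 0) {
    set.seed(seed)
    for (col in c("maize_north", "maize_south", "soybean")) {
      out[[col]] <- out[[col]] + stats::rnorm(nrow(out), 0, noise_sd)
    }
  }
  out
}

#' Daily height-difference series from a growth-curve fixture
#'
#' Convenience chain: spline-interpolates the sampled growth curves to
#' daily resolution and subtracts soybean from each maize side.
#'
#' @param growth Data frame from [make_growth()].
#' @param sowing_date Sowing date (`Date` or ISO string) anchoring DAS to
#'   calendar dates.
#' @return Data frame `date, h_north, h_south` for [simulate_shading()].
#' @export
growth_hms_series <- function(growth, sowing_date) {
  dates <- as.Date(sowing_date) + growth$das
  mn <- interpolate_daily(dates, growth$maize_north)
  ms <- interpolate_daily(dates, growth$maize_south)
  sb <- interpolate_daily(dates, growth$soybean)
  height_difference(mn, ms, sb)
}

#' Write a synthetic scene to disk
#'
#' Serialises a [make_scene()] result: ASCII-grid rasters for the
#' reference ground, crop surface and the three ortho bands, a JSON strip
#' table, and a CSV truth table. These files feed the raster route of
#' [run_pipeline()].
#'
#' @param scene A [make_scene()] result.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix, default `"scene"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- attr(scene$dsm, "pixel_size")
  p <- function(name) file.path(dir, paste0(prefix, "_", name))
  paths <- c(reference = p("reference.asc"), dsm = p("dsm.asc"),
             r = p("ortho_r.asc"), g = p("ortho_g.asc"),
             b = p("ortho_b.asc"), strips = p("strips.json"),
             truth = p("truth.csv"))
  write_ascii_grid(scene$reference, paths["reference"])
  write_ascii_grid(scene$dsm, paths["dsm"])
  write_ascii_grid(raster_grid(scene$ortho$r, ps), paths["r"])
  write_ascii_grid(raster_grid(scene$ortho$g, ps), paths["g"])
  write_ascii_grid(raster_grid(scene$ortho$b, ps), paths["b"])
  jsonlite::write_json(scene$strips, paths["strips"])
  utils::write.csv(scene$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
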