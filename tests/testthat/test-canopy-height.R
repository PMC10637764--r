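test_that("excess green index is the per-pixel band combination", {
  expect_equal(exg(0, 255, 0), 510)
  expect_equal(exg(100, 100, 100), 0)   # grey is index-neutral
  expect_equal(exg(120, 80, 60), -20)
  m <- matrix(1:6, 2, 3)
  expect_equal(exg(m, m, m), matrix(0, 2, 3))
  expect_error(exg(matrix(1, 2, 3), matrix(1, 3, 2), matrix(1, 2, 3)),
               "shape")
  expect_error(exg(-1, 0, 0), ">= 0")
})

test_that("bimodal threshold lands in the valley between two modes", {
  set.seed(42)
  vals <- c(rnorm(3000, -50, 15), rnorm(3000, 200, 30))
  thr <- bimodal_threshold(vals)
  expect_gt(thr, -20)
  expect_lt(thr, 170)
  # oracle: dense scan of the same smoothed density for its interior minimum
  d <- density(vals, n = 4096)
  sel <- d$x > -50 & d$x < 200
  oracle <- d$x[sel][which.min(d$y[sel])]
  expect_lt(abs(thr - oracle), diff(range(vals)) / 100)
  expect_error(bimodal_threshold(rep(1, 100)), "threshold")
  expect_error(bimodal_threshold(rnorm(500)), "unimodal")
})

test_that("canopy height model is the clipped surface difference", {
  ref <- raster_grid(matrix(0, 5, 5), 0.05)
  expect_equal(unclass(chm(ref, ref)), matrix(0, 5, 5),
               ignore_attr = "pixel_size")
  dsm <- raster_grid(matrix(1.2, 5, 5), 0.05)
  expect_equal(unclass(chm(dsm, ref)), matrix(1.2, 5, 5),
               ignore_attr = "pixel_size")
  # below-ground photogrammetric noise clips to zero
  low <- raster_grid(matrix(-0.3, 5, 5), 0.05)
  expect_true(all(unclass(chm(low, ref)) == 0))
  expect_error(chm(raster_grid(matrix(0, 4, 5), 0.05), ref), "shape")
  expect_error(chm(raster_grid(matrix(0, 5, 5), 0.1), ref), "pixel")
})

test_that("species split by height threshold partitions the pixels", {
  s <- separate_species(c(0.6, 0.8, 1.4, 1.6), 1.00)
  expect_equal(s$soybean, c(0.6, 0.8))
  expect_equal(s$maize, c(1.4, 1.6))
  # stage-specific manual thresholds are accepted as-is
  for (thr in c(0.46, 0.78, 1.00, 1.33)) {
    s <- separate_species(c(0.3, 0.45, 1.5, 2.0), thr)
    expect_equal(length(s$maize) + length(s$soybean), 4L)
  }
  expect_warning(separate_species(c(0.1, 0.2), 1.0), "empty class")
})

test_that("strip height is the crop-specific percentile", {
  expect_equal(strip_height(rep(1.5, 50), "maize"), 1.5)
  expect_equal(strip_height(rep(1.5, 50), "soybean"), 1.5)
  # 1001-point uniform grid on [0, 1]: the 90th percentile is 0.90 exactly
  expect_equal(strip_height(seq(0, 1, length.out = 1001), "soybean"), 0.9)
  expect_error(strip_height(numeric(0), "maize"), "no pixels")
  # monotonicity: adding a taller pixel never lowers the strip height
  v <- runif(500, 0, 2)
  expect_gte(strip_height(c(v, 3), "maize"), strip_height(v, "maize"))
  expect_gte(strip_height(c(v, 3), "soybean"), strip_height(v, "soybean"))
})

test_that("maize percentile on a noisy block respects order statistics", {
  set.seed(7)
  block <- rnorm(4000, 1.8, 0.02)
  h <- strip_height(block, "maize")
  # 99.9th percentile of N(1.8, 0.02): above the mean, below mean + 4 sd
  expect_gte(h, 1.80)
  expect_lte(h, 1.88)
})

test_that("daily interpolation is an exact natural spline", {
  dates <- as.Date("2021-07-05") + c(0, 7, 15, 23)
  # collinear points: the natural spline is the straight line
  lin <- interpolate_daily(dates, as.numeric(dates - dates[1]) * 0.05)
  expect_equal(lin$height,
               as.numeric(lin$date - dates[1]) * 0.05, tolerance = 1e-9)
  # passes exactly through measurements
  h <- c(0.4, 0.9, 1.1, 1.4)
  daily <- interpolate_daily(dates, h)
  expect_equal(daily$height[daily$date %in% dates], h)
  expect_equal(nrow(daily), 24L)
  expect_error(interpolate_daily(dates, h,
                                 out_dates = max(dates) + 1), "extrapolate")
  expect_error(interpolate_daily(dates[1:2], h[1:2]), "at least 3")
})

test_that("natural spline recovers a generating curve between knots", {
  # natural spline on 4 knots of a smooth curve stays close mid-interval
  x <- as.Date("2021-07-05") + c(0, 8, 16, 23)
  f <- function(t) 0.5 + 0.05 * t - 5e-4 * t^2
  daily <- interpolate_daily(x, f(as.numeric(x - x[1])))
  t <- as.numeric(daily$date - x[1])
  expect_lt(max(abs(daily$height - f(t))), 0.005)
})

test_that("height differences are side-specific and clipped at zero", {
  d <- data.frame(date = as.Date("2021-07-05") + 0:2)
  mk <- function(h) data.frame(date = d$date, height = h)
  out <- height_difference(mk(c(1.9, 2.0, 2.1)), mk(c(1.85, 1.95, 2.05)),
                           mk(c(0.8, 0.8, 0.8)))
  expect_equal(out$h_north, c(1.1, 1.2, 1.3))
  expect_equal(out$h_south, c(1.05, 1.15, 1.25))
  expect_warning(
    z <- height_difference(mk(c(0.5, 0.5, 0.5)), mk(c(0.5, 0.5, 0.5)),
                           mk(c(0.8, 0.8, 0.8))),
    "clipped")
  expect_true(all(z$h_north == 0))
  expect_error(height_difference(mk(1:3), mk(1:3),
                                 data.frame(date = d$date + 1,
                                            height = 1:3)),
               "identical dates")
})

test_that("agreement statistics match hand arithmetic", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1.1, 2.1, 3.1), c(1, 2, 3)), 0.1)
  # frozen hand computation for {(1,1.1),(2,1.9),(3,3.2)}
  expect_equal(r_squared(c(1.1, 1.9, 3.2), c(1, 2, 3)), 1.13,
               tolerance = 1e-9)
  expect_equal(rmse(c(1.1, 1.9, 3.2), c(1, 2, 3)), 0.1414214,
               tolerance = 1e-6)
  expect_error(r_squared(c(1, 2), c(1, 1)), "zero variance")
})

test_that("the canopy stage recovers a noiseless scene exactly", {
  scene <- make_scene(fixture_layout(), noise_sd = 0, seed = 3)
  h <- scene_strip_heights(scene$dsm, scene$reference, scene$ortho,
                           scene$strips)
  expect_equal(h$height_m, scene$truth$height, tolerance = 1e-9)
})

test_that("the canopy stage recovers strip heights and the mask under noise", {
  scene <- make_scene(fixture_layout(), maize_height = 1.8,
                      soybean_height = 0.7, noise_sd = 0.02, seed = 5)
  # excess-green mask against the ground-truth labels
  index <- exg(scene$ortho$r, scene$ortho$g, scene$ortho$b)
  thr <- bimodal_threshold(index)
  pred <- ifelse(index > thr, "vegetation", "soil")
  expect_gte(mean(pred == scene$labels), 0.99)
  # strip heights within 2 sigma of the generator truth
  h <- scene_strip_heights(scene$dsm, scene$reference, scene$ortho,
                           scene$strips)
  expect_true(all(abs(h$height_m - scene$truth$height) <= 0.04))
  # species split at the height-histogram valley classifies strip pixels
  heights <- unclass(chm(scene$dsm, scene$reference))
  split_thr <- bimodal_threshold(heights[index > thr])
  expect_gt(split_thr, 0.7)
  expect_lt(split_thr, 1.8)
  correct <- 0; total <- 0
  for (k in seq_len(nrow(scene$strips))) {
    cols <- scene$strips$col_start[k]:scene$strips$col_end[k]
    px <- heights[, cols]
    pred <- ifelse(px > split_thr, "maize", "soybean")
    correct <- correct + sum(pred == scene$strips$crop[k])
    total <- total + length(px)
  }
  expect_gte(correct / total, 0.99)
})
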