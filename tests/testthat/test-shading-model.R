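test_that("shading distance reproduces end-member geometry", {
  expect_equal(shading_distance(0, 45, 120, 59), 0)
  # sun parallel to the rows: the cosine term vanishes
  expect_equal(shading_distance(1.5, 30, 180, 0), 0, tolerance = 1e-12)
  # unit case: 1 m height, 45 degree sun, shadow straight across the rows
  expect_equal(shading_distance(1, 45, 90, 0), 1, tolerance = 1e-12)
  # no defined shadow outside daylight
  expect_true(is.na(shading_distance(1, -5, 90, 90)))
  expect_error(shading_distance(-1, 45, 90, 90), ">= 0")
})

test_that("no height difference means no shading anywhere", {
  ctx <- day_context(186, 43.267)
  iv <- daily_intervals(ctx, 0.3, 1.5, 0, 0, direction = 59)
  expect_identical(nrow(iv), 0L)
  expect_equal(attr(iv, "shading_time"), 0)
})

test_that("a row at the origin is shaded almost all day", {
  ctx <- day_context(186, 43.267)
  iv <- daily_intervals(ctx, 1e-9, 1e-9, 1.2, 1.2, direction = 59)
  # shaded at every step except where the cosine term crosses zero
  expect_gt(attr(iv, "shading_time"),
            0.95 * ctx$max_sunshine_duration)
})

test_that("the border row sees northern-source shading before southern-source shading", {
  # mid-season 2M3S-0.6: R1 (southernmost) pattern
  ctx <- day_context(186, 43.267)
  iv <- daily_intervals(ctx, d_north = 1.5, d_south = 0.3,
                        h_north = 1.1, h_south = 1.1, direction = 59)
  expect_gt(nrow(iv), 1L)
  expect_true("north" %in% iv$source && "south" %in% iv$source)
  # shading starts from the northern strip in the morning; the southern
  # strip takes over after the shadow direction flips
  expect_identical(iv$source[1], "north")
  first_south <- min(iv$start[iv$source == "south"])
  expect_gt(first_south, iv$end[1])
})

test_that("interval endpoints converge to a 1-second scan", {
  ctx <- day_context(186, 43.267)
  coarse <- daily_intervals(ctx, 1.5, 0.3, 1.1, 1.1, direction = 59,
                            step_minutes = 1)
  fine <- daily_intervals(ctx, 1.5, 0.3, 1.1, 1.1, direction = 59,
                          step_minutes = 1 / 60)
  expect_identical(nrow(coarse), nrow(fine))
  expect_lt(max(abs(coarse$start - fine$start)), 2 / 60)
  expect_lt(max(abs(coarse$end - fine$end)), 2 / 60)
  expect_lt(abs(attr(coarse, "shading_time") -
                  attr(fine, "shading_time")), 0.05)
})

test_that("shading proportion handles the degenerate cases", {
  ctx <- day_context(186, 43.267)
  expect_equal(shading_proportion(data.frame(start = numeric(0),
                                             end = numeric(0)), ctx), 0)
  all_day <- data.frame(start = ctx$sunrise_lst, end = ctx$sunset_lst)
  expect_equal(shading_proportion(all_day, ctx), 1, tolerance = 1e-9)
  overlapping <- data.frame(start = c(8, 9), end = c(10, 11))
  expect_error(shading_proportion(overlapping, ctx), "disjoint")
  outside <- data.frame(start = 2, end = 3)
  expect_error(shading_proportion(outside, ctx), "daylight")
})

test_that("closed-form shading proportion matches the Riemann-sum oracle", {
  set.seed(101)
  for (rep in 1:40) {
    ctx <- day_context(sample(120:240, 1), 43.267)
    iv <- random_intervals(ctx)
    expect_lt(abs(shading_proportion(iv, ctx) - riemann_sp(iv, ctx)),
              1e-3)
  }
})

test_that("single-branch and noon-spanning intervals both integrate correctly", {
  ctx <- day_context(186, 43.267)
  # strictly pre-noon, strictly post-noon, and noon-spanning
  cases <- list(data.frame(start = 7, end = 10),
                data.frame(start = 14, end = 17),
                data.frame(start = 10.5, end = 14.5))
  for (iv in cases) {
    expect_lt(abs(shading_proportion(iv, ctx) - riemann_sp(iv, ctx)),
              1e-3)
  }
  # symmetric halves sum to the whole day
  am <- data.frame(start = ctx$sunrise_lst, end = 12)
  pm <- data.frame(start = 12, end = ctx$sunset_lst)
  expect_equal(shading_proportion(am, ctx) + shading_proportion(pm, ctx),
               1, tolerance = 1e-9)
})

test_that("shading capacity and strip aggregation are the stated products", {
  expect_equal(shading_capacity(0, 20), 0)
  expect_equal(shading_capacity(1, 17.5), 17.5)
  expect_equal(shading_capacity(0.5, 20), 10)
  expect_error(shading_capacity(1.2, 10), "0, 1")
  expect_error(shading_capacity(0.5, -1), ">= 0")
  expect_equal(aggregate_strip(c(0.5, 0.2, 0.3), rep(0.6, 3)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(aggregate_strip(0.7, 0.6), 0.7)
  expect_equal(aggregate_strip(c(0, 1), c(1, 3)), 0.75)
  expect_error(aggregate_strip(c(1, 2), 1), "length")
})

test_that("per-row shading proportion is monotone in the height difference", {
  lay <- fixture_layout()
  geom <- row_distances(lay)
  ctx <- day_context(186, lay$latitude)
  track <- solar_track(ctx, 1)
  for (i in seq_len(nrow(geom))) {
    sp <- vapply(seq(0, 3, by = 0.25), function(h) {
      iv <- daily_intervals(ctx, geom$d_north_source[i],
                            geom$d_south_source[i], h, h, 59,
                            track = track)
      shading_proportion(iv, ctx)
    }, numeric(1))
    expect_true(all(diff(sp) >= -1e-12))
  }
})

test_that("rows closer to both origins are shaded whenever farther rows are", {
  ctx <- day_context(186, 43.267)
  outer <- daily_intervals(ctx, 1.5, 0.9, 1.1, 1.1, 59)
  inner <- daily_intervals(ctx, 0.9, 0.3, 1.1, 1.1, 59)
  in_union <- function(t, iv) {
    any(t >= iv$start - 1e-9 & t <= iv$end + 1e-9)
  }
  probes <- unlist(Map(seq, outer$start, outer$end,
                       MoreArgs = list(by = 1 / 60)))
  expect_true(all(vapply(probes, in_union, logical(1), iv = inner)))
})

test_that("one simulated day accumulates to exactly that day's capacity", {
  lay <- fixture_layout()
  w <- make_weather("2021-07-15", 1, seed = 2)
  hms <- data.frame(date = as.Date("2021-07-15"), h_north = 1.1,
                    h_south = 1.1)
  sim <- simulate_shading(lay, w, hms)
  expect_equal(sim$summary$CSC, sim$rows$SC)
  expect_equal(attr(sim$summary, "overall_csc"), sim$strips$SC_strip)
})

test_that("a season with no height difference accumulates zero capacity", {
  lay <- fixture_layout()
  w <- make_weather("2021-07-05", 10, seed = 2)
  hms <- data.frame(date = w$date, h_north = 0, h_south = 0)
  sim <- simulate_shading(lay, w, hms)
  expect_true(all(sim$summary$CSC == 0))
  expect_true(all(sim$rows$SP == 0))
})

test_that("simulation rejects gaps and missing height differences", {
  lay <- fixture_layout()
  w <- make_weather("2021-07-05", 5, seed = 2)
  hms <- data.frame(date = w$date, h_north = 1, h_south = 1)
  expect_error(simulate_shading(lay, w[-3, ], hms), "gaps")
  expect_error(simulate_shading(lay, w, hms[-2, ]),
               "no height difference")
})
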