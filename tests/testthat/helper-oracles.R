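# Independent oracles used across tests. These deliberately avoid the
# package's closed-form code paths: the shading-proportion oracle is a
# fine-grained Riemann sum of sin(alpha) d(alpha) along the elevation
# branches, and the elevation it uses is recomputed from first principles.

# sin(alpha) d(alpha) integral ratio at `dt`-hour resolution (default 1 s)
riemann_sp <- function(intervals, ctx, dt = 1 / 3600) {
  t <- seq(ctx$sunrise_lst, ctx$sunset_lst, by = dt)
  d2r <- pi / 180
  sin_a <- sin(ctx$declination * d2r) * sin(ctx$latitude * d2r) +
    cos(ctx$declination * d2r) * cos(ctx$latitude * d2r) *
      cos((15 * (t - 12)) * d2r)
  a <- asin(pmin(1, pmax(-1, sin_a)))          # radians
  da <- abs(diff(a))
  mid_a <- (a[-1] + a[-length(a)]) / 2
  mid_t <- (t[-1] + t[-length(t)]) / 2
  w <- sin(mid_a) * da
  inside <- rep(FALSE, length(mid_t))
  for (k in seq_len(NROW(intervals))) {
    inside <- inside |
      (mid_t >= intervals$start[k] & mid_t <= intervals$end[k])
  }
  sum(w[inside]) / sum(w)
}

# random pairwise-disjoint daylight intervals for property-style tests
random_intervals <- function(ctx, max_n = 3) {
  n <- sample(max_n, 1)
  pts <- sort(runif(2 * n, ctx$sunrise_lst + 1e-6, ctx$sunset_lst - 1e-6))
  data.frame(start = pts[seq(1, 2 * n, 2)], end = pts[seq(2, 2 * n, 2)])
}

# small 2M3S layout used throughout; the field experiment's configuration
fixture_layout <- function(direction = 59, latitude = 43.267,
                           strip_distance = 0.6) {
  strip_layout("2M3S", 2, 3, row_spacing = 0.6,
               strip_distance = strip_distance,
               planting_direction = direction, latitude = latitude)
}

fixture_hms <- function() {
  growth_hms_series(make_growth(), "2021-05-25")
}
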