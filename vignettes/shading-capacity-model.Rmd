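---
title: "The shading capacity model for maize–soybean strip intercropping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The shading capacity model for maize–soybean strip intercropping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripshade)
```

## The problem

In a maize–soybean strip intercropping system the taller maize strips cast
shadows onto the adjacent soybean strips. The energy removed from a soybean
row by that shading — the *shading capacity* (SC, MJ m⁻² day⁻¹) and its
seasonal accumulation, the *cumulative shading capacity* (CSC, MJ m⁻²) —
drives inter-row differences in soybean growth and radiation use. `stripshade`
computes SC and CSC per soybean row from four ingredients:

1. **solar geometry** — declination, elevation and azimuth over the day;
2. **radiation partitioning** — splitting measured daily global radiation
   $R_g$ into its direct ($R_a$) and diffuse ($R_d$) components;
3. **row geometry** — how far each soybean row sits from the maize strips
   on either side;
4. **canopy height differences** $H_{ms}$ — how much taller the adjacent
   maize canopy is, derived from UAV surface rasters or supplied directly.

Only direct-beam shading is modelled: diffuse light does not produce a
defined shadow edge, and maize strips are treated as opaque cuboids (no
within-canopy transmission).

## Model structure

### Solar position

All public interfaces use degrees. For day-of-year $N$ and latitude
$\varphi$, the declination uses the 23.45°-amplitude sine approximation,
the hour angle is $\omega = 15°(\mathrm{LST} - 12)$ in local solar time,
and elevation $\alpha$ and azimuth $\beta$ follow the standard spherical
relations, with azimuth measured clockwise from north on a piecewise
arccos convention (morning branch below 180°, afternoon above). Arcsine
and arccosine arguments are clamped to $[-1, 1]$ with a $10^{-9}$
tolerance so sunrise and sunset do not produce spurious NaNs. At exactly
solar noon the azimuth takes the morning-branch limit (180° at
mid-latitude summer). No longitude or equation-of-time correction is
applied — the model works in local solar time throughout — but
`longitude_time_offset()` is available when inputs are recorded in zone
clock time. Atmospheric refraction and ephemeris-grade precision are out
of scope; the model targets daily energy bookkeeping, not astronomy.

### Radiation partitioning

Daily extraterrestrial radiation $R_0$ comes from the closed-form day
integral with solar constant $I_{sc} = 1367$ W m⁻²; the additive
sunrise-hour-angle term in the bracket is in radians, which is the one
spot where degree/radian mixing classically corrupts this formula, so the
conversion is made explicit in one place. The diffuse fraction
$R_d / R_g$ is an empirical quadratic in the clearness index $R_g/R_0$
and sunshine fraction $S/S_0$:

$$ R_d/R_g = 1.06 - 0.56\,k_t - 0.11\,k_t^2 - 0.26\,s - 1.6\,s^2 $$

clamped into $[0,1]$ because the regression can leave physical bounds at
the edges of its calibration range. Recorded sunshine durations slightly
above the astronomical maximum are clipped to $S_0$ with a warning rather
than rejected (sunshine recorders overshoot). The same coefficients are
applied at every latitude in the sensitivity sweeps; they were calibrated
for the north-east China site, and their transferability is an assumption
the sweeps inherit. Weather is assumed uniform within a day, so
$R_a = R_g - R_d$ holds exactly and conservation is asserted in the tests.

### Row geometry

Rows are indexed from the south (row 1 = southernmost). For shading by
the *northern* maize strip the coordinate origin is the midpoint between
the soybean strip and that northern strip, and symmetrically for the
southern strip, so each row carries two origin distances:

$$ D_{mr}^{south}(i) = D_{ms}/2 + (i-1) D_r, \qquad
   D_{mr}^{north}(i) = D_{ms}/2 + (n-i) D_r . $$

For the experimental 2M3S layout ($D_{ms} = D_r = 0.6$ m) these are
(0.3, 0.9, 1.5) m and (1.5, 0.9, 0.3) m — the nearest row always sits
$D_{ms}/2$ from the origin. Row widths $w_i$ (used when aggregating rows
to a strip) default to $D_r$ for every row, making strip values plain row
means for uniformly spaced designs; a per-row width vector can be
supplied where spacing is not uniform.

### Shading distance, intervals, and cumulative shading time

At any daylight instant the shadow of a height difference $H_{ms}$
reaches

$$ D_s = \frac{H_{ms}}{\tan\alpha}\,\cos(\beta + \gamma - 90°) $$

across the inter-row axis, where $\gamma$ is the planting direction
(counterclockwise from north, axial, stored modulo 180°). The sign of
$D_s$ identifies the source: positive means the shadow falls southward,
i.e. the *northern* maize strip is shading; negative means the southern
strip. A row is shaded when $|D_s| > D_{mr}$ for the source side, using
that side's own $H_{ms}$ — the north and south height differences are
kept separate throughout because the two adjacent strips genuinely differ
in the field.

The day is scanned from sunrise to sunset in 1-minute bins by default
(configurable). Shadedness is evaluated at bin midpoints; contiguous
shaded bins merge into intervals whose endpoints are the outer bin edges,
clipped to daylight. This makes daily cumulative shading time exactly
(number of shaded bins) × (bin length) and gives clean first-order
convergence: halving the step changes seasonal CSC by well under 0.5%
(asserted in the tests).

### Shading proportion and capacity

Instantaneous direct-beam intensity is taken proportional to
$\sin\alpha$. The *shading proportion* SP of a day is the fraction of
$\int \sin\alpha \, d\alpha$ — integrated along the rising and falling
elevation branches — that falls inside the shaded intervals. The full-day
denominator is $2(1 - \cos\alpha_{max})$ since elevation runs
$0 \to \alpha_{max} \to 0$. An interval wholly on one monotone branch
contributes $|\cos\alpha(t_1) - \cos\alpha(t_2)|$; an interval spanning
solar noon contributes
$(\cos\alpha(t_1) - \cos\alpha_{max}) + (\cos\alpha(t_2) - \cos\alpha_{max})$.
Disjoint intervals sum — a border row is typically shaded by the northern
strip in the morning and the southern strip later, and each interval maps
through the branch logic independently. Boundary elevations are zero
exactly when the boundary is sunrise or sunset, which falls out of the
geometry without special-casing. The closed forms are validated against a
1-second Riemann integration of $\sin\alpha\,d\alpha$ to within $10^{-3}$
over randomized interval sets.

Then per row and day $SC = R_a \times SP$; strip values are the
$w_i$-weighted means of row values; CSC is the sum of daily SC over the
analysis window. The accumulation window is a required input: the
package's examples and tests use the 41–64 days-after-sowing window over
which growth measurements exist, since nothing outside a measured
$H_{ms}$ range can be interpolated without extrapolating.

## The canopy-height stage

The $H_{ms}$ input can be derived from UAV photogrammetry products. The
package starts from co-registered surface rasters (photogrammetric
reconstruction itself is out of scope): a pre-emergence reference ground
surface and a per-campaign crop surface. Rasters are plain numeric
matrices with a pixel size, read and written as ESRI ASCII grids — a
text interchange format that keeps fixtures reviewable; strip footprints
are column bands of the grid.

The stage applies, in order: excess-green masking
($EXG = 2g - r - b$) with the threshold at the valley of the smoothed
EXG histogram (`bimodal_threshold()`, which errors on unimodal input
rather than guessing); the canopy height model $CHM = DSM - H_g$ with
negatives clipped to zero (below-ground photogrammetric noise); an
optional maize/soybean split at a height threshold — either the
histogram valley again or a stage-specific manual value; and percentile
height extraction per strip: the 99.9th percentile for maize (open
canopy, the tallest organs set the shading top) and the 90th for soybean
(closed canopy, extremes are outliers). Percentiles interpolate linearly
between order statistics; the choice of percentile definition is a
convention the data sources do not pin down.

Sparse campaign measurements become daily series by a *natural* cubic
spline that passes exactly through the measurements — no smoothing
parameter, and no extrapolation beyond the first and last campaign.
Daily $H_{ms}$ is then maize minus soybean per side, clipped at zero
with a warning if soybean overtops maize.

Agreement statistics: `r_squared()` implements the regression
sum-of-squares ratio $\sum(\hat x_i - \bar x)^2 / \sum(x_i - \bar x)^2$,
deliberately in that form (it can exceed 1 for biased estimators, unlike
$1 - SS_{res}/SS_{tot}$); `rmse()` is the usual root mean square error.

## Synthetic data: what it does and does not emulate

The generators exist so every stage can be exercised end-to-end with
known truth, at desk scale.

* `make_scene()` builds raster triplets (reference, crop surface, RGB
  ortho bands) for a layout, with rectangular strips at known heights.
  Surface noise is **bounded** (uniform, with the requested standard
  deviation): it emulates photogrammetric residuals after ground-control
  correction, and it keeps extreme percentiles within a few standard
  deviations of truth so recovery can be asserted tightly. The
  bare-ground reference carries a tenth of the crop-surface noise, since
  featureless bare soil reconstructs far more accurately than vegetated
  canopy. What the scenes do *not* emulate: within-canopy height
  texture, leaning plants, doming or blur artefacts, mixed pixels at
  strip edges, or weeds — so passing the recovery tests demonstrates the
  pipeline's arithmetic, not robustness to real photogrammetric
  pathology.
* `make_weather()` draws daily $R_g$ uniformly in $[0.30, 0.75] R_0$ and
  $S$ in $[0.25, 0.95] S_0$, spanning overcast to clear days without
  autocorrelation; real weather is serially correlated, which matters
  for CSC variance but not its expectation.
* `make_growth()` samples logistic height curves for maize
  ($K = 2.6$ m, rate 0.15 d⁻¹, inflection 44 DAS) and soybean
  ($K = 0.95$ m, rate 0.18 d⁻¹, inflection 45 DAS) at the four campaign
  dates (41, 48, 56, 64 DAS). These defaults give an $H_{ms}$ rising
  steeply from ≈0.7 m to ≈1.6 m and slowing late — the shape of the
  vegetative window in this system — with a 1 cm north–south asymmetry.
  They are a single fixed choice, not a dial: all tests and examples run
  under these conditions.

All generators are deterministic under a fixed seed and emit their
ground truth.

## Numerical choices

* Time step: 1 minute (configurable); convergence asserted at 0.5 min.
* Inverse-trig clamping tolerance: $10^{-9}$.
* Diffuse fraction clamped to $[0,1]$; $S$ clipped to $S_0$ with warning.
* The azimuth at $\omega = 0$ uses the morning-branch limit.
* Polar day/night raises an explicit error; latitude-sweep grid points
  that hit it are flagged in the output rather than dropped.
* Degenerate inputs error loudly: overlapping shading intervals, gaps in
  the weather series, missing $H_{ms}$ dates, empty pixel sets after
  masking, unimodal histograms.
* Problem sizes in tests and examples: 24-day seasons, 1°-resolution
  direction sweeps (181 points), 1° latitude grids, and raster scenes of
  roughly 40 × 150 pixels at 5 cm — small enough to re-run everywhere,
  large enough that every code path is exercised.

## Known limitations

* Shading is binary per row and instant (shaded or not at the row
  position); partial-row penumbra and within-row position are not
  resolved.
* Only soybean is the shaded crop; maize-on-maize shading and shading of
  maize by anything are not modelled.
* The diffuse-fraction regression is site-calibrated; applying it across
  the latitude sweep assumes transferability.
* The $\sin\alpha$ intensity proxy ignores within-day atmospheric
  variation; multiplying SP by measured daily $R_a$ restores first-order
  realism but the sub-day weighting remains idealized.
* CSC magnitudes depend directly on the $H_{ms}$ trajectory and weather
  supplied; the synthetic defaults are realistic in shape but are not a
  reconstruction of any particular field season.

## A worked run

```{r example, eval = FALSE}
layout <- strip_layout("2M3S", 2, 3, row_spacing = 0.6,
                       strip_distance = 0.6, planting_direction = 59,
                       latitude = 43.267)
hms <- growth_hms_series(make_growth(), sowing_date = "2021-05-25")
weather <- make_weather("2021-07-05", n_days = nrow(hms), seed = 42)
sim <- simulate_shading(layout, weather, hms)
sim$summary      # per-row CSC over the 24-day window
```

The southernmost row accumulates the most shading, the middle row the
least of the borders, reproducing the border-row dominance that motivates
the per-row resolution of the model.
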