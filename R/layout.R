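#' Strip-intercropping layout
#'
#' Describes one repeating unit of a maize-soybean strip intercropping
#' pattern: how many rows each strip has, the within-strip row spacing, the
#' distance between adjacent maize and soybean strips, the planting
#' direction and the site latitude.
#'
#' @param configuration Label such as `"2M3S"` (2 maize rows + 3 soybean
#'   rows) or `"3M6S"`. Purely descriptive.
#' @param n_maize_rows,n_soybean_rows Rows per maize / soybean strip.
#' @param row_spacing Within-strip row spacing `Dr` (m).
#' @param strip_distance Distance `Dms` between adjacent maize and soybean
#'   strips (m).
#' @param planting_direction Row direction `gamma` in degrees,
#'   counterclockwise from north; 0 means rows run north-south. Stored
#'   modulo 180 since direction is axial.
#' @param latitude Site latitude (decimal degrees).
#' @param row_widths Optional per-row widths `w_i` (m) used when averaging
#'   row values up to the strip; defaults to `row_spacing` for every row,
#'   which makes strip values plain row means under uniform spacing.
#' @return An object of class `strip_layout`.
#' @examples
#' strip_layout("2M3S", 2, 3, row_spacing = 0.6, strip_distance = 0.6,
#'              planting_direction = 59, latitude = 43.267)
#' @export
strip_layout <- function(configuration, n_maize_rows, n_soybean_rows,
                         row_spacing, strip_distance,
                         planting_direction = 0, latitude = 43.267,
                         row_widths = NULL) {
  stopifnot(n_maize_rows >= 1, n_soybean_rows >= 1,
            row_spacing > 0, strip_distance > 0)
  gamma <- planting_direction %% 180
  if (is.null(row_widths)) row_widths <- rep(row_spacing, n_soybean_rows)
  if (length(row_widths) != n_soybean_rows || any(row_widths <= 0)) {
    stop("`row_widths` must be ", n_soybean_rows, " positive values",
         call. = FALSE)
  }
  structure(
    list(configuration = configuration,
         n_maize_rows = as.integer(n_maize_rows),
         n_soybean_rows = as.integer(n_soybean_rows),
         row_spacing = row_spacing,
         strip_distance = strip_distance,
         planting_direction = gamma,
         latitude = latitude,
         row_widths = row_widths),
    class = "strip_layout"
  )
}

#' @export
print.strip_layout <- function(x, ...) {
  cat(sprintf(
    "<strip_layout> %s: %d maize + %d soybean rows, Dr = %.2f m, Dms = %.2f m\n  direction %.0f deg CCW from north, latitude %.3f deg\n",
    x$configuration, x$n_maize_rows, x$n_soybean_rows, x$row_spacing,
    x$strip_distance, x$planting_direction, x$latitude
  ))
  invisible(x)
}

#' Per-row distances to the shading-origin points
#'
#' For each soybean row (row 1 is the southernmost), the distance to the
#' origin used by the shading-distance comparison: the midpoint between the
#' soybean strip and the maize strip casting the shadow. The origin differs
#' for the northern and the southern adjacent maize strip, so each row
#' carries two distances. Rows are regularly spaced at `row_spacing`, and
#' the first/last row sits `strip_distance` from the adjacent maize strip,
#' putting the nearest row `strip_distance / 2` from either origin.
#'
#' @param layout A [strip_layout()].
#' @return Data frame with one row per soybean row: `row`,
#'   `d_south_source` (m, origin at the southern maize strip),
#'   `d_north_source` (m, origin at the northern maize strip), `width` (m).
#' @examples
#' lay <- strip_layout("2M3S", 2, 3, 0.6, 0.6)
#' row_distances(lay) # north source: 1.5, 0.9, 0.3 m for rows 1..3
#' @export
row_distances <- function(layout) {
  stopifnot(inherits(layout, "strip_layout"))
  n <- layout$n_soybean_rows
  i <- seq_len(n)
  half <- layout$strip_distance / 2
  data.frame(
    row = i,
    d_south_source = half + (i - 1) * layout$row_spacing,
    d_north_source = half + (n - i) * layout$row_spacing,
    width = layout$row_widths
  )
}

#' Read a layout configuration block
#'
#' Accepts a YAML or JSON file (or a pre-parsed list) with keys
#' `configuration`, `n_maize_rows`, `n_soybean_rows`, `row_spacing_m`,
#' `strip_distance_m`, `planting_direction_deg`, `latitude_deg`.
#'
#' @param x Path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return A [strip_layout()].
#' @export
read_layout <- function(x) {
  if (is.character(x)) {
    x <- if (grepl("\\.json$", x, ignore.case = TRUE)) {
      jsonlite::read_json(x, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(x)
    }
  }
  req <- c("configuration", "n_maize_rows", "n_soybean_rows",
           "row_spacing_m", "strip_distance_m", "planting_direction_deg",
           "latitude_deg")
  missing <- setdiff(req, names(x))
  if (length(missing)) {
    stop("layout config is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  strip_layout(x$configuration, x$n_maize_rows, x$n_soybean_rows,
               x$row_spacing_m, x$strip_distance_m,
               x$planting_direction_deg, x$latitude_deg)
}
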