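# Plain-text raster I/O in ESRI ASCII grid format, the interchange format
# that keeps fixtures and outputs human-readable. Matrix row 1 is the top
# (northernmost) raster row, following the format's convention.

#' Write a raster grid to an ESRI ASCII grid file
#'
#' @param grid A [raster_grid()] (or numeric matrix).
#' @param path Output path (conventionally `.asc`).
#' @param xllcorner,yllcorner Coordinates of the lower-left corner (m).
#' @param nodata Value standing in for missing cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, xllcorner = 0, yllcorner = 0,
                             nodata = -9999) {
  ps <- attr(grid, "pixel_size")
  if (is.null(ps)) ps <- 1
  m <- unclass(grid)
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(xllcorner)),
    paste("yllcorner", format(yllcorner)),
    paste("cellsize", format(ps)),
    paste("NODATA_value", format(nodata))
  ), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path Path to the `.asc` file.
#' @return A [raster_grid()] with `NA` for nodata cells.
#' @export
read_ascii_grid <- function(path) {
  header <- readLines(path, n = 6)
  kv <- strsplit(trimws(header), "\\s+")
  keys <- tolower(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  h <- stats::setNames(vals, keys)
  for (k in c("ncols", "nrows", "cellsize", "nodata_value")) {
    if (!k %in% keys) stop("malformed ASCII grid header: missing ", k,
                           call. = FALSE)
  }
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(as.integer(h["nrows"]), as.integer(h["ncols"])))) {
    stop("ASCII grid body does not match header dimensions", call. = FALSE)
  }
  m[m == h["nodata_value"]] <- NA_real_
  raster_grid(m, h[["cellsize"]])
}
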