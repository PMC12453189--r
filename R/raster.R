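## Gridded covariates (habitat suitability, monthly precipitation,
## imperviousness) are regular planar grids in the analysis projection,
## serialized as plain-text ESRI ASCII grids.  `values` is a matrix whose
## first row is the *top* (northernmost) row of the grid.

#' Create a grid raster
#'
#' @param values numeric matrix; row 1 is the northernmost row
#' @param xll,yll coordinates of the lower-left grid corner (km, projected)
#' @param cellsize cell edge length (km)
#' @param nodata value treated as missing (stored as NA internally)
#' @return object of class `grid_raster`
#' @export
grid_raster <- function(values, xll, yll, cellsize, nodata = -9999) {
  values <- as.matrix(values)
  values[values == nodata] <- NA_real_
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells, cellsize %g km, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g], %d NA cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

## x coordinate of column centres / y coordinate of row centres (row 1 = top).
raster_x_centers <- function(r) r$xll + (seq_len(ncol(r$values)) - 0.5) * r$cellsize
raster_y_centers <- function(r) r$yll + (nrow(r$values) - seq_len(nrow(r$values)) + 0.5) * r$cellsize

#' Read / write ESRI ASCII grid files
#'
#' Plain-text raster exchange format: a six-line header (`NCOLS`, `NROWS`,
#' `XLLCORNER`, `YLLCORNER`, `CELLSIZE`, `NODATA_VALUE`) followed by rows of
#' values from north to south.
#'
#' @param path file path
#' @return `read_ascii_grid` returns a [grid_raster()]
#' @export
read_ascii_grid <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  for (i in 1:6) {
    ln <- strsplit(trimws(readLines(con, 1)), "\\s+")[[1]]
    hdr[[toupper(ln[1])]] <- as.numeric(ln[2])
  }
  vals <- scan(con, what = numeric(), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$NROWS, ncol = hdr$NCOLS, byrow = TRUE)
  grid_raster(m, hdr$XLLCORNER, hdr$YLLCORNER, hdr$CELLSIZE,
              nodata = hdr$NODATA_VALUE %||% -9999)
}

#' @param r a [grid_raster()]
#' @param digits number of significant digits written
#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(r, path, digits = 7) {
  vals <- r$values
  vals[is.na(vals)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("NCOLS", ncol(vals)),
    paste("NROWS", nrow(vals)),
    paste("XLLCORNER", format(r$xll, digits = 12)),
    paste("YLLCORNER", format(r$yll, digits = 12)),
    paste("CELLSIZE", format(r$cellsize, digits = 12)),
    paste("NODATA_VALUE", r$nodata)
  ), con)
  for (i in seq_len(nrow(vals))) {
    writeLines(paste(signif(vals[i, ], digits), collapse = " "), con)
  }
  invisible(path)
}

#' Mean winter precipitation raster
#'
#' Averages monthly precipitation grids over all December, January and
#' February months of the requested winters.  The winter labelled by year
#' `y` spans December of `y - 1` through February of `y`, so "Dec-Feb
#' inclusive" crosses the calendar-year boundary.
#'
#' @param monthly_grids named list of [grid_raster()]s; names are `"YYYY-MM"`
#' @param year_range integer vector of winter labels (year of the Jan/Feb)
#' @return a [grid_raster()] of per-cell mean winter precipitation (mm)
#' @export
winter_precip_raster <- function(monthly_grids, year_range) {
  year_range <- sort(unique(as.integer(year_range)))
  wanted <- unlist(lapply(year_range, function(y) {
    c(sprintf("%d-12", y - 1L), sprintf("%d-01", y), sprintf("%d-02", y))
  }))
  missing <- setdiff(wanted, names(monthly_grids))
  if (length(missing)) {
    stop("missing monthly precipitation grid(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  gs <- monthly_grids[wanted]
  ref <- gs[[1]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (g in gs) {
    stopifnot(identical(dim(g$values), dim(ref$values)))
    acc <- acc + g$values
  }
  grid_raster(acc / length(gs), ref$xll, ref$yll, ref$cellsize, ref$nodata)
}

#' Rescale values to the unit interval
#'
#' Applies `(x - min) / (max - min)` so the minimum maps exactly to 0 and
#' the maximum exactly to 1; used to put winter precipitation on the same
#' unitless scale as the other persistence covariates.
#'
#' @param x a [grid_raster()] or numeric vector
#' @return same shape as `x`, values in `[0, 1]`
#' @export
scale_01 <- function(x) {
  vals <- if (inherits(x, "grid_raster")) x$values else x
  rng <- range(vals, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    stop("cannot rescale: input has no spread (all values equal)", call. = FALSE)
  }
  scaled <- (vals - rng[1]) / (rng[2] - rng[1])
  if (inherits(x, "grid_raster")) {
    grid_raster(scaled, x$xll, x$yll, x$cellsize, x$nodata)
  } else {
    scaled
  }
}
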