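#' Grid geometry of a raster
#'
#' A `grid_spec` describes the georeferencing of a regular, north-up raster:
#' dimensions, top-left corner (origin), pixel sizes, an optional coordinate
#' reference system identifier, and the nodata sentinel used on disk.
#' Row/column indices are 1-based in R code; extents are half-open, so pixel
#' `(1, 1)` covers `[origin_x, origin_x + pixel_size_x) x
#' (origin_y + pixel_size_y, origin_y]`.
#'
#' @param n_rows,n_cols Raster dimensions (>= 1).
#' @param origin_x,origin_y Map coordinates of the top-left corner.
#' @param pixel_size_x Pixel width in map units (> 0).
#' @param pixel_size_y Pixel height in map units; negative for north-up.
#' @param crs_id Free-text coordinate reference system identifier, or `NA`.
#' @param nodata Sentinel value written to file for invalid cells.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols,
                      origin_x = 0, origin_y = n_rows * abs(pixel_size_y),
                      pixel_size_x = 1, pixel_size_y = -pixel_size_x,
                      crs_id = NA_character_, nodata = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (pixel_size_x == 0 || pixel_size_y == 0) {
    stop("pixel sizes must be nonzero")
  }
  if (pixel_size_y > 0) {
    stop("rasters are north-up: pixel_size_y must be negative")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      origin_x = origin_x, origin_y = origin_y,
      pixel_size_x = pixel_size_x, pixel_size_y = pixel_size_y,
      crs_id = crs_id, nodata = nodata
    ),
    class = "grid_spec"
  )
}

#' Test whether two grid specs describe the same grid
#'
#' All geometry fields must agree; the nodata sentinel is ignored, as it is a
#' file-level encoding detail rather than part of the grid.
#'
#' @param a,b `grid_spec` objects.
#' @param tol Numeric tolerance on coordinates and pixel sizes.
#' @return Logical.
#' @export
spec_compatible <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$pixel_size_x - b$pixel_size_x) <= tol &&
    abs(a$pixel_size_y - b$pixel_size_y) <= tol &&
    (identical(is.na(a$crs_id), is.na(b$crs_id)) &&
       (is.na(a$crs_id) || a$crs_id == b$crs_id))
}

#' A single georeferenced raster band
#'
#' The universal currency of the pipeline: a numeric matrix plus its
#' [grid_spec()]. Invalid cells are carried as `NA` in memory (all pipeline
#' arithmetic skips them) and materialised as the spec's nodata sentinel on
#' write.
#'
#' @param values Numeric matrix of shape `(n_rows, n_cols)`.
#' @param spec A [grid_spec()].
#' @param label Free text (a date, band or layer name).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, spec, label = "") {
  stopifnot(inherits(spec, "grid_spec"), is.matrix(values))
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols) {
    stop("values shape does not match grid spec")
  }
  storage.mode(values) <- "double"
  structure(list(values = values, spec = spec, label = label),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<raster_grid> %dx%d px, pixel %gx%g, label '%s'\n  valid %d/%d, range [%s, %s]\n",
    x$spec$n_rows, x$spec$n_cols, x$spec$pixel_size_x, abs(x$spec$pixel_size_y),
    x$label, sum(!is.na(v)), length(v),
    format(suppressWarnings(min(v, na.rm = TRUE))),
    format(suppressWarnings(max(v, na.rm = TRUE)))
  ))
  invisible(x)
}

#' Number of nodata cells in a raster
#' @param grid A [raster_grid()].
#' @return Integer count of invalid (`NA`) cells.
#' @export
n_nodata <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  sum(is.na(grid$values))
}

#' Apply a function to raster values, keeping the geometry
#'
#' @param grid A [raster_grid()].
#' @param f Function taking and returning a numeric matrix/vector.
#' @param label Optional new label.
#' @return A [raster_grid()] on the same spec.
#' @export
map_grid <- function(grid, f, label = grid$label) {
  v <- f(grid$values)
  v <- matrix(as.numeric(v), nrow = grid$spec$n_rows, ncol = grid$spec$n_cols)
  raster_grid(v, grid$spec, label = label)
}

#' A date-indexed stack of rasters on one grid
#'
#' @param dates `Date` vector, strictly increasing.
#' @param grids List of [raster_grid()] objects, one per date, all on
#'   compatible specs.
#' @return An object of class `raster_series`.
#' @export
raster_series <- function(dates, grids) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(grids), length(dates) >= 1)
  if (any(diff(as.numeric(dates)) <= 0)) {
    stop("dates must be strictly increasing")
  }
  for (g in grids) {
    stopifnot(inherits(g, "raster_grid"))
    if (!spec_compatible(g$spec, grids[[1]]$spec)) {
      stop("all grids in a series must share one grid spec")
    }
  }
  structure(list(dates = dates, grids = grids), class = "raster_series")
}

#' @export
print.raster_series <- function(x, ...) {
  cat(sprintf("<raster_series> %d dates (%s .. %s), %dx%d px\n",
              length(x$dates), min(x$dates), max(x$dates),
              x$grids[[1]]$spec$n_rows, x$grids[[1]]$spec$n_cols))
  invisible(x)
}

#' @export
length.raster_series <- function(x) length(x$dates)

# internal: x/y coordinates of cell centers
cell_centers_x <- function(spec) {
  spec$origin_x + (seq_len(spec$n_cols) - 0.5) * spec$pixel_size_x
}
cell_centers_y <- function(spec) {
  spec$origin_y + (seq_len(spec$n_rows) - 0.5) * spec$pixel_size_y
}
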