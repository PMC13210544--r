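#' Convert raw radiation from J m^-2 to MJ m^-2
#'
#' Reanalysis products commonly deliver surface solar radiation in J m^-2;
#' the light-use-efficiency model works in MJ m^-2.
#'
#' @param x Numeric or [raster_grid()] in J m^-2.
#' @return Same container in MJ m^-2.
#' @export
joules_to_megajoules <- function(x) {
  if (inherits(x, "raster_grid")) map_grid(x, function(v) v / 1e6) else x / 1e6
}

#' Photosynthetically active radiation from total solar radiation
#'
#' `PAR = fraction * SOL`, with the canonical fraction of one half.
#'
#' @param sol Total solar radiation (MJ m^-2 month^-1; numeric or
#'   [raster_grid()]).
#' @param par_fraction Fraction of SOL that is PAR.
#' @return PAR in the same container.
#' @export
par_from_sol <- function(sol, par_fraction = 0.5) {
  f <- function(v) {
    if (any(v < 0, na.rm = TRUE)) stop("solar radiation must be >= 0")
    par_fraction * v
  }
  if (inherits(sol, "raster_grid")) map_grid(sol, f, label = "par") else f(sol)
}

#' Absorbed photosynthetically active radiation
#'
#' `APAR = PAR * FPAR`, elementwise; nodata propagates.
#'
#' @param par,fpar Compatible [raster_grid()]s (FPAR in `[0, 1]`).
#' @return APAR [raster_grid()] (MJ m^-2 month^-1).
#' @export
apar <- function(par, fpar) {
  binary_grid_op(par, fpar, `*`, label = "apar")
}

#' Monthly net primary productivity
#'
#' `NPP = APAR * LUE`, elementwise (gC m^-2 month^-1).
#'
#' @param apar APAR [raster_grid()].
#' @param lue Actual light-use-efficiency [raster_grid()] (gC MJ^-1).
#' @return NPP [raster_grid()].
#' @export
npp_monthly <- function(apar, lue) {
  binary_grid_op(apar, lue, `*`, label = "npp")
}

#' Growing-season NPP accumulation
#'
#' Per-pixel sum over the monthly maps; a month with nodata at a pixel is
#' skipped, and the pixel is nodata only when invalid in every month. Under
#' a single-cropping system this June-October accumulation is the annual
#' crop NPP (gC m^-2 a^-1).
#'
#' @param monthly List of monthly NPP [raster_grid()]s.
#' @param strict Error on any nodata gap instead of skipping it.
#' @return Seasonal NPP [raster_grid()].
#' @export
npp_seasonal <- function(monthly, strict = FALSE) {
  if (length(monthly) == 0) stop("empty month list")
  spec <- monthly[[1]]$spec
  sums <- matrix(0, spec$n_rows, spec$n_cols)
  cnts <- matrix(0L, spec$n_rows, spec$n_cols)
  any_valid <- matrix(FALSE, spec$n_rows, spec$n_cols)
  for (g in monthly) {
    if (!spec_compatible(g$spec, spec)) stop("incompatible grids")
    ok <- !is.na(g$values)
    sums[ok] <- sums[ok] + g$values[ok]
    any_valid <- any_valid | ok
    cnts[ok] <- cnts[ok] + 1L
  }
  if (strict && any(any_valid & cnts < length(monthly))) {
    stop("nodata month at a valid pixel (strict accumulation)")
  }
  sums[!any_valid] <- NA_real_
  raster_grid(sums, spec, label = "npp_seasonal")
}

#' Zonal summary of seasonal NPP for one crop
#'
#' @param seasonal_npp Seasonal NPP [raster_grid()].
#' @param crop_map Categorical crop [raster_grid()].
#' @param crop Crop code.
#' @return Data frame: crop code, minimum, maximum, mean, n.
#' @export
zonal_summary <- function(seasonal_npp, crop_map, crop) {
  stopifnot(inherits(seasonal_npp, "raster_grid"),
            inherits(crop_map, "raster_grid"))
  if (!spec_compatible(seasonal_npp$spec, crop_map$spec)) {
    stop("incompatible grids")
  }
  v <- seasonal_npp$values[!is.na(crop_map$values) &
                             crop_map$values == crop]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no valid pixels for crop ", crop)
  data.frame(crop = crop, minimum = min(v), maximum = max(v),
             mean = mean(v), n = length(v))
}
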