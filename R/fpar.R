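#' FPAR scaling constants
#'
#' The linear-stretch endpoints `FPARmax = 0.950` and `FPARmin = 0.001`
#' (standard CASA constants), the NDVI/SR blending weight (equal weighting,
#' 0.5), and a cap on the simple ratio reconstructed from NDVI values
#' approaching one.
#'
#' @param fpar_max,fpar_min Stretch endpoints, `0 <= min < max <= 1`.
#' @param weight_ndvi Weight of the NDVI-based FPAR in the blend.
#' @param sr_cap Upper bound for SR reconstructed near the NDVI singularity.
#' @return An object of class `fpar_constants`.
#' @export
fpar_constants <- function(fpar_max = 0.950, fpar_min = 0.001,
                           weight_ndvi = 0.5, sr_cap = 30) {
  stopifnot(fpar_min >= 0, fpar_min < fpar_max, fpar_max <= 1,
            weight_ndvi >= 0, weight_ndvi <= 1, sr_cap > 1)
  structure(list(fpar_max = fpar_max, fpar_min = fpar_min,
                 weight_ndvi = weight_ndvi, sr_cap = sr_cap),
            class = "fpar_constants")
}

# internal: elementwise binary op on two compatible grids
binary_grid_op <- function(a, b, f, label) {
  stopifnot(inherits(a, "raster_grid"), inherits(b, "raster_grid"))
  if (!spec_compatible(a$spec, b$spec)) stop("incompatible grids")
  raster_grid(f(a$values, b$values), a$spec, label = label)
}

#' NDVI from red and near-infrared reflectance
#'
#' `(NIR - Red) / (NIR + Red)`; pixels with a zero band sum are nodata.
#'
#' @param red,nir Reflectance [raster_grid()]s (e.g. Sentinel-2 B4 and B8).
#' @return NDVI [raster_grid()] in `[-1, 1]`.
#' @export
ndvi_from_bands <- function(red, nir) {
  binary_grid_op(red, nir, function(r, n) {
    s <- n + r
    ifelse(is.na(s) | s == 0, NA_real_, (n - r) / s)
  }, label = "ndvi")
}

#' Simple ratio from red and near-infrared reflectance
#'
#' `NIR / Red`; pixels with zero red reflectance are nodata.
#'
#' @inheritParams ndvi_from_bands
#' @return SR [raster_grid()].
#' @export
sr_from_bands <- function(red, nir) {
  binary_grid_op(red, nir, function(r, n) {
    ifelse(is.na(r) | r == 0, NA_real_, n / r)
  }, label = "sr")
}

#' Reconstruct the simple ratio from NDVI
#'
#' The exact algebraic identity `SR = (1 + NDVI) / (1 - NDVI)`, needed
#' because the fusion step reconstructs NDVI (not bands). NDVI within 1e-6
#' of one is capped at `sr_cap` to guard the singularity; NDVI at or below
#' -1 is nodata.
#'
#' @param ndvi NDVI [raster_grid()] (or numeric vector).
#' @param sr_cap Cap applied near NDVI = 1.
#' @return SR in the same container as the input.
#' @export
sr_from_ndvi <- function(ndvi, sr_cap = 30) {
  f <- function(x) {
    out <- ifelse(x >= 1 - 1e-6, sr_cap, (1 + x) / (1 - x))
    out[!is.na(x) & x <= -1] <- NA_real_
    pmin(out, sr_cap)
  }
  if (inherits(ndvi, "raster_grid")) map_grid(ndvi, f, label = "sr") else f(ndvi)
}

#' Monthly index extrema over one crop's pixels
#'
#' Minimum and maximum of the monthly maximum-value composite restricted to
#' the crop's pixels, optionally trimmed to the `(p, 100-p)` percentiles
#' (default `p = 0`, absolute extremes). When a mask series is supplied,
#' pixels that were masked (gap-filled) at any of the month's dates are
#' excluded from the sample: extrema estimated from directly observed
#' pixels are not contaminated by residual fill error, which otherwise
#' widens the distribution tails and shifts the stretch for every pixel.
#'
#' @param index_series Index [raster_series()] (NDVI or SR).
#' @param crop_map Categorical crop [raster_grid()].
#' @param crop Crop code.
#' @param month Calendar month.
#' @param trim_percent Percentile trim `p` in `[0, 50)`.
#' @param mask_series Optional [raster_series()] on the same dates whose
#'   nonzero values flag masked pixels.
#' @return Named numeric `c(min = , max = )`.
#' @export
monthly_extrema <- function(index_series, crop_map, crop, month,
                            trim_percent = 0, mask_series = NULL) {
  comp <- monthly_composite(index_series, month, method = "max")
  if (!spec_compatible(comp$spec, crop_map$spec)) stop("incompatible grids")
  keep <- !is.na(crop_map$values) & crop_map$values == crop
  if (!is.null(mask_series)) {
    if (!identical(mask_series$dates, index_series$dates)) {
      stop("mask series dates do not match the index series")
    }
    in_month <- as.integer(format(index_series$dates, "%m")) == month
    for (g in mask_series$grids[in_month]) {
      keep <- keep & !is.na(g$values) & g$values == 0
    }
    if (!any(keep)) {
      stop("no unmasked pixels for crop ", crop, " in month ", month)
    }
  }
  vals <- comp$values[keep]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no valid pixels for crop ", crop,
                              " in month ", month)
  if (trim_percent > 0) {
    q <- stats::quantile(vals, c(trim_percent, 100 - trim_percent) / 100,
                         names = FALSE)
    c(min = q[1], max = q[2])
  } else {
    c(min = min(vals), max = max(vals))
  }
}

#' Per-crop, per-month NDVI and SR extrema table
#'
#' The scaling table driving the dual-index FPAR stretch: for each crop and
#' growing-season month, the extrema of the monthly NDVI composite and of
#' the SR derived from it.
#'
#' @param ndvi_series Fine NDVI [raster_series()].
#' @param crop_map Categorical crop [raster_grid()].
#' @param crops Named codes of the crops to tabulate.
#' @param months Growing-season months.
#' @param trim_percent Passed to [monthly_extrema()].
#' @param sr_cap Cap for [sr_from_ndvi()].
#' @param mask_series Passed to [monthly_extrema()]: restrict the extrema
#'   sample to directly observed (never gap-filled) pixels.
#' @return Data frame: crop, code, month, ndvi_min, ndvi_max, sr_min,
#'   sr_max.
#' @export
build_extrema_table <- function(ndvi_series, crop_map,
                                crops = CROP_CODES[c("maize", "rice")],
                                months = 6:10, trim_percent = 0,
                                sr_cap = 30, mask_series = NULL) {
  sr_series <- raster_series(
    ndvi_series$dates,
    lapply(ndvi_series$grids, sr_from_ndvi, sr_cap = sr_cap)
  )
  rows <- list()
  for (k in seq_along(crops)) {
    code <- crops[[k]]
    present <- any(crop_map$values == code, na.rm = TRUE)
    if (!present) next
    for (m in months) {
      nd <- monthly_extrema(ndvi_series, crop_map, code, m, trim_percent,
                            mask_series)
      sr <- monthly_extrema(sr_series, crop_map, code, m, trim_percent,
                            mask_series)
      rows[[length(rows) + 1]] <- data.frame(
        crop = names(crops)[k], code = code, month = m,
        ndvi_min = nd[["min"]], ndvi_max = nd[["max"]],
        sr_min = sr[["min"]], sr_max = sr[["max"]],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Linear FPAR stretch of a vegetation index
#'
#' `FPARmin + (x - x_min) (FPARmax - FPARmin) / (x_max - x_min)`, clipped
#' to `[FPARmin, FPARmax]`. Values outside the stretch range are clipped
#' rather than rejected, since per-month extrema computed on composites can
#' be exceeded by individual pixels after fusion.
#'
#' @param x Index value(s) (numeric or [raster_grid()]).
#' @param x_min,x_max Scaling extrema, `x_max > x_min`.
#' @param constants A [fpar_constants()].
#' @return FPAR in the same container as `x`.
#' @export
fpar_linear <- function(x, x_min, x_max, constants = fpar_constants()) {
  if (x_max <= x_min) {
    stop("degenerate FPAR stretch: x_max must exceed x_min")
  }
  f <- function(v) {
    out <- constants$fpar_min + (v - x_min) *
      (constants$fpar_max - constants$fpar_min) / (x_max - x_min)
    pmin(pmax(out, constants$fpar_min), constants$fpar_max)
  }
  if (inherits(x, "raster_grid")) map_grid(x, f, label = "fpar") else f(x)
}

#' Blend NDVI-based and SR-based FPAR
#'
#' The weighted mean (equal weights by default) of the two stretches,
#' clipped to the FPAR band; nodata in either input propagates.
#'
#' @param fpar_ndvi,fpar_sr FPAR [raster_grid()]s (or numerics).
#' @param constants A [fpar_constants()].
#' @return Combined FPAR.
#' @export
fpar_combined <- function(fpar_ndvi, fpar_sr, constants = fpar_constants()) {
  w <- constants$weight_ndvi
  f <- function(a, b) {
    pmin(pmax(w * a + (1 - w) * b, constants$fpar_min), constants$fpar_max)
  }
  if (inherits(fpar_ndvi, "raster_grid")) {
    binary_grid_op(fpar_ndvi, fpar_sr, f, label = "fpar")
  } else {
    f(fpar_ndvi, fpar_sr)
  }
}

#' Monthly dual-index FPAR map
#'
#' For each crop present: the monthly NDVI maximum-value composite is
#' stretched with the crop's NDVI extrema, the SR reconstructed from the
#' composite is stretched with the crop's SR extrema, and the two are
#' blended. Non-crop pixels are nodata. `scope = "month"` uses that month's
#' extrema row (as the stretch is defined); `scope = "season"` pools the
#' extrema across the table's months.
#'
#' @param fused_ndvi_series Gap-free NDVI [raster_series()].
#' @param crop_map Categorical crop [raster_grid()].
#' @param extrema Table from [build_extrema_table()].
#' @param month Calendar month.
#' @param constants A [fpar_constants()].
#' @param scope `"month"` or `"season"`.
#' @return FPAR [raster_grid()] bounded in `[fpar_min, fpar_max]`.
#' @export
fpar_monthly <- function(fused_ndvi_series, crop_map, extrema, month,
                         constants = fpar_constants(),
                         scope = c("month", "season")) {
  scope <- match.arg(scope)
  comp <- monthly_composite(fused_ndvi_series, month, method = "max")
  if (!spec_compatible(comp$spec, crop_map$spec)) stop("incompatible grids")
  sr <- sr_from_ndvi(comp, sr_cap = constants$sr_cap)
  out <- matrix(NA_real_, comp$spec$n_rows, comp$spec$n_cols)
  crops <- unique(as.vector(crop_map$values))
  crops <- crops[!is.na(crops) & crops %in% extrema$code]
  missing <- setdiff(
    unique(as.vector(crop_map$values)),
    c(NA, CROP_CODES[["other"]], extrema$code)
  )
  if (length(missing) > 0) {
    stop("missing extrema for crop code(s): ", paste(missing, collapse = ", "))
  }
  for (code in crops) {
    if (scope == "month") {
      row <- extrema[extrema$code == code & extrema$month == month, ]
      if (nrow(row) != 1) stop("no extrema for crop ", code, " month ", month)
      nd_rng <- c(row$ndvi_min, row$ndvi_max)
      sr_rng <- c(row$sr_min, row$sr_max)
    } else {
      rows <- extrema[extrema$code == code, ]
      nd_rng <- c(min(rows$ndvi_min), max(rows$ndvi_max))
      sr_rng <- c(min(rows$sr_min), max(rows$sr_max))
    }
    sel <- !is.na(crop_map$values) & crop_map$values == code
    f_nd <- fpar_linear(comp$values[sel], nd_rng[1], nd_rng[2], constants)
    f_sr <- fpar_linear(sr$values[sel], sr_rng[1], sr_rng[2], constants)
    out[sel] <- fpar_combined(f_nd, f_sr, constants)
  }
  raster_grid(out, comp$spec, label = sprintf("fpar_%02d", month))
}
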