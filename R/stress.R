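#' Crop light-use efficiency parameters
#'
#' Maximum light-use efficiency per crop (gC MJ^-1): 1.1 for maize and 0.9
#' for rice, the crop-specific CASA values; the PAR fraction of total solar
#' radiation (0.5); and the scale constant of the high-temperature stress
#' logistic product (1.1841).
#'
#' @param epsilon_max Named vector of per-crop maxima, names matching
#'   [CROP_CODES].
#' @param par_fraction Fraction of solar radiation that is PAR, in `(0, 1]`.
#' @param tepsilon2_scale Scale constant of the high-temperature stress
#'   factor.
#' @return An object of class `crop_params`.
#' @export
crop_params <- function(epsilon_max = c(maize = 1.1, rice = 0.9),
                        par_fraction = 0.5, tepsilon2_scale = 1.1841) {
  stopifnot(all(epsilon_max > 0), par_fraction > 0, par_fraction <= 1,
            tepsilon2_scale > 0, !is.null(names(epsilon_max)))
  structure(list(epsilon_max = epsilon_max, par_fraction = par_fraction,
                 tepsilon2_scale = tepsilon2_scale),
            class = "crop_params")
}

# internal: accept a raster_grid or plain numeric, return in kind
grid_or_numeric <- function(x, f, template = NULL, label = "") {
  if (inherits(x, "raster_grid")) return(map_grid(x, f, label = label))
  f(x)
}

#' Optimum growth temperature per pixel
#'
#' The monthly mean temperature of the month in which the NDVI composite
#' peaks over the growing cycle; ties go to the earliest month, and a pixel
#' with NDVI nodata in every month is nodata.
#'
#' @param monthly_ndvi List of monthly NDVI composite [raster_grid()]s.
#' @param monthly_t_mean List of monthly mean temperature [raster_grid()]s,
#'   aligned month-for-month with `monthly_ndvi`.
#' @return Optimum-temperature [raster_grid()] (degrees C).
#' @export
optimum_temperature <- function(monthly_ndvi, monthly_t_mean) {
  if (length(monthly_ndvi) == 0 ||
      length(monthly_ndvi) != length(monthly_t_mean)) {
    stop("monthly NDVI and temperature lists must align and be nonempty")
  }
  spec <- monthly_ndvi[[1]]$spec
  best_v <- matrix(-Inf, spec$n_rows, spec$n_cols)
  topt <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  for (k in seq_along(monthly_ndvi)) {
    nv <- monthly_ndvi[[k]]$values
    tv <- monthly_t_mean[[k]]$values
    if (!spec_compatible(monthly_ndvi[[k]]$spec, spec) ||
        !spec_compatible(monthly_t_mean[[k]]$spec, spec)) {
      stop("misaligned month grids")
    }
    better <- !is.na(nv) & nv > best_v # strict: earliest month wins ties
    best_v[better] <- nv[better]
    topt[better] <- tv[better]
  }
  raster_grid(topt, spec, label = "t_opt")
}

#' Low-temperature stress scalar
#'
#' The quadratic `0.8 + 0.02 Topt - 0.0005 Topt^2`, clipped to `[0, 1]`.
#' Its vertex sits at 20 degrees C, where the scalar is exactly one.
#'
#' @param t_opt Optimum temperature (numeric or [raster_grid()]).
#' @param clip Clip to `[0, 1]` (the CASA convention; the raw quadratic
#'   goes negative for extreme optima).
#' @return Stress scalar in the same container.
#' @export
t_stress_low <- function(t_opt, clip = TRUE) {
  f <- function(x) {
    v <- 0.8 + 0.02 * x - 0.0005 * x^2
    if (clip) pmin(pmax(v, 0), 1) else v
  }
  grid_or_numeric(t_opt, f, label = "t_stress_low")
}

#' High-temperature stress scalar
#'
#' The two-logistic product
#' `scale / ((1 + exp(0.2 (Topt - 10 - T))) (1 + exp(0.3 (-Topt - 10 + T))))`,
#' clipped to `[0, 1]`. At `T = Topt` it evaluates to about 0.9935 with the
#' default scale 1.1841; it decays towards zero when the month is much
#' colder or much hotter than the pixel's optimum.
#'
#' @param t_opt Optimum temperature (numeric or [raster_grid()]).
#' @param t_mean Monthly mean temperature, same container/shape.
#' @param scale Scale constant (see [crop_params()]).
#' @param clip Clip to `[0, 1]`.
#' @return Stress scalar.
#' @export
t_stress_high <- function(t_opt, t_mean, scale = 1.1841, clip = TRUE) {
  f <- function(topt, t) {
    v <- scale / ((1 + exp(0.2 * (topt - 10 - t))) *
                    (1 + exp(0.3 * (-topt - 10 + t))))
    if (clip) pmin(pmax(v, 0), 1) else v
  }
  if (inherits(t_opt, "raster_grid")) {
    binary_grid_op(t_opt, t_mean, f, label = "t_stress_high")
  } else {
    f(t_opt, t_mean)
  }
}

#' Water stress scalar
#'
#' `0.5 + 0.5 E/P` with E the actual and P the potential evapotranspiration,
#' clipped to `[0.5, 1]`: even fully water-limited vegetation retains half
#' its light-use efficiency. Pixels with nonpositive P are nodata.
#'
#' @param e_actual Actual evapotranspiration (mm; numeric or
#'   [raster_grid()]).
#' @param e_potential Potential evapotranspiration (mm), same container.
#' @return Stress scalar in `[0.5, 1]`.
#' @export
w_stress <- function(e_actual, e_potential) {
  f <- function(e, p) {
    v <- ifelse(is.na(p) | p <= 0, NA_real_, 0.5 + 0.5 * e / p)
    pmin(pmax(v, 0.5), 1)
  }
  if (inherits(e_actual, "raster_grid")) {
    binary_grid_op(e_actual, e_potential, f, label = "w_stress")
  } else {
    f(e_actual, e_potential)
  }
}

#' Actual light-use efficiency
#'
#' `LUE = T1 * T2 * W * epsilon_max(crop)`: the crop's maximum light-use
#' efficiency down-regulated by the three stress scalars. Non-crop pixels
#' ("other") are nodata; a crop code present in the map but missing from
#' `params$epsilon_max` is an error.
#'
#' @param t1,t2,w Stress-scalar [raster_grid()]s.
#' @param crop_map Categorical crop [raster_grid()].
#' @param params A [crop_params()].
#' @return LUE [raster_grid()] (gC MJ^-1), bounded by `epsilon_max`.
#' @export
actual_lue <- function(t1, t2, w, crop_map, params = crop_params()) {
  for (g in list(t1, t2, w, crop_map)) {
    stopifnot(inherits(g, "raster_grid"))
    if (!spec_compatible(g$spec, t1$spec)) stop("incompatible grids")
  }
  codes <- unique(as.vector(crop_map$values))
  codes <- codes[!is.na(codes) & codes != CROP_CODES[["other"]]]
  eps_codes <- CROP_CODES[names(params$epsilon_max)]
  if (any(!codes %in% eps_codes)) {
    stop("crop code(s) without epsilon_max: ",
         paste(setdiff(codes, eps_codes), collapse = ", "))
  }
  eps <- matrix(NA_real_, t1$spec$n_rows, t1$spec$n_cols)
  for (nm in names(params$epsilon_max)) {
    sel <- !is.na(crop_map$values) & crop_map$values == CROP_CODES[[nm]]
    eps[sel] <- params$epsilon_max[[nm]]
  }
  raster_grid(t1$values * t2$values * w$values * eps, t1$spec, label = "lue")
}
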