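#' Crop codes used throughout the pipeline
#'
#' `0` = other, `1` = maize, `2` = rice.
#' @format Named integer vector.
#' @export
CROP_CODES <- c(other = 0L, maize = 1L, rice = 2L)

#' Default 16-day compositing dates for a June-October growing season
#'
#' Ten dates starting June 2, spaced 16 days (two per month, June through
#' October), mimicking a 16-day satellite compositing cycle. Each composite
#' is assigned to the month containing its start date.
#'
#' @param year Calendar year.
#' @return A `Date` vector of length 10.
#' @export
default_season_dates <- function(year = 2025) {
  as.Date(sprintf("%d-06-02", year)) + 16 * (0:9)
}

#' Synthetic scene description
#'
#' Defines the simulated study landscape: the fine working grid, the
#' fine-to-coarse scale factor (e.g. 10 emulating a 10 m sensor against a
#' 100 m-class product, or 25 for 10 m vs 250 m), the field layout, crop
#' mix, season dates, and the master seed for reproducibility.
#'
#' @param n_rows,n_cols Fine grid dimensions.
#' @param pixel_size Fine pixel size in map units (m).
#' @param scale_factor Fine-to-coarse aggregation factor (>= 2).
#' @param n_fields Number of rectangular fields tiling the scene.
#' @param crop_fractions Named proportions over maize/rice/other; must sum
#'   to one.
#' @param season Vector of 16-day composite dates (>= 6).
#' @param seed Integer master seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_rows = 200, n_cols = 200, pixel_size = 10,
                       scale_factor = 10, n_fields = 64,
                       crop_fractions = c(maize = 0.4, rice = 0.4, other = 0.2),
                       season = default_season_dates(2025), seed = 42) {
  stopifnot(scale_factor >= 2, length(season) >= 6,
            all(c("maize", "rice", "other") %in% names(crop_fractions)))
  if (abs(sum(crop_fractions) - 1) > 1e-8) {
    stop("crop_fractions must sum to 1")
  }
  grid <- grid_spec(n_rows, n_cols, origin_x = 0,
                    origin_y = n_rows * pixel_size,
                    pixel_size_x = pixel_size, pixel_size_y = -pixel_size,
                    crs_id = "LOCAL", nodata = -9999)
  structure(
    list(grid = grid, scale_factor = as.integer(scale_factor),
         n_fields = as.integer(n_fields),
         crop_fractions = crop_fractions,
         season = as.Date(season), seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Double-logistic phenology parameters per crop
#'
#' The seasonal NDVI trajectory of each crop is
#' `base + (peak - base) * (logistic(up) - logistic(down))` in day of year,
#' the standard double-logistic seasonal model. Defaults encode a
#' single-cropping maize/rice system: maize greens up quickly, peaks in
#' July-August and senesces sharply by October; rice greens up slightly
#' later, sustains a high canopy July-September and declines through
#' October; "other" land follows a flat low curve. `green_up_day` is the
#' nominal earliest-planting inflection; with the one-sided field delays
#' of [render_fine_series()] the median field greens up roughly twelve
#' days later.
#'
#' @return Data frame with one row per crop code.
#' @export
phenology_params <- function() {
  data.frame(
    crop = c("other", "maize", "rice"),
    code = c(0L, 1L, 2L),
    base_ndvi = c(0.15, 0.18, 0.22),
    peak_ndvi = c(0.25, 0.90, 0.85),
    green_up_day = c(120, 148, 158),
    senescence_day = c(320, 258, 284),
    green_up_rate = c(0.02, 0.10, 0.08),
    senescence_rate = c(0.02, 0.12, 0.09),
    stringsAsFactors = FALSE
  )
}

#' Seasonal NDVI of a crop at a day of year
#'
#' Evaluates the double-logistic curve of [phenology_params()], clipped to
#' `[-1, 1]`.
#'
#' @param crop Crop code (see [CROP_CODES]).
#' @param doy Day(s) of year.
#' @param params Phenology table, one row per crop code.
#' @return NDVI value(s).
#' @export
phenology_ndvi <- function(crop, doy, params = phenology_params()) {
  row <- params[params$code == crop, ]
  if (nrow(row) != 1) stop("unknown crop code: ", crop)
  v <- row$base_ndvi + (row$peak_ndvi - row$base_ndvi) *
    (stats::plogis(row$green_up_rate * (doy - row$green_up_day)) -
       stats::plogis(row$senescence_rate * (doy - row$senescence_day)))
  pmin(pmax(v, -1), 1)
}

#' Generate a rectangular-field crop map
#'
#' Tiles the scene with contiguous rectangular fields and assigns crops by
#' quota (counts proportional to `crop_fractions`, randomly permuted over
#' fields), so realised area fractions track the request closely.
#'
#' @param spec A [scene_spec()].
#' @param seed Seed (defaults to the scene seed).
#' @return A categorical [raster_grid()] with codes 0/1/2 (other, maize,
#'   rice) and an attached `fields` attribute (data frame of field
#'   rectangles and their crops).
#' @export
make_landscape <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  g <- spec$grid
  kr <- max(1L, floor(sqrt(spec$n_fields)))
  kc <- as.integer(ceiling(spec$n_fields / kr))
  if (kr > g$n_rows || kc > g$n_cols) {
    stop("n_fields exceeds grid capacity")
  }
  n_fields <- kr * kc
  fr <- spec$crop_fractions[c("maize", "rice", "other")]
  counts <- diff(c(0, round(cumsum(fr) * n_fields)))
  codes <- rep(c(CROP_CODES[["maize"]], CROP_CODES[["rice"]],
                 CROP_CODES[["other"]]), counts)
  codes <- withr::with_seed(seed, sample(codes))
  rbreaks <- round(seq(0, g$n_rows, length.out = kr + 1))
  cbreaks <- round(seq(0, g$n_cols, length.out = kc + 1))
  m <- matrix(NA_real_, g$n_rows, g$n_cols)
  fields <- data.frame(id = seq_len(n_fields),
                       row0 = 0L, row1 = 0L, col0 = 0L, col1 = 0L,
                       crop = codes)
  k <- 0L
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      k <- k + 1L
      r0 <- rbreaks[i] + 1L; r1 <- rbreaks[i + 1]
      c0 <- cbreaks[j] + 1L; c1 <- cbreaks[j + 1]
      m[r0:r1, c0:c1] <- codes[k]
      fields[k, c("row0", "row1", "col0", "col1")] <- c(r0, r1, c0, c1)
    }
  }
  out <- raster_grid(m, g, label = "crop_map")
  attr(out, "fields") <- fields
  out
}

#' Render the clean fine-resolution NDVI series
#'
#' Per-pixel NDVI follows the crop's double-logistic phenology, with
#' field-level heterogeneity plus per-pixel Gaussian noise, clipped to
#' `[-1, 1]`. Each field draws a small amplitude offset and a one-sided
#' phenological delay (exponential): planting and transplanting can only
#' be late, never early, so most fields track the nominal calendar while a
#' minority lag by weeks. The delay's one-sidedness is what shapes the
#' within-month NDVI distributions - a low-value tail of late fields
#' during green-up and the plateau, a green tail during senescence - and
#' with it the seasonal course of the crop-mean stretched FPAR.
#'
#' @param landscape Crop map from [make_landscape()] (needs its `fields`
#'   attribute for field-level variation; without it, fields vary only by
#'   crop).
#' @param spec A [scene_spec()].
#' @param params Phenology table.
#' @param noise_sd Per-pixel, per-date noise standard deviation (NDVI).
#' @param field_amp_sd Field-level NDVI amplitude offset sd.
#' @param field_delay_mean Mean of the exponential field-level phenology
#'   delay (days).
#' @param seed Seed (defaults to the scene seed).
#' @return A [raster_series()] over `spec$season`.
#' @export
render_fine_series <- function(landscape, spec, params = phenology_params(),
                               noise_sd = 0.02, field_amp_sd = 0.02,
                               field_delay_mean = 18, seed = spec$seed) {
  stopifnot(inherits(landscape, "raster_grid"), inherits(spec, "scene_spec"))
  if (!all(unique(as.vector(landscape$values)) %in% params$code)) {
    stop("landscape contains crop codes without phenology parameters")
  }
  g <- spec$grid
  fields <- attr(landscape, "fields")
  doys <- as.integer(format(spec$season, "%j"))
  withr::with_seed(seed, {
    if (!is.null(fields)) {
      amp <- rnorm(nrow(fields), 0, field_amp_sd)
      shift <- if (field_delay_mean > 0) {
        rexp(nrow(fields), 1 / field_delay_mean)
      } else {
        rep(0, nrow(fields))
      }
    }
    grids <- vector("list", length(doys))
    for (t in seq_along(doys)) {
      m <- matrix(NA_real_, g$n_rows, g$n_cols)
      if (is.null(fields)) {
        for (code in unique(as.vector(landscape$values))) {
          m[landscape$values == code] <-
            phenology_ndvi(code, doys[t], params)
        }
      } else {
        for (k in seq_len(nrow(fields))) {
          f <- fields[k, ]
          val <- phenology_ndvi(f$crop, doys[t] - shift[k], params) + amp[k]
          m[f$row0:f$row1, f$col0:f$col1] <- val
        }
      }
      m <- m + matrix(rnorm(length(m), 0, noise_sd), nrow(m))
      m <- pmin(pmax(m, -1), 1)
      grids[[t]] <- raster_grid(m, g, label = format(spec$season[t]))
    }
    raster_series(spec$season, grids)
  })
}

#' Degrade a fine series to the coarse sensor
#'
#' The synthetic coarse sensor observes the block mean of the fine scene
#' (see [aggregate_to_coarse()]) plus an additive radiometric bias and
#' Gaussian noise, clipped to `[-1, 1]`.
#'
#' @param fine_series Clean fine [raster_series()].
#' @param scale_factor Aggregation factor.
#' @param bias Additive inter-sensor bias (NDVI units).
#' @param noise_sd Coarse per-pixel noise sd.
#' @param seed Seed.
#' @return A coarse-resolution [raster_series()].
#' @export
degrade_to_coarse <- function(fine_series, scale_factor, bias = 0.02,
                              noise_sd = 0.01, seed = 1) {
  stopifnot(inherits(fine_series, "raster_series"))
  withr::with_seed(seed, {
    grids <- lapply(fine_series$grids, function(g) {
      cg <- aggregate_to_coarse(g, scale_factor)
      v <- cg$values + bias
      if (noise_sd > 0) {
        v <- v + matrix(rnorm(length(v), 0, noise_sd), nrow(v))
      }
      raster_grid(pmin(pmax(v, -1), 1), cg$spec, label = g$label)
    })
    raster_series(fine_series$dates, grids)
  })
}

#' Cloud-gap description
#'
#' @param gap_probability Per-date target masked fraction; either one value
#'   recycled over dates or a vector matching the season length. The default
#'   builder [default_cloud_spec()] uses 0.3 for July-August dates and 0.1
#'   otherwise (clouds concentrate in the wet mid-season).
#' @param blob_radius Radius of circular cloud blobs, fine pixels.
#' @param seed Seed.
#' @return An object of class `cloud_spec`.
#' @export
cloud_spec <- function(gap_probability, blob_radius = 6, seed = 7) {
  stopifnot(all(gap_probability >= 0 & gap_probability <= 1),
            blob_radius >= 1)
  structure(list(gap_probability = gap_probability,
                 blob_radius = blob_radius, seed = as.integer(seed)),
            class = "cloud_spec")
}

#' @rdname cloud_spec
#' @param season Season dates used to flag July-August.
#' @param p_peak,p_off Gap probabilities for July-August and other dates.
#' @export
default_cloud_spec <- function(season = default_season_dates(2025),
                               p_peak = 0.3, p_off = 0.1, blob_radius = 6,
                               seed = 7) {
  mo <- as.integer(format(as.Date(season), "%m"))
  cloud_spec(ifelse(mo %in% c(7L, 8L), p_peak, p_off),
             blob_radius = blob_radius, seed = seed)
}

#' Mask a fine series with spatially correlated cloud blobs
#'
#' Circular blobs at random centers are accumulated per date until the
#' masked fraction reaches that date's `gap_probability`; masked pixels
#' become nodata. Blobs, not i.i.d. pixels, because contiguous gaps are what
#' stress a similar-pixel fusion scheme.
#'
#' @param series Fine [raster_series()].
#' @param cloud A [cloud_spec()].
#' @return List with `series` (gapped) and `masks` (a [raster_series()] of
#'   0/1 grids, 1 = masked).
#' @export
apply_cloud_mask <- function(series, cloud) {
  stopifnot(inherits(series, "raster_series"), inherits(cloud, "cloud_spec"))
  p <- rep(cloud$gap_probability, length.out = length(series$dates))
  g <- series$grids[[1]]$spec
  rc <- expand.grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
  withr::with_seed(cloud$seed, {
    out <- series$grids
    masks <- vector("list", length(out))
    for (t in seq_along(out)) {
      mask <- matrix(FALSE, g$n_rows, g$n_cols)
      if (p[t] >= 1) {
        mask[] <- TRUE
      } else if (p[t] > 0) {
        guard <- 0L
        while (mean(mask) < p[t] && guard < 10000L) {
          cr <- runif(1, 1, g$n_rows)
          cc <- runif(1, 1, g$n_cols)
          hit <- (rc$row - cr)^2 + (rc$col - cc)^2 <= cloud$blob_radius^2
          mask[hit] <- TRUE
          guard <- guard + 1L
        }
      }
      v <- out[[t]]$values
      v[mask] <- NA_real_
      out[[t]] <- raster_grid(v, g, label = out[[t]]$label)
      masks[[t]] <- raster_grid(mask + 0, g,
                                label = paste0("mask_", out[[t]]$label))
    }
    list(series = raster_series(series$dates, out),
         masks = raster_series(series$dates, masks))
  })
}

#' Monthly meteorology description
#'
#' Defaults sketch a temperate single-cropping region: temperature follows
#' a sinusoid peaking in July, solar radiation declines from early summer
#' into autumn, and actual evapotranspiration is a month-dependent fraction
#' of potential evapotranspiration. Linear spatial gradients (north-south
#' for temperature and wetness, west-east for radiation) add smooth
#' heterogeneity; set the gradients to zero for spatially constant fields.
#'
#' @param t_base,t_amplitude Annual mean level and seasonal amplitude of the
#'   monthly mean temperature sinusoid (degrees C), peaking in July.
#' @param t_gradient North-south temperature difference across the scene
#'   (degrees C).
#' @param sol_monthly Named total solar radiation per month,
#'   MJ m^-2 month^-1 (months 6-10).
#' @param sol_gradient_frac Relative west-east radiation gradient.
#' @param pet_monthly Potential evapotranspiration per month, mm.
#' @param aet_fraction_monthly Actual/potential ET ratio per month.
#' @param aet_gradient North-south spread of the AET fraction.
#' @param seed Seed (reserved; the default fields are deterministic).
#' @return An object of class `meteo_spec`.
#' @export
meteo_spec <- function(t_base = 14, t_amplitude = 8, t_gradient = 1.5,
                       sol_monthly = c(`6` = 650, `7` = 620, `8` = 560,
                                       `9` = 450, `10` = 330),
                       sol_gradient_frac = 0.06,
                       pet_monthly = c(`6` = 110, `7` = 130, `8` = 120,
                                       `9` = 85, `10` = 55),
                       aet_fraction_monthly = c(`6` = 0.65, `7` = 0.75,
                                                `8` = 0.8, `9` = 0.7,
                                                `10` = 0.6),
                       aet_gradient = 0.08, seed = 11) {
  stopifnot(all(sol_monthly >= 0), all(pet_monthly > 0),
            all(aet_fraction_monthly > 0 & aet_fraction_monthly <= 1))
  structure(list(t_base = t_base, t_amplitude = t_amplitude,
                 t_gradient = t_gradient, sol_monthly = sol_monthly,
                 sol_gradient_frac = sol_gradient_frac,
                 pet_monthly = pet_monthly,
                 aet_fraction_monthly = aet_fraction_monthly,
                 aet_gradient = aet_gradient, seed = as.integer(seed)),
            class = "meteo_spec")
}

#' Monthly meteorology bundle for one month
#'
#' @param month Calendar month.
#' @param t_mean Mean 2 m air temperature grid (degrees C).
#' @param sol Total solar radiation grid (MJ m^-2 month^-1).
#' @param e_actual,e_potential Actual / potential evapotranspiration grids
#'   (mm); potential must be positive wherever actual is valid.
#' @return An object of class `meteo_monthly`.
#' @export
meteo_monthly <- function(month, t_mean, sol, e_actual, e_potential) {
  for (g in list(t_mean, sol, e_actual, e_potential)) {
    stopifnot(inherits(g, "raster_grid"))
    if (!spec_compatible(g$spec, t_mean$spec)) {
      stop("meteorology grids must share one grid")
    }
  }
  bad <- !is.na(e_actual$values) &
    (is.na(e_potential$values) | e_potential$values <= 0)
  if (any(bad)) stop("potential ET must be positive wherever actual ET is valid")
  if (any(sol$values < 0, na.rm = TRUE)) stop("solar radiation must be >= 0")
  structure(list(month = as.integer(month), t_mean = t_mean, sol = sol,
                 e_actual = e_actual, e_potential = e_potential),
            class = "meteo_monthly")
}

#' Generate monthly meteorology fields
#'
#' @param spec A [meteo_spec()].
#' @param grid The working [grid_spec()].
#' @param months Months to generate (default June-October).
#' @return Named list of [meteo_monthly()] objects, one per month.
#' @export
make_meteo <- function(spec = meteo_spec(), grid, months = 6:10) {
  stopifnot(inherits(spec, "meteo_spec"), inherits(grid, "grid_spec"))
  rowf <- matrix((seq_len(grid$n_rows) - 0.5) / grid$n_rows - 0.5,
                 grid$n_rows, grid$n_cols)
  colf <- matrix((seq_len(grid$n_cols) - 0.5) / grid$n_cols - 0.5,
                 grid$n_rows, grid$n_cols, byrow = TRUE)
  out <- list()
  for (m in months) {
    key <- as.character(m)
    tm <- spec$t_base + spec$t_amplitude * cos((m - 7) * pi / 6) +
      spec$t_gradient * rowf
    sol <- spec$sol_monthly[[key]] * (1 + spec$sol_gradient_frac * colf)
    pet <- spec$pet_monthly[[key]] * (1 + spec$sol_gradient_frac * colf)
    frac <- pmin(1, pmax(0.05, spec$aet_fraction_monthly[[key]] +
                           spec$aet_gradient * rowf))
    aet <- pet * frac
    out[[key]] <- meteo_monthly(
      m,
      raster_grid(tm, grid, label = sprintf("t_mean_%02d", m)),
      raster_grid(sol, grid, label = sprintf("sol_%02d", m)),
      raster_grid(aet, grid, label = sprintf("aet_%02d", m)),
      raster_grid(pet, grid, label = sprintf("pet_%02d", m))
    )
  }
  out
}

#' Forward-model ground-truth NPP from clean inputs
#'
#' Composes the whole estimation chain - monthly maximum-value composites,
#' per-crop index extrema, dual-index FPAR, optimum temperature, stress
#' scalars, crop-specific light-use efficiency, APAR and NPP - on the
#' uncorrupted fine NDVI series. Running the same chain on cloud-degraded,
#' fused inputs and comparing against this truth is the package's
#' parameter-recovery test.
#'
#' @param fine_series Clean fine NDVI [raster_series()].
#' @param crop_map Categorical crop [raster_grid()].
#' @param meteo List of [meteo_monthly()] from [make_meteo()].
#' @param crop_pars A [crop_params()].
#' @param constants A [fpar_constants()].
#' @param months Growing-season months.
#' @param extrema_scope Passed to [fpar_monthly()].
#' @param trim_percent Percentile trim for [build_extrema_table()]; nonzero
#'   values make the stretch extrema robust to single-pixel outliers.
#' @return List: `monthly` (named list of NPP grids), `seasonal` (grid),
#'   `fpar`, `lue` (named lists), `extrema` (data frame), `topt` (grid).
#' @export
forward_truth_npp <- function(fine_series, crop_map, meteo,
                              crop_pars = crop_params(),
                              constants = fpar_constants(),
                              months = 6:10, extrema_scope = "month",
                              trim_percent = 0) {
  crops <- intersect(unique(as.vector(crop_map$values)),
                     as.numeric(CROP_CODES[c("maize", "rice")]))
  if (length(crops) == 0) {
    stop("crop map contains no parameterized crop pixels")
  }
  composites <- lapply(months, function(m) monthly_composite(fine_series, m))
  names(composites) <- as.character(months)
  extrema <- build_extrema_table(fine_series, crop_map, months = months,
                                 trim_percent = trim_percent,
                                 sr_cap = constants$sr_cap)
  topt <- optimum_temperature(
    composites, lapply(meteo[as.character(months)], function(x) x$t_mean)
  )
  fpar <- list(); lue <- list(); npp <- list()
  t1 <- t_stress_low(topt)
  for (m in months) {
    key <- as.character(m)
    fpar[[key]] <- fpar_monthly(fine_series, crop_map, extrema, m,
                                constants = constants,
                                scope = extrema_scope)
    t2 <- t_stress_high(topt, meteo[[key]]$t_mean)
    w <- w_stress(meteo[[key]]$e_actual, meteo[[key]]$e_potential)
    lue[[key]] <- actual_lue(t1, t2, w, crop_map, crop_pars)
    par <- par_from_sol(meteo[[key]]$sol, crop_pars$par_fraction)
    npp[[key]] <- npp_monthly(apar(par, fpar[[key]]), lue[[key]])
  }
  list(monthly = npp, seasonal = npp_seasonal(npp), fpar = fpar, lue = lue,
       extrema = extrema, topt = topt)
}
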