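small_scene <- function(...) {
  scene_spec(n_rows = 40, n_cols = 40, pixel_size = 10, scale_factor = 4,
             n_fields = 16, ...)
}

test_that("crop_fractions (1, 0, 0) yield an all-maize map", {
  spec <- small_scene(crop_fractions = c(maize = 1, rice = 0, other = 0))
  land <- make_landscape(spec)
  expect_true(all(land$values == CROP_CODES[["maize"]]))
})

test_that("make_landscape is deterministic and tracks requested fractions", {
  spec <- scene_spec(n_rows = 100, n_cols = 100, n_fields = 64,
                     crop_fractions = c(maize = 0.5, rice = 0.5, other = 0))
  l1 <- make_landscape(spec)
  l2 <- make_landscape(spec)
  expect_identical(l1$values, l2$values)
  cropped <- l1$values[l1$values != CROP_CODES[["other"]]]
  share <- mean(cropped == CROP_CODES[["maize"]])
  expect_gte(share, 0.40)
  expect_lte(share, 0.60)
})

test_that("phenology curve: tails, peak, and the closed form at green-up", {
  p <- phenology_params()
  maize <- p[p$crop == "maize", ]
  expect_equal(phenology_ndvi(1, maize$green_up_day - 100),
               maize$base_ndvi, tolerance = 0.011)
  mid <- (maize$green_up_day + maize$senescence_day) / 2
  expect_equal(phenology_ndvi(1, mid), maize$peak_ndvi, tolerance = 0.011)
  # direct evaluation of the double-logistic at the green-up inflection
  expected <- maize$base_ndvi + (maize$peak_ndvi - maize$base_ndvi) *
    (0.5 - stats::plogis(maize$senescence_rate *
                           (maize$green_up_day - maize$senescence_day)))
  expect_equal(phenology_ndvi(1, maize$green_up_day), expected)
  expect_error(phenology_ndvi(99, 180), "unknown crop code")
})

test_that("noise-free render makes all same-crop pixels identical", {
  spec <- small_scene()
  land <- make_landscape(spec)
  ser <- render_fine_series(land, spec, noise_sd = 0, field_amp_sd = 0,
                            field_delay_mean = 0)
  maize <- land$values == CROP_CODES[["maize"]]
  for (g in ser$grids) {
    expect_equal(length(unique(g$values[maize])), 1L)
  }
})

test_that("render is seed-deterministic and matches the curve in the mean", {
  spec <- small_scene()
  land <- make_landscape(spec)
  s1 <- render_fine_series(land, spec)
  s2 <- render_fine_series(land, spec)
  for (k in seq_along(s1$grids)) {
    expect_identical(s1$grids[[k]]$values, s2$grids[[k]]$values)
  }
  # with only pixel noise, the crop mean sits on the phenology curve
  noise_sd <- 0.02
  ser <- render_fine_series(land, spec, noise_sd = noise_sd,
                            field_amp_sd = 0, field_delay_mean = 0)
  maize <- land$values == CROP_CODES[["maize"]]
  peak_idx <- 5 # 2025-08-05
  doy <- as.integer(format(spec$season[peak_idx], "%j"))
  expect_equal(mean(ser$grids[[peak_idx]]$values[maize]),
               phenology_ndvi(1, doy),
               tolerance = 3 * noise_sd / sqrt(sum(maize)))
  expect_true(all(vapply(ser$grids, function(g)
    all(g$values >= -1 & g$values <= 1), logical(1))))
})

test_that("degrade_to_coarse: exact block means, additive bias, determinism", {
  spec <- small_scene()
  land <- make_landscape(spec)
  fine <- render_fine_series(land, spec)
  clean <- degrade_to_coarse(fine, 4, bias = 0, noise_sd = 0)
  expect_equal(clean$grids[[1]]$values,
               aggregate_to_coarse(fine$grids[[1]], 4)$values)
  biased <- degrade_to_coarse(fine, 4, bias = 0.05, noise_sd = 0)
  expect_equal(mean(biased$grids[[1]]$values - clean$grids[[1]]$values), 0.05)
  d1 <- degrade_to_coarse(fine, 4, seed = 9)
  d2 <- degrade_to_coarse(fine, 4, seed = 9)
  expect_identical(d1$grids[[3]]$values, d2$grids[[3]]$values)
})

test_that("cloud masking: zero, total, and targeted gap fractions", {
  g200 <- mk_grid(cmat(0.5, 200, 200))
  dates <- default_season_dates(2025)[1:6]
  ser <- raster_series(dates, rep(list(g200), 6))

  clear <- apply_cloud_mask(ser, cloud_spec(0))
  expect_identical(clear$series$grids[[1]]$values, g200$values)
  expect_true(all(clear$masks$grids[[1]]$values == 0))

  total <- apply_cloud_mask(ser, cloud_spec(1))
  expect_true(all(is.na(total$series$grids[[1]]$values)))

  part <- apply_cloud_mask(ser, cloud_spec(0.3))
  frac <- mean(part$masks$grids[[1]]$values)
  expect_gte(frac, 0.15)
  expect_lte(frac, 0.45)
  # determinism
  part2 <- apply_cloud_mask(ser, cloud_spec(0.3))
  expect_identical(part$masks$grids[[2]]$values, part2$masks$grids[[2]]$values)
})

test_that("meteo: zero gradients give constant fields; July warmer than October; E/P in (0, 1]", {
  grid <- grid_spec(20, 20)
  flat <- make_meteo(meteo_spec(t_gradient = 0, sol_gradient_frac = 0,
                                aet_gradient = 0), grid)
  for (m in names(flat)) {
    for (f in c("t_mean", "sol", "e_actual", "e_potential")) {
      expect_equal(length(unique(as.vector(flat[[m]][[f]]$values))), 1L)
    }
  }
  met <- make_meteo(meteo_spec(), grid)
  expect_true(all(met[["7"]]$t_mean$values > met[["10"]]$t_mean$values))
  for (m in names(met)) {
    ratio <- met[[m]]$e_actual$values / met[[m]]$e_potential$values
    expect_true(all(ratio > 0 & ratio <= 1))
  }
})

test_that("forward_truth_npp rejects a scene without parameterized crops", {
  spec <- small_scene()
  land <- mk_grid(cmat(0, 40, 40), pixel = 10)
  land <- raster_grid(land$values, spec$grid)
  fine <- render_fine_series(land, spec,
                             params = phenology_params())
  met <- make_meteo(meteo_spec(), spec$grid)
  expect_error(forward_truth_npp(fine, land, met),
               "no parameterized crop")
})

test_that("forward_truth_npp is linear in SOL", {
  spec <- small_scene()
  land <- make_landscape(spec)
  fine <- render_fine_series(land, spec)
  met <- make_meteo(meteo_spec(), spec$grid)
  met2 <- lapply(met, function(x) {
    meteo_monthly(x$month, x$t_mean,
                  map_grid(x$sol, function(v) 2 * v),
                  x$e_actual, x$e_potential)
  })
  t1 <- forward_truth_npp(fine, land, met)
  t2 <- forward_truth_npp(fine, land, met2)
  for (key in names(t1$monthly)) {
    expect_equal(t2$monthly[[key]]$values, 2 * t1$monthly[[key]]$values)
  }
  expect_equal(t2$seasonal$values, 2 * t1$seasonal$values)
})

test_that("forward_truth_npp equals the hand-chained model at a probed pixel", {
  spec <- small_scene()
  land <- make_landscape(spec)
  fine <- render_fine_series(land, spec)
  met <- make_meteo(meteo_spec(), spec$grid)
  truth <- forward_truth_npp(fine, land, met)

  idx <- which(land$values == CROP_CODES[["maize"]], arr.ind = TRUE)[1, ]
  r <- idx[1]; c <- idx[2]
  months <- 6:10
  comps <- vapply(months, function(m)
    monthly_composite(fine, m)$values[r, c], numeric(1))
  topt <- met[[as.character(months[which.max(comps)])]]$t_mean$values[r, c]
  expect_equal(truth$topt$values[r, c], topt)
  for (m in months) {
    key <- as.character(m)
    row <- truth$extrema[truth$extrema$code == 1 & truth$extrema$month == m, ]
    nd <- comps[m - 5]
    f_nd <- fpar_linear(nd, row$ndvi_min, row$ndvi_max)
    f_sr <- fpar_linear(sr_from_ndvi(nd), row$sr_min, row$sr_max)
    fp <- fpar_combined(f_nd, f_sr)
    expect_equal(truth$fpar[[key]]$values[r, c], fp)
    lue <- t_stress_low(topt) *
      t_stress_high(topt, met[[key]]$t_mean$values[r, c]) *
      w_stress(met[[key]]$e_actual$values[r, c],
               met[[key]]$e_potential$values[r, c]) * 1.1
    expect_equal(truth$lue[[key]]$values[r, c], lue)
    npp <- 0.5 * met[[key]]$sol$values[r, c] * fp * lue
    expect_equal(truth$monthly[[key]]$values[r, c], npp)
  }
})
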