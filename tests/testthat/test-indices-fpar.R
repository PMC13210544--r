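test_that("NDVI from bands: symmetry, arithmetic, boundary, zero-sum", {
  red <- mk_grid(matrix(c(0.2, 0.1, 0.0, 0.0), 2, 2))
  nir <- mk_grid(matrix(c(0.2, 0.5, 0.5, 0.0), 2, 2))
  nd <- ndvi_from_bands(red, nir)
  expect_equal(nd$values[1, 1], 0)
  expect_equal(nd$values[2, 1], 0.6667, tolerance = 1e-4)
  expect_equal(nd$values[1, 2], 1.0)
  expect_true(is.na(nd$values[2, 2])) # zero band sum
})

test_that("SR from bands and the SR-NDVI algebraic identity", {
  red <- mk_grid(matrix(c(0.2, 0.1), 1, 2))
  nir <- mk_grid(matrix(c(0.2, 0.5), 1, 2))
  sr <- sr_from_bands(red, nir)
  expect_equal(sr$values[1, 1], 1)
  expect_equal(sr$values[1, 2], 5)
  # SR == (1 + NDVI) / (1 - NDVI) from the same bands: 0.6667 <-> 5
  nd <- ndvi_from_bands(red, nir)
  expect_equal(sr_from_ndvi(nd)$values, sr$values)
  # zero red reflectance is nodata
  red0 <- mk_grid(matrix(0, 1, 1))
  expect_true(is.na(sr_from_bands(red0, mk_grid(matrix(0.4, 1, 1)))$values))
})

test_that("sr_from_ndvi: closed form, cap, nodata below -1", {
  expect_equal(sr_from_ndvi(0), 1)
  expect_equal(sr_from_ndvi(0.9), 19, tolerance = 1e-12)
  expect_equal(sr_from_ndvi(1), 30)
  expect_equal(sr_from_ndvi(0.999999999), 30)
  expect_true(is.na(sr_from_ndvi(-1)))
  # round-trip through the identity
  x <- c(-0.5, 0, 0.3, 0.8)
  expect_equal((sr_from_ndvi(x) - 1) / (sr_from_ndvi(x) + 1), x)
})

test_that("monthly_extrema: constants, direct min/max, crop masking", {
  crop <- mk_grid(matrix(c(1, 1, 1, 0), 2, 2))
  s <- mk_series("2025-07-04", list(matrix(c(0.2, 0.5, 0.9, 0.99), 2, 2)))
  ex <- monthly_extrema(s, crop, 1, 7)
  expect_equal(ex, c(min = 0.2, max = 0.9)) # non-crop 0.99 excluded

  s2 <- mk_series("2025-07-04", list(cmat(0.6, 2, 2)))
  expect_equal(monthly_extrema(s2, crop, 1, 7), c(min = 0.6, max = 0.6))
  expect_error(monthly_extrema(s2, crop, 2, 7), "no valid pixels")
})

test_that("monthly_extrema honors percentile trim and the mask series", {
  crop <- mk_grid(matrix(1, 10, 10))
  vals <- matrix(seq(0, 0.99, length.out = 100), 10, 10)
  s <- mk_series("2025-07-04", list(vals))
  ex <- monthly_extrema(s, crop, 1, 7, trim_percent = 10)
  expect_equal(unname(ex), unname(stats::quantile(vals, c(0.1, 0.9))),
               tolerance = 1e-12)

  # masked pixels excluded from the sample
  mask <- matrix(0, 10, 10)
  mask[vals >= 0.9] <- 1
  ms <- mk_series("2025-07-04", list(mask))
  ex2 <- monthly_extrema(s, crop, 1, 7, mask_series = ms)
  expect_lt(ex2[["max"]], 0.9)
  mask_all <- mk_series("2025-07-04", list(matrix(1, 10, 10)))
  expect_error(monthly_extrema(s, crop, 1, 7, mask_series = mask_all),
               "no unmasked pixels")
})

test_that("build_extrema_table covers crops and months with min < max", {
  spec <- scene_spec(n_rows = 30, n_cols = 30, scale_factor = 3,
                     n_fields = 9)
  land <- make_landscape(spec)
  fine <- render_fine_series(land, spec)
  tab <- build_extrema_table(fine, land)
  expect_setequal(tab$crop, c("maize", "rice"))
  expect_setequal(tab$month, 6:10)
  expect_true(all(tab$ndvi_min < tab$ndvi_max))
  expect_true(all(tab$sr_min < tab$sr_max))
  expect_true(all(tab$sr_max <= 30))
})

test_that("fpar_linear: endpoints, midpoint, clipping, degenerate stretch", {
  expect_identical(fpar_linear(0.9, 0.2, 0.9), 0.950)
  expect_identical(fpar_linear(0.2, 0.2, 0.9), 0.001)
  expect_equal(fpar_linear(0.55, 0.2, 0.9), 0.4755)
  # out-of-range values clip rather than extrapolate
  expect_equal(fpar_linear(1.5, 0.2, 0.9), 0.950)
  expect_equal(fpar_linear(-0.5, 0.2, 0.9), 0.001)
  expect_error(fpar_linear(0.5, 0.9, 0.2), "degenerate")
  expect_error(fpar_linear(0.5, 0.5, 0.5), "degenerate")
})

test_that("fpar_linear is monotone in the index", {
  x <- seq(0.2, 0.9, length.out = 50)
  y <- fpar_linear(x, 0.2, 0.9)
  expect_true(all(diff(y) >= 0))
})

test_that("fpar_combined: idempotent mean, arithmetic mean, Table-4 maxima", {
  expect_equal(fpar_combined(0.95, 0.95), 0.95)
  expect_equal(fpar_combined(0.8, 0.6), 0.7)
  # a pixel at both monthly maxima (literature fixture values for maize in
  # July: NDVI 0.917, SR 23.096) stretches to the FPAR ceiling on both
  # paths, so the blend is exactly 0.950
  fix <- read.csv(system.file("extdata", "extrema_fixture.csv",
                              package = "casafuse"))
  row <- fix[fix$crop == "maize" & fix$month == 7, ]
  f_nd <- fpar_linear(row$ndvi_max, row$ndvi_min, row$ndvi_max)
  f_sr <- fpar_linear(row$sr_max, row$sr_min, row$sr_max)
  expect_equal(row$ndvi_max, 0.917)
  expect_equal(row$sr_max, 23.096)
  expect_identical(fpar_combined(f_nd, f_sr), 0.950)
})

test_that("fpar_monthly: uniform ceiling, probed chain, bounds, errors", {
  crop <- mk_grid(matrix(c(1, 1, 2, 2, 1, 1, 2, 2, 0), 3, 3))
  vals <- matrix(c(0.5, 0.6, 0.7, 0.8, 0.55, 0.65, 0.75, 0.85, 0.2), 3, 3)
  s <- mk_series("2025-07-04", list(vals))
  tab <- build_extrema_table(s, crop, months = 7)

  fp <- fpar_monthly(s, crop, tab, 7)
  # probed pixel: hand-chain the two stretches and the blend
  r <- 2; c <- 1
  row <- tab[tab$code == 1 & tab$month == 7, ]
  f_nd <- fpar_linear(vals[r, c], row$ndvi_min, row$ndvi_max)
  f_sr <- fpar_linear(sr_from_ndvi(vals[r, c]), row$sr_min, row$sr_max)
  expect_equal(fp$values[r, c], fpar_combined(f_nd, f_sr))
  # non-crop pixels nodata; valid pixels within the FPAR band
  expect_true(is.na(fp$values[3, 3]))
  v <- fp$values[!is.na(fp$values)]
  expect_true(all(v >= 0.001 & v <= 0.950))

  # all crop pixels at their crop's monthly maximum -> uniform 0.950
  vmax <- matrix(0.2, 3, 3)
  vmax[crop$values == 1] <- tab$ndvi_max[tab$code == 1]
  vmax[crop$values == 2] <- tab$ndvi_max[tab$code == 2]
  smax <- mk_series("2025-07-04", list(vmax))
  fpu <- fpar_monthly(smax, crop, tab, 7)
  expect_equal(fpu$values[!is.na(fpu$values)], rep(0.950, 8))

  # missing extrema for a present crop is an error
  expect_error(fpar_monthly(s, crop, tab[tab$code == 1, ], 7),
               "missing extrema")
})
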