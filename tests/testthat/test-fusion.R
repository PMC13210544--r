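test_that("similar-pixel selection: homogeneous, two-class, unique center", {
  # perfectly homogeneous window: every valid pixel selected
  w <- cmat(0.5, 5, 5)
  sel <- select_similar_pixels(w, c(3, 3), n_classes = 3)
  expect_equal(nrow(sel), 25L)

  # two well-separated classes: center's class only
  w2 <- cmat(0.2, 4, 4)
  w2[, 3:4] <- 0.8
  sel2 <- select_similar_pixels(w2, c(2, 1), n_classes = 2)
  # hand check: sd of {8x0.2, 8x0.8} = 0.3098, thr = 2*sd/2 = 0.3098 < 0.6
  expect_true(all(w2[sel2] == 0.2))
  expect_equal(nrow(sel2), 8L)

  # center unique and threshold tiny: only the center survives
  w3 <- cmat(0.2, 3, 3)
  w3[2, 2] <- 0.9
  sel3 <- select_similar_pixels(w3, c(2, 2), n_classes = 50)
  expect_equal(unname(sel3), matrix(c(2L, 2L), 1, 2))

  # nodata pixels are never selected; nodata center errors
  w4 <- cmat(0.5, 3, 3)
  w4[1, 1] <- NA
  expect_equal(nrow(select_similar_pixels(w4, c(2, 2), 3)), 8L)
  expect_error(select_similar_pixels(w4, c(1, 1), 3), "nodata")
})

test_that("similar-pixel weights: normalization, symmetry, 4/7-2/7-1/7", {
  fine <- cmat(0.5, 3, 3)
  coarse <- cmat(0.5, 3, 3)
  # single similar pixel: weight one
  expect_equal(similar_pixel_weights(matrix(c(2L, 2L), 1, 2), c(2, 2),
                                     fine, coarse, 1), 1)
  # two pixels with identical D*S: equal halves
  sim <- rbind(c(2L, 1L), c(2L, 3L))
  expect_equal(similar_pixel_weights(sim, c(2, 2), fine, coarse, 1),
               c(0.5, 0.5))
  # constructed D*S of 1, 2, 4 -> weights 4/7, 2/7, 1/7:
  # fine == coarse everywhere (S = 1) on a 1x4 window, center (1, 1),
  # half size 1 -> D = 1 + dist = 1, 2, 4 at distances 0, 1, 3
  fine1 <- matrix(0.5, 1, 4)
  sim3 <- cbind(1L, c(1L, 2L, 4L))
  w <- similar_pixel_weights(sim3, c(1, 1), fine1, fine1, 1)
  expect_equal(w, c(4, 2, 1) / 7)
  expect_equal(sum(w), 1)
  expect_error(similar_pixel_weights(sim3[0, , drop = FALSE], c(1, 1),
                                     fine1, fine1, 1), "empty")
})

test_that("conversion coefficient: identity, exact line, degeneracies", {
  prm <- fusion_params(regression_min_points = 5, regression_min_r2 = 0.2)
  x <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  expect_equal(conversion_coefficient(x, x, prm), 1)
  expect_equal(conversion_coefficient(2 * x + 0.1, x, prm), 2)
  # zero coarse variance -> fallback
  expect_equal(conversion_coefficient(x, rep(0.4, 5), prm), 1)
  # too few points -> fallback
  expect_equal(conversion_coefficient(2 * x[1:3] + 0.1, x[1:3], prm), 1)
  # negative slope -> fallback
  expect_equal(conversion_coefficient(rev(x), x, prm), 1)
  # uncorrelated noise (r^2 below the floor) -> fallback
  y <- c(0.5, 0.2, 0.6, 0.3, 0.5, 0.4, 0.2, 0.6)
  xr <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  r2 <- stats::cor(xr, y)^2
  expect_lt(r2, 0.2)
  expect_equal(conversion_coefficient(y, xr, prm), 1)
})

test_that("prediction identity: unchanged coarse returns the fine reference", {
  set.seed(11)
  f1 <- mk_grid(matrix(runif(100, 0.1, 0.9), 10, 10))
  c1 <- mk_grid(matrix(runif(100, 0.1, 0.9), 10, 10))
  pair <- reference_pair(f1, c1, "2025-06-02")
  out <- predict_single_pair(pair, c1, fusion_params(window_half_size = 3))
  expect_equal(out$values, f1$values)
})

test_that("homogeneous scene + uniform coarse offset shifts by the offset", {
  f1 <- mk_grid(cmat(0.4, 8, 8))
  c1 <- mk_grid(cmat(0.4, 8, 8))
  c2 <- mk_grid(cmat(0.5, 8, 8))
  pair <- reference_pair(f1, c1, "2025-06-02")
  out <- predict_single_pair(pair, c2, fusion_params(window_half_size = 2))
  expect_equal(out$values, cmat(0.5, 8, 8), tolerance = 1e-8)
})

test_that("5x5 toy prediction matches the brute-force oracle", {
  set.seed(12)
  f1 <- mk_grid(matrix(runif(25, 0.1, 0.9), 5, 5))
  c1 <- mk_grid(matrix(runif(25, 0.1, 0.9), 5, 5))
  c2 <- mk_grid(matrix(runif(25, 0.1, 0.9), 5, 5))
  prm <- fusion_params(window_half_size = 2, n_classes = 2,
                       regression_min_points = 4)
  pair <- reference_pair(f1, c1, "2025-06-02")
  out <- predict_single_pair(pair, c2, prm)
  expect_equal(out$values, oracle_predict(pair, c2, prm), tolerance = 1e-10)
})

test_that("pooled two-pair kernel path matches the oracle", {
  set.seed(13)
  mk <- function() mk_grid(matrix(runif(49, 0.1, 0.9), 7, 7))
  f1 <- mk(); c1 <- mk(); f2 <- mk(); c2r <- mk(); ct <- mk()
  f2$values[3, 4] <- NA # exercise per-pixel dual-selection fallback
  prm <- fusion_params(window_half_size = 3, n_classes = 2,
                       regression_min_points = 4)
  p1 <- reference_pair(f1, c1, "2025-06-02")
  p2 <- reference_pair(f2, c2r, "2025-07-04")
  out <- predict_single_pair(p1, ct, prm, pool_pair = p2)
  expect_equal(out$values, oracle_predict(p1, ct, prm, pool_pair = p2),
               tolerance = 1e-10)
})

test_that("prediction respects nodata centers, targets and bounds", {
  set.seed(14)
  f1 <- mk_grid(matrix(runif(36, 0.1, 0.9), 6, 6))
  f1$values[2, 2] <- NA
  c1 <- mk_grid(matrix(runif(36, 0.1, 0.9), 6, 6))
  c2 <- mk_grid(matrix(runif(36, -1, 1), 6, 6))
  pair <- reference_pair(f1, c1, "2025-06-02")
  tgt <- matrix(FALSE, 6, 6); tgt[, 1:3] <- TRUE
  out <- predict_single_pair(pair, c2, fusion_params(window_half_size = 2),
                             target = tgt)
  expect_true(is.na(out$values[2, 2]))
  expect_true(all(is.na(out$values[, 4:6])))
  v <- out$values[!is.na(out$values)]
  expect_true(all(v >= -1 & v <= 1))
})

test_that("two-pair blending: degenerate and limiting weights", {
  set.seed(15)
  f1 <- mk_grid(matrix(runif(64, 0.2, 0.8), 8, 8))
  c1 <- mk_grid(matrix(runif(64, 0.2, 0.8), 8, 8))
  prm <- fusion_params(window_half_size = 2)
  pair <- reference_pair(f1, c1, "2025-06-02")
  c2 <- mk_grid(matrix(runif(64, 0.2, 0.8), 8, 8))

  # pair2 identical to pair1: equals the single-pair prediction
  both <- predict_two_pair(pair, pair, c2, prm)
  single <- predict_single_pair(pair, c2, prm, pool_pair = pair)
  expect_equal(both$values, single$values)

  # coarse_t2 equal to pair1's coarse but not pair2's: pair1 dominates
  f2 <- mk_grid(matrix(runif(64, 0.2, 0.8), 8, 8))
  c2r <- mk_grid(matrix(runif(64, 0.2, 0.8), 8, 8))
  pair2 <- reference_pair(f2, c2r, "2025-07-04")
  out <- predict_two_pair(pair, pair2, c1, prm)
  p1_only <- predict_single_pair(pair, c1, prm, pool_pair = pair2)
  expect_equal(out$values, p1_only$values, tolerance = 1e-6)

  # both coarse references equal to coarse_t2: average of the two fines
  pair_b <- reference_pair(f2, c1, "2025-07-04")
  avg <- predict_two_pair(pair, pair_b, c1, prm)
  expect_equal(avg$values, (f1$values + f2$values) / 2, tolerance = 1e-8)
})

test_that("fuse_series: gap-free input, bracketed fill, edge single mode", {
  spec <- scene_spec(n_rows = 30, n_cols = 30, scale_factor = 3,
                     n_fields = 9, season = default_season_dates(2025)[1:6])
  land <- make_landscape(spec)
  fine <- render_fine_series(land, spec)
  coarse <- degrade_to_coarse(fine, 3, seed = 5)
  prm <- fusion_params(window_half_size = 5, n_classes = 3)

  # no gaps anywhere: output identical, every mode "clear"
  res0 <- fuse_series(fine, coarse, prm)
  expect_true(all(res0$report$mode == "clear"))
  expect_equal(res0$report$n_filled, rep(0L, 6))
  for (k in 1:6) {
    expect_identical(res0$series$grids[[k]]$values, fine$grids[[k]]$values)
  }

  # one fully clouded date bracketed by clear dates: filled completely
  gapped <- fine
  gapped$grids[[3]] <- raster_grid(matrix(NA_real_, 30, 30), fine$grids[[3]]$spec)
  res1 <- fuse_series(gapped, coarse, prm)
  expect_equal(n_nodata(res1$series$grids[[3]]), 0L)
  expect_equal(res1$report$mode[3], "double")
  expect_equal(res1$report$ref1[3], fine$dates[2])
  expect_equal(res1$report$ref2[3], fine$dates[4])
  expect_equal(res1$report$n_filled[3], 900L)
  # clear pixels kept verbatim on other dates
  expect_identical(res1$series$grids[[1]]$values, fine$grids[[1]]$values)

  # gap at the final date: single-pair mode from the nearest earlier date
  gapped2 <- fine
  v <- gapped2$grids[[6]]$values
  v[1:10, 1:10] <- NA
  gapped2$grids[[6]] <- raster_grid(v, fine$grids[[6]]$spec)
  res2 <- fuse_series(gapped2, coarse, prm)
  expect_equal(res2$report$mode[6], "single")
  expect_equal(res2$report$ref1[6], fine$dates[5])
  expect_equal(n_nodata(res2$series$grids[[6]]), 0L)
  # untouched pixels kept verbatim
  expect_identical(res2$series$grids[[6]]$values[11:30, ],
                   fine$grids[[6]]$values[11:30, ])
})

test_that("fuse_series errors when no reference date is cloud-acceptable", {
  g <- matrix(NA_real_, 10, 10)
  spec <- grid_spec(10, 10)
  dates <- default_season_dates(2025)[1:6]
  fine <- raster_series(dates, rep(list(raster_grid(g, spec)), 6))
  coarse <- raster_series(dates, rep(list(raster_grid(cmat(0.5, 10, 10),
                                                      spec)), 6))
  expect_error(fuse_series(fine, coarse, fusion_params(window_half_size = 2)),
               "no cloud-acceptable reference")
})
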