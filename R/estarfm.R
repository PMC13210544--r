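#' ESTARFM fusion controls
#'
#' @param window_half_size Half-size of the moving window in fine pixels;
#'   the window is `(2h+1)^2`. Default 15 (a 31x31 window); smaller windows
#'   can work better when the landscape's patches are small relative to the
#'   window (see [pipeline_config()]).
#' @param n_classes Number of spectral classes assumed inside a window; the
#'   similar-pixel threshold is `2*sd/n_classes`.
#' @param min_similar Minimum similar-pixel count below which the prediction
#'   falls back to propagating the coarse change at the center pixel.
#' @param pair_mode `"double"` to combine two bracketing reference pairs
#'   with temporal weights where available, `"single"` to always use the
#'   nearest clear pair.
#' @param regression_min_points Minimum similar pixels for the conversion
#'   coefficient regression; below it, `V = 1`.
#' @param regression_min_r2 Minimum squared fine/coarse correlation for the
#'   regression to be trusted; below it the mixed-pixel decomposition is
#'   uninformative (a slope fitted to noise alone) and `V = 1`.
#' @return An object of class `fusion_params`.
#' @export
fusion_params <- function(window_half_size = 15, n_classes = 3,
                          min_similar = 1, pair_mode = c("double", "single"),
                          regression_min_points = 5,
                          regression_min_r2 = 0.2) {
  pair_mode <- match.arg(pair_mode)
  stopifnot(window_half_size >= 1, n_classes >= 1, min_similar >= 1,
            regression_min_points >= 2,
            regression_min_r2 >= 0, regression_min_r2 <= 1)
  structure(
    list(window_half_size = as.integer(window_half_size),
         n_classes = as.integer(n_classes),
         min_similar = as.integer(min_similar),
         pair_mode = pair_mode,
         regression_min_points = as.integer(regression_min_points),
         regression_min_r2 = regression_min_r2),
    class = "fusion_params"
  )
}

#' A fine/coarse reference pair at one date
#'
#' @param fine Fine-resolution [raster_grid()] at the reference date.
#' @param coarse Coarse image at the same date, already resampled to the
#'   fine grid (see [resample_bilinear()]).
#' @param date Reference date.
#' @return An object of class `reference_pair`.
#' @export
reference_pair <- function(fine, coarse, date) {
  stopifnot(inherits(fine, "raster_grid"), inherits(coarse, "raster_grid"))
  if (!spec_compatible(fine$spec, coarse$spec)) {
    stop("reference pair grids are not on the same grid")
  }
  structure(list(fine = fine, coarse = coarse, date = as.Date(date)),
            class = "reference_pair")
}

#' Select spectrally similar pixels within a window
#'
#' Pixels whose fine-reference value lies within `2*sd/n_classes` of the
#' center pixel's value, where `sd` is taken over the valid pixels of the
#' window. The center is always included; nodata pixels never are.
#'
#' @param fine_window Numeric matrix (the window cut from the fine image).
#' @param center `c(row, col)` of the center pixel within the window.
#' @param n_classes Class count controlling the threshold.
#' @return Two-column integer matrix of (row, col) indices into the window.
#' @export
select_similar_pixels <- function(fine_window, center, n_classes) {
  stopifnot(is.matrix(fine_window), length(center) == 2)
  fc <- fine_window[center[1], center[2]]
  if (is.na(fc)) stop("center pixel is nodata")
  vals <- fine_window[!is.na(fine_window)]
  sdw <- if (length(vals) > 1) stats::sd(vals) else 0
  thr <- 2 * sdw / n_classes
  ok <- !is.na(fine_window) & abs(fine_window - fc) <= thr
  ok[center[1], center[2]] <- TRUE
  which(ok, arr.ind = TRUE)
}

#' Weights of similar pixels
#'
#' `W_i` is proportional to `1 / (D_i * S_i)` with the normalised spatial
#' distance `D_i = 1 + dist(p, center) / window_half_size` and the spectral
#' fine/coarse difference `S_i = 1 + |fine(p) - coarse(p)|`, normalised to
#' sum to one.
#'
#' @param similar Two-column (row, col) matrix from
#'   [select_similar_pixels()].
#' @param center `c(row, col)` of the center pixel.
#' @param fine_window,coarse_window_t1 Matrices of fine and coarse reference
#'   values on the window.
#' @param window_half_size Normalising length for the distance term.
#' @return Numeric vector of weights summing to one.
#' @export
similar_pixel_weights <- function(similar, center, fine_window,
                                  coarse_window_t1,
                                  window_half_size = max(dim(fine_window)) %/% 2) {
  if (is.null(dim(similar))) similar <- matrix(similar, ncol = 2)
  if (nrow(similar) == 0) stop("empty similar-pixel set")
  d <- sqrt((similar[, 1] - center[1])^2 + (similar[, 2] - center[2])^2)
  D <- 1 + d / window_half_size
  S <- 1 + abs(fine_window[similar] - coarse_window_t1[similar])
  w <- 1 / (D * S)
  w / sum(w)
}

#' Conversion coefficient relating coarse change to fine change
#'
#' The least-squares slope of fine reference values on coarse reference
#' values over the similar pixels (pooled across the reference pairs when
#' two are available). The regression is abandoned in favour of `V = 1`
#' when it is degenerate: fewer than `regression_min_points` points, coarse
#' sample variance below 1e-8, a slope outside `(0, 5]`, or a squared
#' fine/coarse correlation below `regression_min_r2` (a slope carried by
#' noise alone would attenuate the temporal change).
#'
#' @param fine_vals,coarse_vals Paired fine/coarse values at similar
#'   pixels, pooled across reference pairs.
#' @param params A [fusion_params()].
#' @return A single conversion coefficient `V`.
#' @export
conversion_coefficient <- function(fine_vals, coarse_vals,
                                   params = fusion_params()) {
  ok <- !is.na(fine_vals) & !is.na(coarse_vals)
  x <- coarse_vals[ok]; y <- fine_vals[ok]
  n <- length(x)
  if (n < params$regression_min_points) return(1)
  vx <- stats::var(x); vy <- stats::var(y)
  if (!is.finite(vx) || vx < 1e-8) return(1)
  cxy <- stats::cov(x, y)
  slope <- cxy / vx
  r2 <- if (vy > 0) cxy^2 / (vx * vy) else 0
  if (slope > 0 && slope <= 5 && r2 >= params$regression_min_r2) slope else 1
}

#' Predict a fine image at the target date from one reference pair
#'
#' The moving-window prediction
#' `F(x0, t2) = F(x0, t1) + sum_i W_i V (C(xi, t2) - C(xi, t1))`, with
#' similar-pixel selection, inverse distance-and-spectral-difference
#' weights, and a regression-based conversion coefficient (see
#' [select_similar_pixels()], [similar_pixel_weights()],
#' [conversion_coefficient()]). Output is clipped to `[-1, 1]`; centers that
#' are nodata in the fine reference stay nodata; windows truncate at the
#' border.
#'
#' @param pair A [reference_pair()] (coarse already on the fine grid).
#' @param coarse_t2 Coarse image at the target date, on the fine grid.
#' @param params A [fusion_params()].
#' @param target Optional logical matrix: predict only where `TRUE`
#'   (other cells are returned as nodata). Default: everywhere.
#' @param pool_pair Optional second [reference_pair()] whose values at the
#'   similar pixels are pooled into the conversion-coefficient regression
#'   (used by [predict_two_pair()]).
#' @return A [raster_grid()] with the predicted fine image.
#' @export
predict_single_pair <- function(pair, coarse_t2, params = fusion_params(),
                                target = NULL, pool_pair = NULL) {
  stopifnot(inherits(pair, "reference_pair"),
            inherits(coarse_t2, "raster_grid"))
  if (!spec_compatible(pair$fine$spec, coarse_t2$spec)) {
    stop("coarse target image is not on the fine grid")
  }
  spec <- pair$fine$spec
  if (is.null(target)) {
    target <- matrix(TRUE, spec$n_rows, spec$n_cols)
  }
  stopifnot(is.logical(target),
            nrow(target) == spec$n_rows, ncol(target) == spec$n_cols)
  empty <- matrix(numeric(0), 0, 0)
  pf <- if (is.null(pool_pair)) empty else pool_pair$fine$values
  pc <- if (is.null(pool_pair)) empty else pool_pair$coarse$values
  out <- estarfm_predict_cpp(
    pair$fine$values, pair$coarse$values, coarse_t2$values,
    params$window_half_size, params$n_classes, params$min_similar,
    params$regression_min_points, params$regression_min_r2, target, pf, pc
  )
  raster_grid(out, spec, label = paste0("estarfm_", coarse_t2$label))
}

# internal: truncated-window box sum via a summed-area table
box_sum <- function(m, h) {
  m0 <- ifelse(is.na(m), 0, m)
  nr <- nrow(m0); nc <- ncol(m0)
  sat <- apply(apply(m0, 2, cumsum), 1, cumsum) # transposed SAT
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  r1 <- pmax(seq_len(nr) - h, 1); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1); c2 <- pmin(seq_len(nc) + h, nc)
  S <- sat[r2 + 1, c2 + 1, drop = FALSE] - sat[r1, c2 + 1, drop = FALSE] -
    sat[r2 + 1, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]
  S
}

#' Predict a fine image from two bracketing reference pairs
#'
#' Runs [predict_single_pair()] from each pair and blends the two
#' predictions with per-pixel temporal weights
#' `T_k ~ 1 / |sum_window C(t1_k) - sum_window C(t2)|`: the reference whose
#' coarse neighbourhood looks more like the target date dominates. When both
#' differences vanish (below 1e-8) the predictions are averaged equally.
#'
#' @param pair1,pair2 [reference_pair()] objects.
#' @inheritParams predict_single_pair
#' @return A [raster_grid()].
#' @export
predict_two_pair <- function(pair1, pair2, coarse_t2,
                             params = fusion_params(), target = NULL) {
  p1 <- predict_single_pair(pair1, coarse_t2, params, target,
                            pool_pair = pair2)
  p2 <- predict_single_pair(pair2, coarse_t2, params, target,
                            pool_pair = pair1)
  h <- params$window_half_size
  s2 <- box_sum(coarse_t2$values, h)
  d1 <- abs(box_sum(pair1$coarse$values, h) - s2)
  d2 <- abs(box_sum(pair2$coarse$values, h) - s2)
  eps <- 1e-8
  both_zero <- d1 < eps & d2 < eps
  w1 <- ifelse(both_zero, 0.5,
               ifelse(d1 < eps, 1,
                      ifelse(d2 < eps, 0,
                             (1 / d1) / (1 / d1 + 1 / d2))))
  v1 <- p1$values; v2 <- p2$values
  out <- w1 * v1 + (1 - w1) * v2
  out[is.na(v1)] <- v2[is.na(v1)]
  out[is.na(v2)] <- v1[is.na(v2)]
  out <- pmin(pmax(out, -1), 1)
  raster_grid(out, p1$spec, label = p1$label)
}

#' Fill cloud gaps in a fine NDVI series by spatiotemporal fusion
#'
#' For every date whose fine image has nodata gaps, the gap pixels are
#' predicted from the nearest reference date on each side with a gap
#' fraction at most `max_ref_gap` - a two-pair prediction when such dates
#' bracket the target (and `pair_mode = "double"`), else a single-pair
#' prediction from the nearest eligible date (ties broken towards the
#' earlier date). Reference clouds are handled per pixel: where a
#' reference is itself nodata its prediction is nodata there, the two-pair
#' blend falls back to the other pair, and pixels neither primary
#' reference can predict are filled from the remaining eligible dates in
#' order of temporal distance. Clear pixels of the original image are kept
#' verbatim. Coarse images are resampled to the fine grid bilinearly when
#' they arrive on their native coarse grid.
#'
#' @param fine_series [raster_series()] of fine NDVI with gaps as nodata.
#' @param coarse_series [raster_series()] of coarse NDVI covering every fine
#'   date (same dates).
#' @param params A [fusion_params()].
#' @param max_ref_gap Largest gap fraction a date may have and still serve
#'   as a reference. The permissive default keeps nearby partly-clouded
#'   dates eligible: because cloud positions are largely independent
#'   between dates, a near date that is clear at the target pixel predicts
#'   far better than a fully clear but temporally distant one.
#' @return A list with `series` (the gap-free [raster_series()]) and
#'   `report` (a data frame: date, mode, reference date(s), pixels filled).
#' @export
fuse_series <- function(fine_series, coarse_series, params = fusion_params(),
                        max_ref_gap = 0.6) {
  stopifnot(inherits(fine_series, "raster_series"),
            inherits(coarse_series, "raster_series"))
  if (!identical(as.character(fine_series$dates),
                 as.character(coarse_series$dates))) {
    stop("fine and coarse series must cover the same dates")
  }
  fspec <- fine_series$grids[[1]]$spec
  coarse_on_fine <- lapply(coarse_series$grids, function(g) {
    if (spec_compatible(g$spec, fspec)) g else resample_bilinear(g, fspec)
  })
  gaps <- vapply(fine_series$grids, n_nodata, integer(1))
  gap_frac <- gaps / (fspec$n_rows * fspec$n_cols)
  out <- fine_series$grids
  rep_rows <- list()
  for (i in seq_along(out)) {
    if (gaps[i] == 0) {
      rep_rows[[i]] <- data.frame(
        date = fine_series$dates[i], mode = "clear",
        ref1 = as.Date(NA), ref2 = as.Date(NA),
        n_filled = 0L,
        fraction_filled = 0,
        stringsAsFactors = FALSE
      )
      next
    }
    acceptable <- setdiff(which(gap_frac <= max_ref_gap), i)
    if (length(acceptable) == 0) {
      stop("no cloud-acceptable reference date in the fine series")
    }
    dd <- abs(as.numeric(fine_series$dates[acceptable] -
                           fine_series$dates[i]))
    acceptable <- acceptable[order(dd, fine_series$dates[acceptable])]
    gap_mask <- is.na(out[[i]]$values)
    t2c <- coarse_on_fine[[i]]
    make_pair <- function(j) {
      reference_pair(fine_series$grids[[j]], coarse_on_fine[[j]],
                     fine_series$dates[j])
    }
    before <- acceptable[acceptable < i]
    after <- acceptable[acceptable > i]
    if (length(before) > 0 && length(after) > 0 &&
        params$pair_mode == "double") {
      i1 <- max(before); i2 <- min(after)
      pr <- predict_two_pair(make_pair(i1), make_pair(i2), t2c, params,
                             target = gap_mask)
      mode <- "double"
      r1 <- fine_series$dates[i1]; r2 <- fine_series$dates[i2]
      used <- c(i1, i2)
    } else {
      iref <- acceptable[1]
      pr <- predict_single_pair(make_pair(iref), t2c, params,
                                target = gap_mask)
      mode <- "single"
      r1 <- fine_series$dates[iref]; r2 <- as.Date(NA)
      used <- iref
    }
    v <- out[[i]]$values
    fill <- gap_mask & !is.na(pr$values)
    v[fill] <- pr$values[fill]
    # residual gaps (reference nodata at the center): next references in turn
    for (j in setdiff(acceptable, used)) {
      remaining <- gap_mask & is.na(v)
      if (!any(remaining)) break
      pr2 <- predict_single_pair(make_pair(j), t2c, params,
                                 target = remaining)
      fill <- remaining & !is.na(pr2$values)
      v[fill] <- pr2$values[fill]
    }
    out[[i]] <- raster_grid(v, fspec, label = out[[i]]$label)
    rep_rows[[i]] <- data.frame(
      date = fine_series$dates[i], mode = mode, ref1 = r1, ref2 = r2,
      n_filled = sum(gap_mask & !is.na(v)),
      fraction_filled = mean(gap_mask),
      stringsAsFactors = FALSE
    )
  }
  list(
    series = raster_series(fine_series$dates, out),
    report = do.call(rbind, rep_rows)
  )
}
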