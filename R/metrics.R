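#' A paired observed/predicted sample
#'
#' @param observed,predicted Equal-length numeric vectors; pairs with a
#'   missing member are dropped.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  ok <- !is.na(observed) & !is.na(predicted)
  structure(list(observed = observed[ok], predicted = predicted[ok],
                 n = sum(ok)),
            class = "paired_sample")
}

#' Coefficient of determination
#'
#' `1 - SSres/SStot` against the observed mean; may be negative when the
#' predictions do worse than that mean.
#'
#' @param s A [paired_sample()] with `n >= 2` and nonconstant observations.
#' @return R-squared.
#' @export
r_squared <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  if (s$n < 2) stop("need at least 2 pairs for R-squared")
  sstot <- sum((s$observed - mean(s$observed))^2)
  if (sstot == 0) stop("observed values have zero variance")
  1 - sum((s$observed - s$predicted)^2) / sstot
}

#' Mean absolute error
#' @param s A [paired_sample()] with `n >= 1`.
#' @return MAE, in the units of the data.
#' @export
mae <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  if (s$n < 1) stop("empty sample")
  mean(abs(s$observed - s$predicted))
}

#' Mean absolute percentage error
#'
#' `100 * mean(|y - yhat| / |y|)` over pairs with a nonzero observation;
#' zero-observed pairs are excluded (the ratio is undefined) and their
#' count reported via a message.
#'
#' @param s A [paired_sample()].
#' @return MAPE in percent.
#' @export
mape <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  keep <- s$observed != 0
  dropped <- sum(!keep)
  if (sum(keep) == 0) stop("all observed values are zero; MAPE undefined")
  if (dropped > 0) {
    message("mape: excluded ", dropped, " pair(s) with observed == 0")
  }
  100 * mean(abs(s$observed[keep] - s$predicted[keep]) /
               abs(s$observed[keep]))
}

#' Root mean square error
#' @param s A [paired_sample()] with `n >= 1`.
#' @return RMSE, in the units of the data.
#' @export
rmse <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  if (s$n < 1) stop("empty sample")
  sqrt(mean((s$observed - s$predicted)^2))
}

#' All four accuracy metrics at once
#'
#' @param s A [paired_sample()].
#' @return Data frame with `r2`, `mae`, `mape_percent`, `rmse`, `n`.
#' @export
eval_report <- function(s) {
  data.frame(r2 = r_squared(s), mae = mae(s),
             mape_percent = suppressMessages(mape(s)), rmse = rmse(s),
             n = s$n)
}

#' Randomly sample validation points from a raster pair
#'
#' Draws `n_points` distinct pixels uniformly without replacement from the
#' cells valid in both rasters, for the random-point validation protocol.
#'
#' @param reference,test Compatible [raster_grid()]s.
#' @param n_points Number of points to draw.
#' @param seed Seed making the draw reproducible.
#' @return A [paired_sample()] (`observed` = reference, `predicted` =
#'   test).
#' @export
sample_validation_points <- function(reference, test, n_points, seed = 1) {
  stopifnot(inherits(reference, "raster_grid"),
            inherits(test, "raster_grid"))
  if (!spec_compatible(reference$spec, test$spec)) stop("incompatible grids")
  valid <- which(!is.na(reference$values) & !is.na(test$values))
  if (length(valid) < n_points) {
    stop("only ", length(valid), " jointly valid pixels; requested ",
         n_points)
  }
  idx <- withr::with_seed(seed, sample(valid, n_points))
  paired_sample(reference$values[idx], test$values[idx])
}
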