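# Small fixture builders shared across test files, plus one memoised
# end-to-end pipeline run reused by the acceptance tests.

# a raster_grid on a trivial local spec
mk_grid <- function(values, pixel = 1, crs = NA_character_) {
  values <- as.matrix(values)
  spec <- grid_spec(nrow(values), ncol(values),
                    pixel_size_x = pixel, pixel_size_y = -pixel,
                    crs_id = crs)
  raster_grid(values, spec)
}

# a raster_series from a list of plain matrices on one spec
mk_series <- function(dates, mats, pixel = 1) {
  grids <- lapply(mats, mk_grid, pixel = pixel)
  raster_series(as.Date(dates), grids)
}

# constant matrix shorthand
cmat <- function(v, nr, nc = nr) matrix(v, nr, nc)

# Memoised default pipeline run (default scene, seed 42, no raster output).
# Run once, shared by the end-to-end acceptance tests; elapsed time is kept
# for the runtime criterion.
.default_run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.default_run_cache$res)) {
    t0 <- proc.time()[["elapsed"]]
    res <- run_pipeline(pipeline_config(write_rasters = FALSE))
    .default_run_cache$elapsed <- proc.time()[["elapsed"]] - t0
    .default_run_cache$res <- res
  }
  .default_run_cache$res
}
default_run_elapsed <- function() {
  default_run()
  .default_run_cache$elapsed
}

# Crop-mean FPAR per month from a pipeline result, for one crop code.
crop_mean_fpar <- function(res, code, months = 6:10) {
  vapply(as.character(months), function(key) {
    sel <- !is.na(res$landscape$values) & res$landscape$values == code
    mean(res$fpar[[key]]$values[sel], na.rm = TRUE)
  }, numeric(1))
}
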