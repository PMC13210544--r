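#' Read a single-band georeferenced raster
#'
#' Reads an ESRI ASCII Grid (`.asc`): a plain-text, single-band raster format
#' whose header carries the grid georeferencing (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`). A `.prj` sidecar
#' next to the file, when present, supplies the CRS identifier. Cells equal
#' to the nodata sentinel (or non-finite when the sentinel is `NaN`) are
#' returned as `NA`.
#'
#' @param path Path to an existing `.asc` file.
#' @return A [raster_grid()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  head_lines <- readLines(path, n = 6L, warn = FALSE)
  if (length(head_lines) < 6L) {
    stop("not a georeferenced ASCII raster (header too short): ", path)
  }
  keys <- tolower(vapply(strsplit(trimws(head_lines), "\\s+"),
                         `[`, character(1), 1))
  vals <- suppressWarnings(as.numeric(
    vapply(strsplit(trimws(head_lines), "\\s+"), `[`, character(1), 2)
  ))
  expected <- c("ncols", "nrows", "xllcorner", "yllcorner",
                "cellsize", "nodata_value")
  if (!identical(keys, expected) || anyNA(vals[1:5])) {
    stop("not a georeferenced ASCII raster (bad header): ", path)
  }
  nc <- as.integer(vals[1]); nr <- as.integer(vals[2])
  cell <- vals[5]
  nodata <- vals[6] # NA here means the sentinel is NaN ("nan" in the file)
  body <- scan(path, what = double(), skip = 6L, quiet = TRUE, na.strings =
                 c("nan", "NaN", "NA"))
  if (length(body) != nr * nc) {
    stop("raster body has ", length(body), " values, expected ", nr * nc)
  }
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if (is.na(nodata)) {
    nodata <- NaN
    m[!is.finite(m)] <- NA
  } else {
    m[!is.na(m) & m == nodata] <- NA
  }
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  crs <- if (file.exists(prj)) readLines(prj, n = 1L, warn = FALSE) else NA_character_
  spec <- grid_spec(
    n_rows = nr, n_cols = nc,
    origin_x = vals[3], origin_y = vals[4] + nr * cell,
    pixel_size_x = cell, pixel_size_y = -cell,
    crs_id = crs, nodata = nodata
  )
  raster_grid(m, spec, label = basename(path))
}

#' Write a raster as an ESRI ASCII Grid
#'
#' `NA` cells are written as the spec's nodata sentinel. When `crs_id` is set
#' it is written to a `.prj` sidecar. The format requires square pixels.
#'
#' @param grid A [raster_grid()].
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  spec <- grid$spec
  if (abs(abs(spec$pixel_size_y) - spec$pixel_size_x) > 1e-12) {
    stop("ASCII Grid output requires square pixels")
  }
  nodata <- spec$nodata
  nodata_str <- if (is.nan(nodata)) "nan" else sprintf("%.10g", nodata)
  hdr <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_x),
    sprintf("yllcorner %.10g", spec$origin_y + spec$n_rows * spec$pixel_size_y),
    sprintf("cellsize %.10g", spec$pixel_size_x),
    sprintf("NODATA_value %s", nodata_str)
  )
  v <- grid$values
  chr <- sprintf("%.9g", v)
  chr[is.na(v)] <- nodata_str
  rows <- apply(matrix(chr, nrow = spec$n_rows), 1, paste, collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  if (!is.na(spec$crs_id)) {
    writeLines(spec$crs_id, paste0(tools::file_path_sans_ext(path), ".prj"))
  }
  invisible(path)
}

#' Resample a raster onto a target grid
#'
#' `nearest` assigns each target cell the source cell containing its center;
#' `mean` averages the source cells whose centers fall inside each target
#' cell (nodata-aware). Target cells outside the source footprint, or with no
#' contributing source cell, are nodata. Reprojection is refused: both grids
#' must share a CRS (or both have none).
#'
#' @param src A [raster_grid()].
#' @param target A [grid_spec()].
#' @param method `"nearest"` or `"mean"`.
#' @return A [raster_grid()] on `target`.
#' @export
align_to_grid <- function(src, target, method = c("nearest", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(src, "raster_grid"), inherits(target, "grid_spec"))
  s <- src$spec
  if (!identical(is.na(s$crs_id), is.na(target$crs_id)) ||
      (!is.na(s$crs_id) && s$crs_id != target$crs_id)) {
    stop("CRS mismatch: align_to_grid does not reproject")
  }
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  if (method == "nearest") {
    tx <- cell_centers_x(target)
    ty <- cell_centers_y(target)
    sc <- floor((tx - s$origin_x) / s$pixel_size_x) + 1L
    sr <- floor((ty - s$origin_y) / s$pixel_size_y) + 1L
    okc <- sc >= 1L & sc <= s$n_cols
    okr <- sr >= 1L & sr <= s$n_rows
    out[okr, okc] <- src$values[sr[okr], sc[okc], drop = FALSE]
  } else {
    sx <- cell_centers_x(s)
    sy <- cell_centers_y(s)
    tc <- floor((sx - target$origin_x) / target$pixel_size_x) + 1L
    tr <- floor((sy - target$origin_y) / target$pixel_size_y) + 1L
    okc <- tc >= 1L & tc <= target$n_cols
    okr <- tr >= 1L & tr <= target$n_rows
    v <- src$values[okr, okc, drop = FALSE]
    idx <- matrix(tr[okr], nrow = sum(okr), ncol = sum(okc)) +
      (matrix(tc[okc], nrow = sum(okr), ncol = sum(okc), byrow = TRUE) - 1L) *
      target$n_rows
    valid <- !is.na(v)
    if (any(valid)) {
      sums <- rep(0, target$n_rows * target$n_cols)
      cnts <- rep(0L, target$n_rows * target$n_cols)
      tb_s <- tapply(v[valid], idx[valid], sum)
      tb_n <- tapply(rep(1L, sum(valid)), idx[valid], sum)
      ii <- as.integer(names(tb_s))
      sums[ii] <- tb_s
      cnts[ii] <- tb_n
      res <- ifelse(cnts > 0, sums / cnts, NA_real_)
      out[] <- res
    }
  }
  raster_grid(out, target, label = src$label)
}

#' Bilinear resampling onto a target grid
#'
#' Used to bring coarse-resolution imagery onto the fine grid ahead of
#' spatiotemporal fusion. Edge cells are clamped (no extrapolation beyond the
#' outermost cell centers); nodata neighbours are dropped from the weighted
#' mean, and a cell with no valid neighbour is nodata.
#'
#' @inheritParams align_to_grid
#' @return A [raster_grid()] on `target`.
#' @export
resample_bilinear <- function(src, target) {
  stopifnot(inherits(src, "raster_grid"), inherits(target, "grid_spec"))
  s <- src$spec
  u <- (cell_centers_x(target) - s$origin_x) / s$pixel_size_x - 0.5
  w <- (cell_centers_y(target) - s$origin_y) / s$pixel_size_y - 0.5
  u <- pmin(pmax(u, 0), s$n_cols - 1)
  w <- pmin(pmax(w, 0), s$n_rows - 1)
  c0 <- pmin(floor(u), s$n_cols - 2); c0 <- pmax(c0, 0)
  r0 <- pmin(floor(w), s$n_rows - 2); r0 <- pmax(r0, 0)
  if (s$n_cols == 1) c0 <- rep(0, length(u))
  if (s$n_rows == 1) r0 <- rep(0, length(w))
  fx <- u - c0
  fy <- w - r0
  nrT <- target$n_rows; ncT <- target$n_cols
  R0 <- matrix(r0, nrT, ncT) ; FY <- matrix(fy, nrT, ncT)
  C0 <- matrix(c0, nrT, ncT, byrow = TRUE); FX <- matrix(fx, nrT, ncT, byrow = TRUE)
  c1 <- pmin(C0 + 1, s$n_cols - 1)
  r1 <- pmin(R0 + 1, s$n_rows - 1)
  g <- function(rr, cc) src$values[rr + cc * s$n_rows + 1L]
  vals <- list(g(R0, C0), g(R0, c1), g(r1, C0), g(r1, c1))
  wts <- list((1 - FY) * (1 - FX), (1 - FY) * FX, FY * (1 - FX), FY * FX)
  num <- matrix(0, nrT, ncT); den <- matrix(0, nrT, ncT)
  for (k in 1:4) {
    ok <- !is.na(vals[[k]])
    num[ok] <- num[ok] + wts[[k]][ok] * vals[[k]][ok]
    den[ok] <- den[ok] + wts[[k]][ok]
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  raster_grid(out, target, label = src$label)
}

#' Aggregate a fine raster to a coarser resolution by block mean
#'
#' Blocks of `factor` x `factor` fine cells are averaged, skipping nodata;
#' an all-nodata block is nodata. Trailing partial blocks (when dimensions do
#' not divide evenly) are averaged over the cells available. The output
#' pixel size is the fine pixel size times `factor`.
#'
#' @param fine A [raster_grid()].
#' @param factor Positive integer aggregation factor.
#' @return A [raster_grid()] at the coarser resolution.
#' @export
aggregate_to_coarse <- function(fine, factor) {
  stopifnot(inherits(fine, "raster_grid"))
  if (length(factor) != 1 || factor < 1 || factor != round(factor)) {
    stop("factor must be a positive integer")
  }
  factor <- as.integer(factor)
  s <- fine$spec
  gr <- (seq_len(s$n_rows) - 1L) %/% factor + 1L
  gc <- (seq_len(s$n_cols) - 1L) %/% factor + 1L
  v <- fine$values
  valid <- !is.na(v)
  v0 <- ifelse(valid, v, 0)
  sums <- rowsum(v0, gr, reorder = TRUE)
  sums <- t(rowsum(t(sums), gc, reorder = TRUE))
  cnts <- rowsum(valid + 0, gr, reorder = TRUE)
  cnts <- t(rowsum(t(cnts), gc, reorder = TRUE))
  out <- ifelse(cnts > 0, sums / cnts, NA_real_)
  dimnames(out) <- NULL
  spec <- grid_spec(
    n_rows = nrow(out), n_cols = ncol(out),
    origin_x = s$origin_x, origin_y = s$origin_y,
    pixel_size_x = s$pixel_size_x * factor,
    pixel_size_y = s$pixel_size_y * factor,
    crs_id = s$crs_id, nodata = s$nodata
  )
  raster_grid(out, spec, label = fine$label)
}

#' Composite a raster series to one month
#'
#' Per-pixel composite over the dates falling in `month`. `max` is the
#' maximum-value composite conventionally used for vegetation indices (it
#' suppresses residual cloud-depressed values); `mean` suits meteorology.
#' Nodata dates are skipped per pixel; a pixel invalid on every date in the
#' month is nodata.
#'
#' @param series A [raster_series()].
#' @param month Calendar month, 1-12.
#' @param method `"max"` or `"mean"`.
#' @return A [raster_grid()].
#' @export
monthly_composite <- function(series, month, method = c("max", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "raster_series"))
  sel <- which(as.integer(format(series$dates, "%m")) == month)
  if (length(sel) == 0) {
    stop("no dates in the series fall in month ", month)
  }
  mats <- lapply(series$grids[sel], function(g) g$values)
  if (method == "max") {
    out <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE), mats)
  } else {
    sums <- Reduce(`+`, lapply(mats, function(m) ifelse(is.na(m), 0, m)))
    cnts <- Reduce(`+`, lapply(mats, function(m) (!is.na(m)) + 0L))
    out <- ifelse(cnts > 0, sums / cnts, NA_real_)
  }
  raster_grid(out, series$grids[[sel[1]]]$spec,
              label = sprintf("month_%02d_%s", month, method))
}
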