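# Naive, loop-by-loop re-implementation of the moving-window fusion
# prediction, used as an independent oracle for predict_single_pair().
# Every rule of the fast kernel is restated here in the plainest possible
# form: similar-pixel threshold 2*sd/n_classes (sample sd over valid fine
# window pixels), candidate validity (fine + both coarse valid), the
# optional second-pair dual selection and pooled regression, the
# distance/spectral weights, the regression fallbacks, and the [-1, 1]
# clip. Intermediate sums deliberately use the same one-pass formulas and
# the same column-major accumulation order as the kernel so agreement can
# be required to 1e-10.
oracle_estarfm <- function(fine1, coarse1, coarse2, half_window, n_classes,
                           min_similar, min_points, min_r2, target = NULL,
                           pool_fine = NULL, pool_coarse = NULL) {
  nr <- nrow(fine1); nc <- ncol(fine1)
  if (is.null(target)) target <- matrix(TRUE, nr, nc)
  pooled <- !is.null(pool_fine)
  out <- matrix(NA_real_, nr, nc)
  for (c0 in seq_len(nc)) {
    for (r0 in seq_len(nr)) {
      if (!target[r0, c0]) next
      fc <- fine1[r0, c0]
      if (is.na(fc)) next
      rs <- max(1, r0 - half_window):min(nr, r0 + half_window)
      cs <- max(1, c0 - half_window):min(nc, c0 + half_window)

      # candidate list in the kernel's column-major order
      cand_r <- integer(0); cand_c <- integer(0)
      s1 <- 0; s2 <- 0; nval <- 0
      for (cc in cs) {
        for (rr in rs) {
          f <- fine1[rr, cc]
          if (is.na(f)) next
          s1 <- s1 + f; s2 <- s2 + f * f; nval <- nval + 1
          if (is.na(coarse1[rr, cc]) || is.na(coarse2[rr, cc])) next
          cand_r <- c(cand_r, rr); cand_c <- c(cand_c, cc)
        }
      }
      sdw <- 0
      if (nval > 1) {
        v <- (s2 - s1 * s1 / nval) / (nval - 1)
        if (v > 0) sdw <- sqrt(v)
      }
      thr <- 2 * sdw / n_classes

      fc2 <- if (pooled) pool_fine[r0, c0] else NA_real_
      dual <- pooled && !is.na(fc2)
      thr2 <- 0
      if (dual) {
        p1 <- 0; p2 <- 0; np <- 0
        for (cc in cs) {
          for (rr in rs) {
            f <- pool_fine[rr, cc]
            if (is.na(f)) next
            p1 <- p1 + f; p2 <- p2 + f * f; np <- np + 1
          }
        }
        if (np > 1) {
          vp <- (p2 - p1 * p1 / np) / (np - 1)
          if (vp > 0) thr2 <- 2 * sqrt(vp) / n_classes
        }
      }

      keep <- logical(length(cand_r))
      for (i in seq_along(cand_r)) {
        if (cand_r[i] == r0 && cand_c[i] == c0) {
          keep[i] <- TRUE
          next
        }
        if (abs(fine1[cand_r[i], cand_c[i]] - fc) > thr) next
        if (dual) {
          pf <- pool_fine[cand_r[i], cand_c[i]]
          if (is.na(pf) || abs(pf - fc2) > thr2) next
        }
        keep[i] <- TRUE
      }
      sel_r <- cand_r[keep]; sel_c <- cand_c[keep]

      cl1 <- coarse1[r0, c0]; cl2 <- coarse2[r0, c0]
      if (length(sel_r) < max(1, min_similar)) {
        pred <- fc
        if (!is.na(cl1) && !is.na(cl2)) pred <- pred + (cl2 - cl1)
        out[r0, c0] <- min(1, max(-1, pred))
        next
      }

      w <- numeric(length(sel_r))
      for (i in seq_along(sel_r)) {
        d <- 1 + sqrt((sel_r[i] - r0)^2 + (sel_c[i] - c0)^2) / half_window
        s <- 1 + abs(fine1[sel_r[i], sel_c[i]] - coarse1[sel_r[i], sel_c[i]])
        w[i] <- 1 / (d * s)
      }
      w <- w / sum(w)

      sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0; n <- 0
      for (i in seq_along(sel_r)) {
        x <- coarse1[sel_r[i], sel_c[i]]; y <- fine1[sel_r[i], sel_c[i]]
        sx <- sx + x; sy <- sy + y
        sxx <- sxx + x * x; syy <- syy + y * y; sxy <- sxy + x * y
        n <- n + 1
        if (pooled) {
          px <- pool_coarse[sel_r[i], sel_c[i]]
          py <- pool_fine[sel_r[i], sel_c[i]]
          if (!is.na(px) && !is.na(py)) {
            sx <- sx + px; sy <- sy + py
            sxx <- sxx + px * px; syy <- syy + py * py; sxy <- sxy + px * py
            n <- n + 1
          }
        }
      }
      V <- 1
      if (n >= min_points && n > 1) {
        varx <- (sxx - sx * sx / n) / (n - 1)
        vary <- (syy - sy * sy / n) / (n - 1)
        covxy <- (sxy - sx * sy / n) / (n - 1)
        if (varx >= 1e-8) {
          slope <- covxy / varx
          r2 <- if (vary > 0) covxy^2 / (varx * vary) else 0
          if (slope > 0 && slope <= 5 && r2 >= min_r2) V <- slope
        }
      }

      acc <- 0
      for (i in seq_along(sel_r)) {
        acc <- acc + w[i] * V *
          (coarse2[sel_r[i], sel_c[i]] - coarse1[sel_r[i], sel_c[i]])
      }
      out[r0, c0] <- min(1, max(-1, fc + acc))
    }
  }
  out
}

# Convenience wrapper taking the package's objects
oracle_predict <- function(pair, coarse_t2, params, target = NULL,
                           pool_pair = NULL) {
  oracle_estarfm(pair$fine$values, pair$coarse$values, coarse_t2$values,
                 params$window_half_size, params$n_classes,
                 params$min_similar, params$regression_min_points,
                 params$regression_min_r2, target,
                 pool_fine = if (is.null(pool_pair)) NULL else
                   pool_pair$fine$values,
                 pool_coarse = if (is.null(pool_pair)) NULL else
                   pool_pair$coarse$values)
}
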