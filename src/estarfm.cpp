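#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Moving-window ESTARFM prediction of a fine-resolution image at the target
// date from one fine/coarse reference pair plus the coarse target image,
// all co-registered on the fine grid.
//
// Per center pixel: similar pixels are window pixels whose fine reference
// value lies within 2*sd/n_classes of the center's (sd over valid fine
// window pixels, sample sd); weights combine spatial distance and the
// fine/coarse spectral difference, W_i ~ 1/(D_i*S_i) with
// D_i = 1 + dist/half_window and S_i = 1 + |fine - coarse_t1|; the
// conversion coefficient V is the least-squares slope of fine on coarse
// over the similar set, pooled with a second reference pair when one is
// supplied (pool_fine/pool_coarse nonempty), falling back to 1 when the
// regression is degenerate: too few points, coarse variance < 1e-8, slope
// outside (0, 5], or squared correlation below min_r2 (a slope carried by
// noise alone would otherwise attenuate the temporal change). The
// prediction is fine_t1(center) + sum W_i * V * (coarse_t2 - coarse_t1),
// clipped to [-1, 1]. Windows are truncated at the image border.
// [[Rcpp::export]]
NumericMatrix estarfm_predict_cpp(NumericMatrix fine1, NumericMatrix coarse1,
                                  NumericMatrix coarse2, int half_window,
                                  int n_classes, int min_similar,
                                  int regression_min_points, double min_r2,
                                  LogicalMatrix target,
                                  NumericMatrix pool_fine,
                                  NumericMatrix pool_coarse) {
  const int nr = fine1.nrow(), nc = fine1.ncol();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<int> rr, cc;
  std::vector<double> fv, c1v, c2v;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!target(r0, c0)) continue;
      const double fc = fine1(r0, c0);
      if (NumericMatrix::is_na(fc)) continue; // nodata center stays nodata
      const int rlo = std::max(0, r0 - half_window);
      const int rhi = std::min(nr - 1, r0 + half_window);
      const int clo = std::max(0, c0 - half_window);
      const int chi = std::min(nc - 1, c0 + half_window);
      rr.clear(); cc.clear(); fv.clear(); c1v.clear(); c2v.clear();
      double sum = 0.0, sum2 = 0.0;
      int nval = 0;
      for (int c = clo; c <= chi; ++c) {
        for (int r = rlo; r <= rhi; ++r) {
          const double f = fine1(r, c);
          if (NumericMatrix::is_na(f)) continue;
          sum += f; sum2 += f * f; ++nval;
          const double a = coarse1(r, c), b = coarse2(r, c);
          if (NumericMatrix::is_na(a) || NumericMatrix::is_na(b)) continue;
          rr.push_back(r); cc.push_back(c);
          fv.push_back(f); c1v.push_back(a); c2v.push_back(b);
        }
      }
      const double cl1 = coarse1(r0, c0), cl2 = coarse2(r0, c0);
      const bool center_coarse_ok =
        !NumericMatrix::is_na(cl1) && !NumericMatrix::is_na(cl2);
      double sdw = 0.0;
      if (nval > 1) {
        const double var = (sum2 - sum * sum / nval) / (nval - 1);
        sdw = var > 0.0 ? std::sqrt(var) : 0.0;
      }
      const double thr = 2.0 * sdw / n_classes;
      // with a second reference pair, similar pixels must satisfy the
      // threshold in both fine reference images (classical two-pair
      // selection): one date alone cannot separate classes whose values
      // coincide there but diverge over time
      const bool pooled = pool_fine.nrow() == nr && pool_coarse.nrow() == nr;
      const double fc2 = pooled ? pool_fine(r0, c0) : NA_REAL;
      const bool dual_select = pooled && !NumericMatrix::is_na(fc2);
      double thr2 = 0.0;
      if (dual_select) {
        double sum_p = 0.0, sum2_p = 0.0;
        int nval_p = 0;
        for (int c = clo; c <= chi; ++c) {
          for (int r = rlo; r <= rhi; ++r) {
            const double f = pool_fine(r, c);
            if (NumericMatrix::is_na(f)) continue;
            sum_p += f; sum2_p += f * f; ++nval_p;
          }
        }
        if (nval_p > 1) {
          const double var_p =
            (sum2_p - sum_p * sum_p / nval_p) / (nval_p - 1);
          thr2 = var_p > 0.0 ? 2.0 * std::sqrt(var_p) / n_classes : 0.0;
        }
      }
      std::vector<int> idx;
      for (size_t i = 0; i < fv.size(); ++i) {
        const bool is_center = (rr[i] == r0 && cc[i] == c0);
        if (is_center) { idx.push_back((int)i); continue; }
        if (std::fabs(fv[i] - fc) > thr) continue;
        if (dual_select) {
          const double pf = pool_fine(rr[i], cc[i]);
          if (NumericMatrix::is_na(pf) || std::fabs(pf - fc2) > thr2)
            continue;
        }
        idx.push_back((int)i);
      }
      if ((int)idx.size() < std::max(1, min_similar)) {
        // degenerate window: propagate the coarse change at the center only
        double pred = fc;
        if (center_coarse_ok) pred += cl2 - cl1;
        out(r0, c0) = std::min(1.0, std::max(-1.0, pred));
        continue;
      }
      double wsum = 0.0;
      std::vector<double> w(idx.size());
      for (size_t k = 0; k < idx.size(); ++k) {
        const int i = idx[k];
        const double dr = rr[i] - r0, dc = cc[i] - c0;
        const double d = 1.0 + std::sqrt(dr * dr + dc * dc) / half_window;
        const double s = 1.0 + std::fabs(fv[i] - c1v[i]);
        w[k] = 1.0 / (d * s);
        wsum += w[k];
      }
      double V = 1.0;
      {
        double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
        int n = 0;
        for (size_t k = 0; k < idx.size(); ++k) {
          const int i = idx[k];
          sx += c1v[i]; sy += fv[i];
          sxx += c1v[i] * c1v[i]; syy += fv[i] * fv[i];
          sxy += c1v[i] * fv[i];
          ++n;
          if (pooled) {
            const double pf = pool_fine(rr[i], cc[i]);
            const double pc = pool_coarse(rr[i], cc[i]);
            if (!NumericMatrix::is_na(pf) && !NumericMatrix::is_na(pc)) {
              sx += pc; sy += pf;
              sxx += pc * pc; syy += pf * pf; sxy += pc * pf;
              ++n;
            }
          }
        }
        if (n >= regression_min_points && n > 1) {
          const double varx = (sxx - sx * sx / n) / (n - 1);
          const double vary = (syy - sy * sy / n) / (n - 1);
          const double covxy = (sxy - sx * sy / n) / (n - 1);
          if (varx >= 1e-8) {
            const double slope = covxy / varx;
            const double r2 =
              vary > 0.0 ? (covxy * covxy) / (varx * vary) : 0.0;
            if (slope > 0.0 && slope <= 5.0 && r2 >= min_r2) V = slope;
          }
        }
      }
      double acc = 0.0;
      for (size_t k = 0; k < idx.size(); ++k) {
        const int i = idx[k];
        acc += (w[k] / wsum) * V * (c2v[i] - c1v[i]);
      }
      out(r0, c0) = std::min(1.0, std::max(-1.0, fc + acc));
    }
  }
  return out;
}
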