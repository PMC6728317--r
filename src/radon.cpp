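// Parallel-beam projector, adjoint, SART sweeps, TV gradient, affine warp.
// Geometry: square n x n grid, pixel centre coordinates x = j - c, y = i - c
// with c = (n-1)/2 (i = row, j = column).  Detector has n bins with unit
// spacing; a pixel at (x, y) projects to t = x cos(theta) + y sin(theta) + c
// and its full mass is split linearly between the two neighbouring bins, so
// every projection row conserves total image mass exactly (for content inside
// the inscribed circle).  The adjoint interpolates each row back with the
// same weights, making (forward, adjoint) an exact transpose pair.
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
NumericMatrix cpp_radon_forward(const NumericMatrix& img,
                                const NumericVector& angles) {
  const int n = img.nrow();
  if (img.ncol() != n) stop("image must be square");
  const int na = angles.size();
  const double c = 0.5 * (n - 1);
  NumericMatrix sino(na, n);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < n; ++j) {
      const double x = j - c;
      for (int i = 0; i < n; ++i) {
        const double v = img(i, j);
        if (v == 0.0) continue;
        const double t = x * ct + (i - c) * st + c;
        int t0 = (int)std::floor(t);
        const double w = t - t0;
        if (t0 >= 0 && t0 < n) sino(a, t0) += v * (1.0 - w);
        if (t0 + 1 >= 0 && t0 + 1 < n) sino(a, t0 + 1) += v * w;
      }
    }
  }
  return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_radon_adjoint(const NumericMatrix& sino,
                                const NumericVector& angles,
                                int n) {
  const int na = angles.size();
  if (sino.nrow() != na) stop("rows of sino must match angle count");
  if (sino.ncol() != n) stop("detector bin count must equal n");
  const double c = 0.5 * (n - 1);
  NumericMatrix img(n, n);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < n; ++j) {
      const double x = j - c;
      for (int i = 0; i < n; ++i) {
        const double t = x * ct + (i - c) * st + c;
        int t0 = (int)std::floor(t);
        const double w = t - t0;
        double v = 0.0;
        if (t0 >= 0 && t0 < n) v += sino(a, t0) * (1.0 - w);
        if (t0 + 1 >= 0 && t0 + 1 < n) v += sino(a, t0 + 1) * w;
        img(i, j) += v;
      }
    }
  }
  return img;
}

// Angle-sequential SART.  For each acquired angle the residual between the
// measured row and the current estimate's projection is normalized by the
// per-bin ray weight (the projection of an all-ones image) and back-
// distributed; per-pixel column weights are identically 1 because the splat
// weights of each pixel sum to 1.  Missing rows are skipped entirely.
// [[Rcpp::export]]
NumericMatrix cpp_sart(const NumericMatrix& sino,
                       const NumericVector& angles,
                       const LogicalVector& acquired,
                       double lambda,
                       int n_sweeps,
                       const NumericMatrix& x0) {
  const int n = sino.ncol();
  const int na = angles.size();
  NumericMatrix x = clone(x0);
  std::vector<double> proj(n), wray(n);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int a = 0; a < na; ++a) {
      if (!acquired[a]) continue;
      const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
      const double c = 0.5 * (n - 1);
      std::fill(proj.begin(), proj.end(), 0.0);
      std::fill(wray.begin(), wray.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        const double xx = j - c;
        for (int i = 0; i < n; ++i) {
          const double t = xx * ct + (i - c) * st + c;
          int t0 = (int)std::floor(t);
          const double w = t - t0;
          if (t0 >= 0 && t0 < n) {
            proj[t0] += x(i, j) * (1.0 - w);
            wray[t0] += 1.0 - w;
          }
          if (t0 + 1 >= 0 && t0 + 1 < n) {
            proj[t0 + 1] += x(i, j) * w;
            wray[t0 + 1] += w;
          }
        }
      }
      for (int t = 0; t < n; ++t) {
        const double den = std::max(wray[t], 1e-8);
        proj[t] = lambda * (sino(a, t) - proj[t]) / den;
      }
      for (int j = 0; j < n; ++j) {
        const double xx = j - c;
        for (int i = 0; i < n; ++i) {
          const double t = xx * ct + (i - c) * st + c;
          int t0 = (int)std::floor(t);
          const double w = t - t0;
          double upd = 0.0;
          if (t0 >= 0 && t0 < n) upd += proj[t0] * (1.0 - w);
          if (t0 + 1 >= 0 && t0 + 1 < n) upd += proj[t0 + 1] * w;
          x(i, j) += upd;
          if (!std::isfinite(x(i, j)))
            stop("SART diverged (non-finite estimate) at sweep %d", sweep + 1);
        }
      }
    }
  }
  return x;
}

// Gradient of the smoothed isotropic total variation
// TV(x) = sum sqrt(dx^2 + dy^2 + eps^2) with forward differences.
// [[Rcpp::export]]
NumericMatrix cpp_tv_grad(const NumericMatrix& img, double eps) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix g(nr, nc);
  auto dx = [&](int i, int j) { return (j + 1 < nc) ? img(i, j + 1) - img(i, j) : 0.0; };
  auto dy = [&](int i, int j) { return (i + 1 < nr) ? img(i + 1, j) - img(i, j) : 0.0; };
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double mij = std::sqrt(dx(i, j) * dx(i, j) + dy(i, j) * dy(i, j) + eps * eps);
      g(i, j) += -(dx(i, j) + dy(i, j)) / mij;
      if (j > 0) {
        const double m = std::sqrt(dx(i, j - 1) * dx(i, j - 1) + dy(i, j - 1) * dy(i, j - 1) + eps * eps);
        g(i, j) += dx(i, j - 1) / m;
      }
      if (i > 0) {
        const double m = std::sqrt(dx(i - 1, j) * dx(i - 1, j) + dy(i - 1, j) * dy(i - 1, j) + eps * eps);
        g(i, j) += dy(i - 1, j) / m;
      }
    }
  }
  return g;
}

// Inverse-mapped affine warp with bilinear interpolation and zero padding.
// M is the 2x3 matrix taking centred output coordinates (x, y) to centred
// input coordinates: xs = M(0,0) x + M(0,1) y + M(0,2), similarly ys.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(const NumericMatrix& img, const NumericMatrix& M) {
  const int nr = img.nrow(), nc = img.ncol();
  const double cx = 0.5 * (nc - 1), cy = 0.5 * (nr - 1);
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double x = j - cx;
    for (int i = 0; i < nr; ++i) {
      const double y = i - cy;
      const double xs = M(0, 0) * x + M(0, 1) * y + M(0, 2) + cx;
      const double ys = M(1, 0) * x + M(1, 1) * y + M(1, 2) + cy;
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      const double fx = xs - x0, fy = ys - y0;
      double v = 0.0;
      for (int dy2 = 0; dy2 <= 1; ++dy2) {
        for (int dx2 = 0; dx2 <= 1; ++dx2) {
          const int xi = x0 + dx2, yi = y0 + dy2;
          if (xi < 0 || xi >= nc || yi < 0 || yi >= nr) continue;
          const double w = (dx2 ? fx : 1.0 - fx) * (dy2 ? fy : 1.0 - fy);
          v += w * img(yi, xi);
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}
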