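// Off-lattice cell-centre mechanics inner loops.
//
// Overdamped motion of overlapping spheres constrained to the crypt
// surface (hemisphere of radius R joined to a cylinder of height H).
// Linear overlap springs with pair stiffness sqrt(s_i * s_j); drag
// proportional to stiffness.  These loops dominate the simulation cost,
// hence compiled.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void project_point(double &x, double &y, double &z,
                                 const double R, const double H) {
  if (z > 0.0) {
    double rho = std::sqrt(x * x + y * y);
    if (rho < 1e-12) { x = 1e-6; rho = 1e-6; }
    const double f = R / rho;
    x *= f; y *= f;
    if (z > H) z = H;
  } else {
    double nrm = std::sqrt(x * x + y * y + z * z);
    if (nrm < 1e-12) { z = -1e-12; nrm = 1e-12; }
    const double g = R / nrm;
    x *= g; y *= g; z *= g;
  }
}

// [[Rcpp::export(name = ".relax_cpp")]]
List relax_cpp(NumericMatrix X, NumericVector r, NumericVector s,
               double k_spring, double h, int nsub, double max_disp,
               double R, double H, double k_adh, double adh_range,
               LogicalVector paneth, double paneth_rest,
               NumericVector drag_in) {
  const int n = X.nrow();
  std::vector<double> x(n), y(n), z(n), rr(n), ss(n), drag(n);
  for (int i = 0; i < n; ++i) {
    x[i] = X(i, 0); y[i] = X(i, 1); z[i] = X(i, 2);
    rr[i] = r[i]; ss[i] = s[i];
    drag[i] = drag_in[i];
  }
  // Verlet list with a skin; cells move far less than the skin within
  // one relax call (displacements are bounded by max_disp per sub-step,
  // and typical moves are ~1e-3), so one build per call suffices
  const double skin = 0.4;
  std::vector<int> pi_, pj_;
  std::vector<double> pk_, prs_;
  pi_.reserve(8 * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double rs = rr[i] + rr[j];
      const double lim = rs * adh_range + skin;
      if (dx * dx + dy * dy + dz * dz < lim * lim) {
        pi_.push_back(i); pj_.push_back(j);
        pk_.push_back(k_spring * std::sqrt(ss[i] * ss[j]));
        // Paneth interfaces are interdigitated: shorter rest length,
        // hence permanent compression at the contact
        prs_.push_back((paneth[i] || paneth[j]) ? paneth_rest * rs : rs);
      }
    }
  }
  const int np = (int) pi_.size();
  std::vector<double> fx(n), fy(n), fz(n);
  double worst = 0.0;
  for (int it = 0; it < nsub; ++it) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int p = 0; p < np; ++p) {
      const int i = pi_[p], j = pj_[p];
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double rs = prs_[p];
      const double reach = rs * adh_range;
      if (d2 >= reach * reach) continue;
      const double d = std::max(std::sqrt(d2), 1e-6);
      // repulsive overlap spring inside contact, short-range adhesion
      // just outside it
      const double w = (d < rs)
        ? pk_[p] * (rs - d) / d
        : -k_adh * (pk_[p] / k_spring) * (d - rs) / d *
          (reach - d) / (reach - rs);
      fx[i] += w * dx; fy[i] += w * dy; fz[i] += w * dz;
      fx[j] -= w * dx; fy[j] -= w * dy; fz[j] -= w * dz;
    }
    for (int i = 0; i < n; ++i) {
      const double vx = fx[i] / drag[i], vy = fy[i] / drag[i],
        vz = fz[i] / drag[i];
      const double disp = std::sqrt(vx * vx + vy * vy + vz * vz) * h;
      if (disp > worst) worst = disp;
      if (disp > max_disp) {
        NumericMatrix P(n, 3);
        for (int q = 0; q < n; ++q) {
          P(q, 0) = x[q]; P(q, 1) = y[q]; P(q, 2) = z[q];
        }
        return List::create(_["X"] = P, _["max_disp"] = worst,
                            _["ok"] = false);
      }
      double xn = x[i] + vx * h, yn = y[i] + vy * h, zn = z[i] + vz * h;
      project_point(xn, yn, zn, R, H);
      x[i] = xn; y[i] = yn; z[i] = zn;
    }
  }
  NumericMatrix P(n, 3);
  for (int q = 0; q < n; ++q) {
    P(q, 0) = x[q]; P(q, 1) = y[q]; P(q, 2) = z[q];
  }
  return List::create(_["X"] = P, _["max_disp"] = worst, _["ok"] = true);
}

// [[Rcpp::export(name = ".contact_pairs_cpp")]]
List contact_pairs_cpp(NumericMatrix X, NumericVector r,
                       double contact_factor) {
  const int n = X.nrow();
  std::vector<int> ii, jj;
  std::vector<double> dd, oo;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = X(i, 0) - X(j, 0);
      const double dy = X(i, 1) - X(j, 1);
      const double dz = X(i, 2) - X(j, 2);
      const double rs = r[i] + r[j];
      const double lim = rs * contact_factor;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < lim * lim) {
        const double d = std::sqrt(d2);
        ii.push_back(i + 1); jj.push_back(j + 1);
        dd.push_back(d); oo.push_back(rs - d);
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["dist"] = wrap(dd), _["overlap"] = wrap(oo));
}
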