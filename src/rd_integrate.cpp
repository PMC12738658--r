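#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Tridiagonal solve for (I - r*L) x = d where L is the 1-D Neumann (no-flux)
// Laplacian stencil [1, -2, 1] (already divided by h^2 through r).
// Diagonal: 1 + r at both ends, 1 + 2r inside; off-diagonals: -r.
// Constant coefficients, so the forward-elimination pivots are precomputed.
struct ThomasNeumann {
  int n;
  double r;
  std::vector<double> cp; // modified super-diagonal after elimination

  ThomasNeumann(int n_, double r_) : n(n_), r(r_), cp(n_) {
    double diag0 = 1.0 + r;
    double diagi = 1.0 + 2.0 * r;
    cp[0] = -r / diag0;
    for (int i = 1; i < n - 1; ++i) cp[i] = -r / (diagi + r * cp[i - 1]);
    cp[n - 1] = 0.0;
  }

  // solve in place on d (stride-1 access through raw pointer with stride)
  void solve(double *d, int stride) const {
    double diag0 = 1.0 + r;
    double diagi = 1.0 + 2.0 * r;
    double dn = diag0; // last row diagonal equals first by symmetry
    d[0] = d[0] / diag0;
    for (int i = 1; i < n; ++i) {
      double diag = (i == n - 1) ? dn : diagi;
      double denom = diag + r * cp[i - 1];
      d[i * stride] = (d[i * stride] + r * d[(i - 1) * stride]) / denom;
    }
    for (int i = n - 2; i >= 0; --i)
      d[i * stride] -= cp[i] * d[(i + 1) * stride];
  }
};

// Semi-implicit integrator for a two-component reaction-diffusion system
// with Schnakenberg kinetics
//   u_t = Du lap(u) + gamma (a - u + u^2 v)
//   v_t = Dv lap(v) + gamma (b - u^2 v)
// on a 1-D or 2-D uniform grid with no-flux boundaries. Reaction is explicit
// Euler, diffusion implicit (unconditionally stable), with Lie splitting of
// the two spatial directions in 2-D. Integration stops once the max-norm
// relative change per unit time drops below stat_tol, or at max_steps.
// [[Rcpp::export]]
List rd_integrate_cpp(NumericVector u0, NumericVector v0,
                      int nx, int ny,
                      double a, double b, double gamma,
                      double Du, double Dv,
                      double hx, double dt,
                      int max_steps, int check_every, double stat_tol) {
  const int ntot = nx * ny;
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> uprev(u), vprev(v);

  const double rx_u = Du * dt / (hx * hx);
  const double rx_v = Dv * dt / (hx * hx);
  ThomasNeumann tx_u(nx, rx_u), tx_v(nx, rx_v);
  ThomasNeumann ty_u(ny > 1 ? ny : 2, ny > 1 ? Du * dt / (hx * hx) : 0.0);
  ThomasNeumann ty_v(ny > 1 ? ny : 2, ny > 1 ? Dv * dt / (hx * hx) : 0.0);

  bool stationary = false, diverged = false;
  double t = 0.0, div_time = NA_REAL;
  int step = 0;

  for (step = 0; step < max_steps; ++step) {
    // explicit reaction
    for (int i = 0; i < ntot; ++i) {
      double uu = u[i], vv = v[i];
      double uuvv = uu * uu * vv;
      u[i] = uu + dt * gamma * (a - uu + uuvv);
      v[i] = vv + dt * gamma * (b - uuvv);
    }
    // implicit diffusion, x-direction (columns are contiguous: index i + nx*j)
    for (int j = 0; j < ny; ++j) {
      tx_u.solve(&u[(size_t)j * nx], 1);
      tx_v.solve(&v[(size_t)j * nx], 1);
    }
    // implicit diffusion, y-direction
    if (ny > 1) {
      for (int i = 0; i < nx; ++i) {
        ty_u.solve(&u[i], nx);
        ty_v.solve(&v[i], nx);
      }
    }
    t += dt;

    if ((step + 1) % check_every == 0 || step == max_steps - 1) {
      double umax = 0.0, vmax = 0.0, du = 0.0, dv = 0.0;
      bool bad = false;
      for (int i = 0; i < ntot; ++i) {
        if (!std::isfinite(u[i]) || !std::isfinite(v[i]) ||
            std::fabs(u[i]) > 1e10 || std::fabs(v[i]) > 1e10) { bad = true; break; }
        umax = std::max(umax, std::fabs(u[i]));
        vmax = std::max(vmax, std::fabs(v[i]));
        du = std::max(du, std::fabs(u[i] - uprev[i]));
        dv = std::max(dv, std::fabs(v[i] - vprev[i]));
      }
      if (bad) { diverged = true; div_time = t; break; }
      double elapsed = dt * check_every;
      double rate = std::max(du / (elapsed * std::max(umax, 1e-12)),
                             dv / (elapsed * std::max(vmax, 1e-12)));
      if (rate < stat_tol) { stationary = true; ++step; break; }
      uprev = u; vprev = v;
    }
  }

  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["time"] = t,
                      _["steps"] = step,
                      _["stationary"] = stationary,
                      _["diverged"] = diverged,
                      _["divergence_time"] = div_time);
}
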