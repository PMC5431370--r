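#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout fixed by par_vec() on the R side:
// k, a, eps, mu1, mu2, I_st, D_u, k0, k1, k2, alpha, beta
enum { K = 0, A, EPS, MU1, MU2, IST, DU, K0, K1, K2, ALPHA, BETA, NPAR };

// Integration modes (keep in sync with .mode_code in R).
enum { MODE_BASELINE = 0, MODE_INDUCTION = 1, MODE_DIFFUSION = 2 };

static inline double lap_at(const NumericMatrix &f, int i, int j,
                            int nr, int nc, double inv_dx2) {
  // Mirror-ghost no-flux boundary: the missing neighbour takes the
  // centre value, so its contribution to (sum - 4c) vanishes.
  const double c = f(i, j);
  const double up = (i > 0) ? f(i - 1, j) : c;
  const double dn = (i < nr - 1) ? f(i + 1, j) : c;
  const double lf = (j > 0) ? f(i, j - 1) : c;
  const double rt = (j < nc - 1) ? f(i, j + 1) : c;
  return (up + dn + lf + rt - 4.0 * c) * inv_dx2;
}

// Full lattice Euler-forward integrator.
//
// u0, v0, phi0 : state fields at time t0 (not modified)
// par          : parameter vector, layout above
// det_forcing  : optional time-independent flux drive lattice F(x,y)
// noise_cells  : 0-based column-major linear indices receiving noise
// noise_sd     : per-cell increment standard deviation (same length);
//                one N(0,1) draw per cell per step, in entry order,
//                taken from R's RNG so set.seed() governs the run
// extra_inc    : optional additive phi increment lattice applied each
//                step outside the h * rate product (single-step use)
// snap_steps   : sorted step counts (0..n_steps) at which to snapshot
// mon_i, mon_j : 0-based monitored node coordinates
// stride       : series recording stride in steps (>= 1)
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix u0, NumericMatrix v0, NumericMatrix phi0,
                  double t0, NumericVector par, double dx, double h,
                  int n_steps, int mode,
                  Nullable<NumericMatrix> det_forcing,
                  IntegerVector noise_cells, NumericVector noise_sd,
                  Nullable<NumericMatrix> extra_inc,
                  IntegerVector snap_steps,
                  IntegerVector mon_i, IntegerVector mon_j,
                  int stride, double guard, double blowup) {
  const int nr = u0.nrow(), nc = u0.ncol();
  if (v0.nrow() != nr || v0.ncol() != nc || phi0.nrow() != nr ||
      phi0.ncol() != nc)
    stop("state fields must share one grid shape");
  if (par.size() != NPAR) stop("parameter vector has wrong length");
  if (h <= 0.0 || dx <= 0.0) stop("h and dx must be positive");
  if (stride < 1) stop("stride must be >= 1");

  NumericMatrix u = clone(u0), v = clone(v0), phi = clone(phi0);
  NumericMatrix un(nr, nc), vn(nr, nc), pn(nr, nc);

  const double k = par[K], a = par[A], eps = par[EPS], mu1 = par[MU1],
               mu2 = par[MU2], I_st = par[IST], D_u = par[DU], k0 = par[K0],
               k1 = par[K1], k2 = par[K2], alpha = par[ALPHA],
               beta = par[BETA];
  const double inv_dx2 = 1.0 / (dx * dx);

  const bool has_det = det_forcing.isNotNull();
  NumericMatrix F;
  if (has_det) {
    F = NumericMatrix(det_forcing);
    if (F.nrow() != nr || F.ncol() != nc)
      stop("forcing lattice shape does not match the grid");
  }
  const bool has_inc = extra_inc.isNotNull();
  NumericMatrix Inc;
  if (has_inc) {
    Inc = NumericMatrix(extra_inc);
    if (Inc.nrow() != nr || Inc.ncol() != nc)
      stop("increment lattice shape does not match the grid");
  }
  const int n_noise = noise_cells.size();
  if (noise_sd.size() != n_noise)
    stop("noise_cells and noise_sd must have equal length");

  const int nm = mon_i.size();
  const int n_save = n_steps / stride + 1;
  NumericMatrix series(n_save, 1 + 3 * nm);
  int save_row = 0;
  series(save_row, 0) = t0;
  for (int m = 0; m < nm; ++m) {
    series(save_row, 1 + 3 * m) = u(mon_i[m], mon_j[m]);
    series(save_row, 2 + 3 * m) = v(mon_i[m], mon_j[m]);
    series(save_row, 3 + 3 * m) = phi(mon_i[m], mon_j[m]);
  }
  ++save_row;

  const int n_snap = snap_steps.size();
  List snap_u(n_snap), snap_v(n_snap), snap_phi(n_snap);
  NumericVector snap_t(n_snap);
  int snap_ptr = 0;
  while (snap_ptr < n_snap && snap_steps[snap_ptr] == 0) {
    snap_u[snap_ptr] = clone(u);
    snap_v[snap_ptr] = clone(v);
    snap_phi[snap_ptr] = clone(phi);
    snap_t[snap_ptr] = t0;
    ++snap_ptr;
  }

  for (int s = 1; s <= n_steps; ++s) {
    double max_abs = 0.0;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        const double uu = u(i, j), vv = v(i, j), pp = phi(i, j);
        double du, dv, dp;
        if (mode == MODE_DIFFUSION) {
          du = D_u * lap_at(u, i, j, nr, nc, inv_dx2);
          dv = 0.0;
          dp = 0.0;
        } else {
          const double denom = uu + mu2;
          if (std::fabs(denom) < guard)
            stop("recovery rate undefined: |u + mu2| < %g at node (%d,%d), t = %g",
                 guard, i + 1, j + 1, t0 + (s - 1) * h);
          const double feedback =
              (mode == MODE_INDUCTION)
                  ? k0 * (alpha + 3.0 * beta * pp * pp) * uu
                  : I_st;
          du = -k * uu * (uu - a) * (uu - 1.0) - uu * vv + feedback +
               D_u * lap_at(u, i, j, nr, nc, inv_dx2);
          dv = (eps + vv * mu1 / denom) * (-vv - k * uu * (uu - a - 1.0));
          dp = k1 * uu - k2 * pp + (has_det ? F(i, j) : 0.0);
        }
        const double nu = uu + h * du;
        const double nv = vv + h * dv;
        double np = pp + h * dp;
        if (has_inc) np += Inc(i, j);
        un(i, j) = nu;
        vn(i, j) = nv;
        pn(i, j) = np;
        const double m1 = std::fabs(nu), m2 = std::fabs(nv),
                     m3 = std::fabs(np);
        if (m1 > max_abs) max_abs = m1;
        if (m2 > max_abs) max_abs = m2;
        if (m3 > max_abs) max_abs = m3;
      }
    }
    for (int q = 0; q < n_noise; ++q)
      pn[noise_cells[q]] += noise_sd[q] * norm_rand();
    if (!(max_abs <= blowup) || std::isnan(max_abs))
      stop("state diverged (max |state| = %g > %g) at t = %g", max_abs,
           blowup, t0 + s * h);
    std::copy(un.begin(), un.end(), u.begin());
    std::copy(vn.begin(), vn.end(), v.begin());
    std::copy(pn.begin(), pn.end(), phi.begin());

    if (s % stride == 0) {
      series(save_row, 0) = t0 + s * h;
      for (int m = 0; m < nm; ++m) {
        series(save_row, 1 + 3 * m) = u(mon_i[m], mon_j[m]);
        series(save_row, 2 + 3 * m) = v(mon_i[m], mon_j[m]);
        series(save_row, 3 + 3 * m) = phi(mon_i[m], mon_j[m]);
      }
      ++save_row;
    }
    while (snap_ptr < n_snap && snap_steps[snap_ptr] == s) {
      snap_u[snap_ptr] = clone(u);
      snap_v[snap_ptr] = clone(v);
      snap_phi[snap_ptr] = clone(phi);
      snap_t[snap_ptr] = t0 + s * h;
      ++snap_ptr;
    }
    if (s % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["u"] = u, _["v"] = v, _["phi"] = phi, _["t"] = t0 + n_steps * h,
      _["series"] = series, _["snap_u"] = snap_u, _["snap_v"] = snap_v,
      _["snap_phi"] = snap_phi, _["snap_t"] = snap_t);
}
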