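#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integration of the driver/driven rate network:
//   tau0 dx1/dt = -x2 - x3
//   tau0 dx2/dt =  x1 + alpha x2
//   tau0 dx3/dt =  beta + x3 (x1 - gamma)
//   tau0 dy/dt  = -lambda y + 10 tanh(Jyx x + Jyy y + I)  with Jyx = g * ones
// An optional pulse injects a constant external current S into one unit while
// stim_active is true (held constant within a step). The current enters each
// unit through its input port: for rate units (index >= 3) it adds to the
// argument of the tanh transfer function, alongside I; for the Rossler
// coordinates (no input port) it adds S/tau0 to the derivative.
// States are recorded after each step; columns keep_from..n_steps-1 (0-based)
// of the step sequence are returned.
static inline void deriv(const double *st, double *dst,
                         const double *Jyy, int n_y,
                         double g, double alpha, double beta, double gamma,
                         double tau0, double lambda, double Iext,
                         int stim_unit, double stim_cur) {
  const double x1 = st[0], x2 = st[1], x3 = st[2];
  dst[0] = (-x2 - x3) / tau0;
  dst[1] = (x1 + alpha * x2) / tau0;
  dst[2] = (beta + x3 * (x1 - gamma)) / tau0;
  const double xin = g * (x1 + x2 + x3);
  for (int i = 0; i < n_y; ++i) {
    double u = xin + Iext;
    if (stim_unit == 3 + i) u += stim_cur;
    const double *Jrow = Jyy + (size_t)i; // column-major: Jyy[i + n_y*j]
    const double *y = st + 3;
    for (int j = 0; j < n_y; ++j) u += Jrow[(size_t)n_y * j] * y[j];
    dst[3 + i] = (-lambda * st[3 + i] + 10.0 * std::tanh(u)) / tau0;
  }
  if (stim_unit >= 0 && stim_unit < 3) dst[stim_unit] += stim_cur / tau0;
}

// [[Rcpp::export]]
NumericMatrix rk4_network_cpp(NumericVector state0, NumericMatrix Jyy,
                              double g, double alpha, double beta, double gamma,
                              double tau0, double lambda, double Iext,
                              double dt, int n_steps, int keep_from,
                              int stim_unit, LogicalVector stim_active,
                              double stim_S, double guard,
                              double noise_sd) {
  const int n_y = Jyy.nrow();
  const int n = 3 + n_y;
  if (state0.size() != n) stop("state0 length must be 3 + nrow(Jyy)");
  const bool has_stim = stim_unit >= 0;
  if (has_stim && stim_active.size() != n_steps)
    stop("stim_active must have one entry per step");

  std::vector<double> st(state0.begin(), state0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  const int n_keep = n_steps - keep_from;
  if (n_keep <= 0) stop("keep_from must be smaller than n_steps");
  NumericMatrix out(n, n_keep);
  const double *J = &Jyy[0];
  // Dynamical noise (Euler-Maruyama increment on the driven units) uses R's
  // RNG so the trajectory is reproducible under set.seed().
  const bool noisy = noise_sd > 0.0;
  const double noise_scale = noise_sd * std::sqrt(dt);
  RNGScope rngScope;

  for (int s = 0; s < n_steps; ++s) {
    const double cur = (has_stim && stim_active[s]) ? stim_S : 0.0;
    const int su = has_stim ? stim_unit : -1;
    deriv(st.data(), k1.data(), J, n_y, g, alpha, beta, gamma, tau0, lambda, Iext, su, cur);
    for (int i = 0; i < n; ++i) tmp[i] = st[i] + 0.5 * dt * k1[i];
    deriv(tmp.data(), k2.data(), J, n_y, g, alpha, beta, gamma, tau0, lambda, Iext, su, cur);
    for (int i = 0; i < n; ++i) tmp[i] = st[i] + 0.5 * dt * k2[i];
    deriv(tmp.data(), k3.data(), J, n_y, g, alpha, beta, gamma, tau0, lambda, Iext, su, cur);
    for (int i = 0; i < n; ++i) tmp[i] = st[i] + dt * k3[i];
    deriv(tmp.data(), k4.data(), J, n_y, g, alpha, beta, gamma, tau0, lambda, Iext, su, cur);
    for (int i = 0; i < n; ++i) {
      st[i] += dt * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]) / 6.0;
      if (noisy && i >= 3) st[i] += noise_scale * R::norm_rand();
      if (!std::isfinite(st[i]) || std::fabs(st[i]) > guard)
        stop("trajectory diverged (|state| > %g) at step %d; check g, g_r and dt",
             guard, s + 1);
    }
    if (s >= keep_from)
      for (int i = 0; i < n; ++i) out(i, s - keep_from) = st[i];
  }
  return out;
}

// Simplex-projection cross-map predictions with contiguous-block
// cross-validation and a Theiler exclusion window.
//
// emb: m x d delay-state matrix, rows in time order (consecutive samples).
// src: length-m source values aligned with the rows of emb.
// fold: integer fold label per row; when use_folds, the library for row r is
//   restricted to rows of other folds. Rows within `theiler` samples of r are
//   always excluded, as is r itself.
// Neighbor ties in distance are broken toward the earlier row index. Weights
// are exp(-d/dmin); when dmin == 0, exact matches get weight 1 and the rest 0.
// [[Rcpp::export]]
NumericVector simplex_cv_cpp(NumericMatrix emb, NumericVector src,
                             IntegerVector fold, int k, int theiler,
                             bool use_folds) {
  const int m = emb.nrow(), d = emb.ncol();
  if (src.size() != m) stop("src length must match rows of embedding");
  if (k < 1) stop("k must be >= 1");
  NumericVector pred(m);
  // row-major copy for cache-friendly scans
  std::vector<double> E((size_t)m * d);
  for (int c = 0; c < d; ++c)
    for (int r = 0; r < m; ++r) E[(size_t)r * d + c] = emb(r, c);
  const int *fp = INTEGER(fold);
  // k-best kept sorted ascending by (distance, index)
  std::vector<double> kd(k);
  std::vector<int> ki(k);

  for (int r = 0; r < m; ++r) {
    const double *er = &E[(size_t)r * d];
    const int fr = fp[r];
    int cnt = 0;
    double worst = R_PosInf;
    for (int s = 0; s < m; ++s) {
      int gap = s - r; if (gap < 0) gap = -gap;
      if (gap <= theiler) continue; // also excludes s == r
      if (use_folds && fp[s] == fr) continue;
      const double *es = &E[(size_t)s * d];
      double dist2 = 0.0;
      int c = 0;
      for (; c < d; ++c) {
        const double df = er[c] - es[c];
        dist2 += df * df;
        if (dist2 > worst) break;
      }
      if (c < d) continue; // early abandon
      if (cnt == k &&
          !(dist2 < worst || (dist2 == worst && s < ki[k - 1]))) continue;
      // insertion by (dist2, s); earlier index wins ties
      int pos = (cnt < k) ? cnt : k - 1;
      while (pos > 0 &&
             (kd[pos - 1] > dist2 || (kd[pos - 1] == dist2 && ki[pos - 1] > s))) {
        if (pos < k) { kd[pos] = kd[pos - 1]; ki[pos] = ki[pos - 1]; }
        --pos;
      }
      kd[pos] = dist2; ki[pos] = s;
      if (cnt < k) ++cnt;
      if (cnt == k) worst = kd[k - 1];
    }
    if (cnt < k)
      stop("fewer library points (%d) than k = %d neighbors at row %d",
           cnt, k, r + 1);
    const double dmin = std::sqrt(kd[0]);
    double wsum = 0.0, psum = 0.0;
    for (int q = 0; q < k; ++q) {
      double w;
      if (dmin <= 0.0) w = (kd[q] <= 0.0) ? 1.0 : 0.0;
      else w = std::exp(-std::sqrt(kd[q]) / dmin);
      wsum += w; psum += w * src[ki[q]];
    }
    pred[r] = psum / wsum;
  }
  return pred;
}
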