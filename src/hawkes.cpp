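#include <Rcpp.h>
#include <cmath>
#include <cfloat>
#include <algorithm>

using namespace Rcpp;

// integral of exp(-rate * (u - center)^2) du over [lo, hi],
// written with erf so no R callbacks are needed in hot loops
static inline double interval_mass(double center, double rate,
                                   double lo, double hi) {
  const double s = std::sqrt(rate);
  const double root_pi = 1.7724538509055160273;
  double elo = std::isfinite(lo) ? std::erf((lo - center) * s) : -1.0;
  double ehi = std::isfinite(hi) ? std::erf((hi - center) * s) : 1.0;
  return 0.5 * (root_pi / s) * (ehi - elo);
}

// Triggering history sums G_j(i): for each event i and triggering component
// j, the sum of exp(-alpha_j dx^2 - beta_j dy^2 - gamma_j dt) over the
// min(n_star, i-1) immediately preceding events with strictly smaller time.
// [[Rcpp::export]]
NumericMatrix cpp_trigger_history_sums(NumericVector x, NumericVector y,
                                       NumericVector t,
                                       NumericVector alpha, NumericVector beta,
                                       NumericVector gamma, double n_star) {
  const int n = x.size();
  const int q1 = alpha.size();
  NumericMatrix G(n, q1);
  for (int i = 0; i < n; ++i) {
    int lo = 0;
    if (R_finite(n_star)) lo = std::max(0, i - (int)n_star);
    for (int l = lo; l < i; ++l) {
      const double dt = t[i] - t[l];
      if (dt <= 0.0) continue; // equal times do not trigger each other
      const double dx2 = (x[i] - x[l]) * (x[i] - x[l]);
      const double dy2 = (y[i] - y[l]) * (y[i] - y[l]);
      for (int j = 0; j < q1; ++j) {
        G(i, j) += std::exp(-alpha[j] * dx2 - beta[j] * dy2 - gamma[j] * dt);
      }
    }
  }
  return G;
}

// Full log-likelihood breakdown over S x D with the truncated history sum.
// Returns point term, background compensator, triggering compensator and a
// degeneracy flag (intensity floored at DBL_MIN at some event).
// [[Rcpp::export]]
List cpp_loglik(NumericVector x, NumericVector y, NumericVector t,
                NumericVector bg_a, NumericVector bg_c, NumericVector bg_d,
                NumericVector bg_alpha, NumericVector bg_beta,
                NumericVector tr_b, NumericVector tr_alpha,
                NumericVector tr_beta, NumericVector tr_gamma,
                double n_star,
                double x_lo, double x_hi, double y_lo, double y_hi,
                double t_lo, double t_hi) {
  const int n = x.size();
  const int p1 = bg_a.size();
  const int q1 = tr_b.size();

  bool degenerate = false;
  double point = 0.0;
  for (int i = 0; i < n; ++i) {
    double lam = 0.0;
    for (int j = 0; j < p1; ++j) {
      const double dx = x[i] - bg_c[j];
      const double dy = y[i] - bg_d[j];
      lam += bg_a[j] * std::exp(-bg_alpha[j] * dx * dx - bg_beta[j] * dy * dy);
    }
    int lo = 0;
    if (R_finite(n_star)) lo = std::max(0, i - (int)n_star);
    for (int l = lo; l < i; ++l) {
      const double dt = t[i] - t[l];
      if (dt <= 0.0) continue;
      const double dx2 = (x[i] - x[l]) * (x[i] - x[l]);
      const double dy2 = (y[i] - y[l]) * (y[i] - y[l]);
      for (int j = 0; j < q1; ++j) {
        lam += tr_b[j] * std::exp(-tr_alpha[j] * dx2 - tr_beta[j] * dy2 -
                                  tr_gamma[j] * dt);
      }
    }
    if (lam < DBL_MIN) { lam = DBL_MIN; degenerate = true; }
    point += std::log(lam);
  }

  double bg_comp = 0.0;
  const double T = t_hi - t_lo;
  for (int j = 0; j < p1; ++j) {
    bg_comp += bg_a[j] * interval_mass(bg_c[j], bg_alpha[j], x_lo, x_hi) *
               interval_mass(bg_d[j], bg_beta[j], y_lo, y_hi) * T;
  }

  double tr_comp = 0.0;
  for (int i = 0; i < n; ++i) {
    const double rem = t_hi - t[i];
    if (rem <= 0.0) continue; // events at or beyond t_hi trigger nothing in D
    for (int j = 0; j < q1; ++j) {
      const double H = -std::expm1(-tr_gamma[j] * rem) / tr_gamma[j];
      tr_comp += tr_b[j] * interval_mass(x[i], tr_alpha[j], x_lo, x_hi) *
                 interval_mass(y[i], tr_beta[j], y_lo, y_hi) * H;
    }
  }

  return List::create(_["point_term"] = point,
                      _["background_compensator"] = bg_comp,
                      _["trigger_compensator"] = tr_comp,
                      _["degenerate"] = degenerate);
}

// fraction of the circle centered at (cx, cy) with radius r lying inside
// the rectangle, by counting n_circ evenly spaced points on the circle
static inline double circle_fraction(double cx, double cy, double r,
                                     double x_lo, double x_hi,
                                     double y_lo, double y_hi, int n_circ) {
  int inside = 0;
  const double step = 2.0 * M_PI / n_circ;
  for (int k = 0; k < n_circ; ++k) {
    const double a = k * step;
    const double px = cx + r * std::cos(a);
    const double py = cy + r * std::sin(a);
    if (px >= x_lo && px <= x_hi && py >= y_lo && py <= y_hi) ++inside;
  }
  if (inside == 0) inside = 1; // guard: center is inside, some arc must be
  return (double)inside / (double)n_circ;
}

// Edge-corrected Ripley K on a distance grid (nondecreasing distances).
// K(d) = |S| n^-2 sum_{i != j} w_ij^-1 1(d_ij < d), with w_ij the fraction
// of the circle centered at point i with radius d_ij inside the rectangle.
// [[Rcpp::export]]
NumericVector cpp_ripley_k(NumericVector x, NumericVector y,
                           double x_lo, double x_hi, double y_lo, double y_hi,
                           NumericVector d, int n_circ) {
  const int n = x.size();
  const int nd = d.size();
  NumericVector incr(nd);
  const double dmax = d[nd - 1];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j];
      const double dy = y[i] - y[j];
      const double dij = std::sqrt(dx * dx + dy * dy);
      if (dij >= dmax) continue;
      // first grid index with d > d_ij receives the pair's contribution
      int pos = std::upper_bound(d.begin(), d.end(), dij) - d.begin();
      if (pos >= nd) continue;
      const double wi = circle_fraction(x[i], y[i], dij, x_lo, x_hi,
                                        y_lo, y_hi, n_circ);
      const double wj = circle_fraction(x[j], y[j], dij, x_lo, x_hi,
                                        y_lo, y_hi, n_circ);
      incr[pos] += 1.0 / wi + 1.0 / wj;
    }
  }
  const double area = (x_hi - x_lo) * (y_hi - y_lo);
  NumericVector K(nd);
  double acc = 0.0;
  for (int k = 0; k < nd; ++k) {
    acc += incr[k];
    K[k] = area * acc / ((double)n * (double)n);
  }
  return K;
}
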