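#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Grid fit of the heterozygote relative risk r1 to observed mating-type
// ratios, plus the multinomial bootstrap of var(log r1). The theoretical
// ratio grid (4 x G, additive constraint r2 = 2*r1 - 1) is precomputed in R
// once per session; the observed ratios and flags mirror
// grr_observed_ratios() exactly. Cell order: 0/0 0/1 0/2 1/1 1/2 2/2.

static void observed_ratios(const double *c, double *rho, bool *est) {
  // cell order: 0=0/0 1=0/1 2=0/2 3=1/1 4=1/2 5=2/2
  // rho1 = c12^2/(c11*c22); rho2 = c02^2/(c00*c22);
  // rho3 = c01*c12/(c02*c11); rho4 = c01*c12/(c00*c22)
  const int num1[4] = {4, 2, 1, 1}, num2[4] = {4, 2, 4, 4};
  const int den1[4] = {3, 0, 2, 0}, den2[4] = {5, 5, 3, 5};
  for (int k = 0; k < 4; ++k) {
    double n1 = c[num1[k]], n2 = c[num2[k]], d1 = c[den1[k]], d2 = c[den2[k]];
    est[k] = n1 > 0 && n2 > 0 && d1 > 0 && d2 > 0;
    rho[k] = est[k] ? (n1 * n2) / (d1 * d2) : NA_REAL;
  }
}

// workspace holding the grid in point-major layout (4 values per grid point,
// contiguous) plus a distance buffer for the full scan
struct GridWork {
  int G;
  std::vector<double> thp;   // G x 4, point-major
  std::vector<double> dist;  // G
  explicit GridWork(const NumericMatrix &grid_ratios)
      : G(grid_ratios.ncol()), thp((size_t)4 * grid_ratios.ncol()),
        dist(grid_ratios.ncol()) {
    for (int g = 0; g < G; ++g)
      for (int k = 0; k < 4; ++k) thp[(size_t)g * 4 + k] = grid_ratios(k, g);
  }
};

static inline double point_dist(const GridWork &w, int g, const double *rho,
                                const bool *est) {
  const double *t = &w.thp[(size_t)g * 4];
  double d = 0.0;
  for (int k = 0; k < 4; ++k)
    if (est[k]) d += std::fabs(t[k] - rho[k]);
  return d;
}

// index of the grid point minimising the sum of absolute distances over the
// estimable ratios (first/smallest r1 on ties); -1 when none is estimable.
// Exhaustive scan of the whole grid.
static int fit_index(const double *counts, GridWork &w) {
  double rho[4];
  bool est[4];
  observed_ratios(counts, rho, est);
  if (!(est[0] || est[1] || est[2] || est[3])) return -1;
  int best = 0;
  double best_d = R_PosInf;
  for (int g = 0; g < w.G; ++g) {
    double d = point_dist(w, g, rho, est);
    if (d < best_d) { best_d = d; best = g; }
  }
  return best;
}

// Hierarchical scan of the same grid: coarse pass at COARSE-point stride,
// then exhaustive refinement of the windows around the best few coarse
// points. The distance profile is a sum of at most four |smooth U-shaped
// curve - constant| terms, so its basins are wide relative to the stride;
// keeping several candidate basins also resolves the near-symmetric
// risk/protective pair of minima. Agreement with the exhaustive scan is
// checked in the tests.
#define COARSE 8
#define NBASIN 3
static int fit_index_fast(const double *counts, GridWork &w) {
  double rho[4];
  bool est[4];
  observed_ratios(counts, rho, est);
  if (!(est[0] || est[1] || est[2] || est[3])) return -1;
  const int G = w.G;
  // best coarse point per distinct basin: candidates closer than 2*COARSE
  // are treated as the same basin and merged
  int bidx[NBASIN];
  double bd[NBASIN];
  int nb = 0;
  for (int g = 0; g < G; g += COARSE) {
    double d = point_dist(w, g, rho, est);
    int same = -1;
    for (int s = 0; s < nb; ++s)
      if (g - bidx[s] <= 2 * COARSE && bidx[s] - g <= 2 * COARSE) { same = s; break; }
    if (same >= 0) {
      if (d < bd[same]) { bd[same] = d; bidx[same] = g; }
      continue;
    }
    // insert as a new basin candidate, keeping the NBASIN best
    int worst = 0;
    for (int s = 1; s < nb; ++s) if (bd[s] > bd[worst]) worst = s;
    if (nb < NBASIN) { bidx[nb] = g; bd[nb] = d; ++nb; }
    else if (d < bd[worst]) { bidx[worst] = g; bd[worst] = d; }
  }
  int best = -1;
  double best_d = R_PosInf;
  for (int s = 0; s < nb; ++s) {
    int lo = bidx[s] - COARSE; if (lo < 0) lo = 0;
    int hi = bidx[s] + COARSE; if (hi >= G) hi = G - 1;
    for (int g = lo; g <= hi; ++g) {
      double d = point_dist(w, g, rho, est);
      if (d < best_d || (d == best_d && g < best)) { best_d = d; best = g; }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_grr_fit(NumericVector counts, NumericVector grid_r1,
                 NumericMatrix grid_ratios) {
  GridWork w(grid_ratios);
  int idx = fit_index(counts.begin(), w);
  double rho[4];
  bool est[4];
  observed_ratios(counts.begin(), rho, est);
  return List::create(
      _["r1"] = idx < 0 ? NA_REAL : grid_r1[idx],
      _["r2"] = idx < 0 ? NA_REAL : 2.0 * grid_r1[idx] - 1.0,
      _["n_estimable"] = (int)(est[0] + est[1] + est[2] + est[3]));
}

static double bootstrap_var(const double *counts, int B,
                            const NumericVector &grid_r1, GridWork &w) {
  double n = 0.0;
  for (int k = 0; k < 6; ++k) n += counts[k];
  if (n <= 0) return NA_REAL;
  double prob[6];
  for (int k = 0; k < 6; ++k) prob[k] = counts[k] / n;
  int draw[6];
  double resampled[6];
  double sum = 0.0, sumsq = 0.0;
  int ok = 0;
  for (int b = 0; b < B; ++b) {
    R::rmultinom((int)n, prob, 6, draw);
    for (int k = 0; k < 6; ++k) resampled[k] = draw[k];
    int idx = fit_index_fast(resampled, w);
    if (idx < 0) continue;
    double lg = std::log(grid_r1[idx]);
    sum += lg;
    sumsq += lg * lg;
    ++ok;
  }
  if (ok < 10) return NA_REAL;
  return (sumsq - sum * sum / ok) / (ok - 1);
}

// [[Rcpp::export]]
double cpp_grr_bootstrap(NumericVector counts, int B, NumericVector grid_r1,
                         NumericMatrix grid_ratios) {
  GridWork w(grid_ratios);
  return bootstrap_var(counts.begin(), B, grid_r1, w);
}

// fit + bootstrap + normalised lr for a 6 x V matrix of mating-type counts
// [[Rcpp::export]]
List cpp_grr_lr(NumericMatrix counts, int B, NumericVector grid_r1,
                NumericMatrix grid_ratios) {
  GridWork w(grid_ratios);
  int V = counts.ncol();
  NumericVector r1(V, NA_REAL), r2(V, NA_REAL), varlog(V, NA_REAL), lr(V);
  IntegerVector n_est(V);
  for (int v = 0; v < V; ++v) {
    const double *c = &counts(0, v);
    double rho[4];
    bool est[4];
    observed_ratios(c, rho, est);
    n_est[v] = est[0] + est[1] + est[2] + est[3];
    int idx = fit_index(c, w);
    lr[v] = 0.0;
    if (idx < 0) continue;
    r1[v] = grid_r1[idx];
    r2[v] = 2.0 * r1[v] - 1.0;
    double vl = bootstrap_var(c, B, grid_r1, w);
    varlog[v] = vl;
    if (!ISNA(vl) && vl > 0) lr[v] = std::log(r1[v]) / std::sqrt(vl);
  }
  return List::create(_["r1"] = r1, _["r2"] = r2, _["var_log_r1"] = varlog,
                      _["lr"] = lr, _["n_estimable"] = n_est);
}

// exposed for the test suite: both scan strategies on the same counts
// [[Rcpp::export]]
IntegerVector cpp_grr_fit_both(NumericVector counts, NumericMatrix grid_ratios) {
  GridWork w(grid_ratios);
  return IntegerVector::create(fit_index(counts.begin(), w) + 1,
                               fit_index_fast(counts.begin(), w) + 1);
}
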