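#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cmath>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Adaptive sign-flip permutation engine for the combined region statistic.
//
// Families' scores D (families x variants) are flipped by one +/-1 sign per
// family and per chromosome (all variants of a chromosome share the sign,
// preserving LD; all units of a family flip together, preserving linkage).
// Per permutation the per-variant statistics X = (sum_i s_i D_i)^2 / sum_i
// D_i^2 are recomputed (denominators are sign-invariant), the ordered-subset
// common statistic is re-evaluated on the FIXED |lr| ordering, the rare
// burden is summed per MAF threshold, and the combined statistics M_t are
// stored. After each batch the per-threshold means/SDs are recomputed from
// all permutations so far, observed and permuted values are standardised,
// and exceedances of the maximum standardised statistic are recounted over
// the full history. Stops at >= target exceedances once >= min_K
// permutations are done, or at max_K.

struct RegionStats {
  double C, min_p;
  int subset_size;
  std::vector<double> R_t, M_t;
};

static void eval_stats(const std::vector<double> &X,
                       const std::vector<int> &ord,
                       const std::vector<std::vector<int> > &rare,
                       double gate, RegionStats &out) {
  double cum = 0.0, min_p = 1.0, s_at = 0.0;
  int k_at = 0;
  for (size_t i = 0; i < ord.size(); ++i) {
    cum += X[ord[i]];
    double p = R::pchisq(cum, (double)(i + 1), 0, 0);
    if (p < min_p) { min_p = p; s_at = cum; k_at = (int)(i + 1); }
  }
  out.min_p = min_p;
  out.C = (min_p <= gate) ? s_at : 0.0;
  out.subset_size = (min_p <= gate) ? k_at : 0;
  size_t T = rare.size();
  out.R_t.assign(T, 0.0);
  out.M_t.assign(T, 0.0);
  for (size_t t = 0; t < T; ++t) {
    double r = 0.0;
    for (size_t j = 0; j < rare[t].size(); ++j) r += X[rare[t][j]];
    out.R_t[t] = r;
    out.M_t[t] = r + out.C;
  }
}

// [[Rcpp::export]]
List cpp_perm_engine(NumericMatrix D, IntegerVector chrom, int nchrom,
                     IntegerVector ord_in, List rare_in, double gate,
                     int min_K, int target_exc, int max_K, int batch) {
  int F = D.nrow(), V = D.ncol();
  int T = rare_in.size();
  std::vector<int> ord(ord_in.begin(), ord_in.end());
  std::vector<std::vector<int> > rare(T);
  for (int t = 0; t < T; ++t) {
    IntegerVector ix = rare_in[t];
    rare[t].assign(ix.begin(), ix.end());
  }

  std::vector<double> denom(V, 0.0);
  for (int v = 0; v < V; ++v) {
    double s = 0.0;
    for (int i = 0; i < F; ++i) { double d = D(i, v); s += d * d; }
    denom[v] = s;
  }

  // observed statistics (identity signs)
  std::vector<double> X(V, 0.0);
  for (int v = 0; v < V; ++v) {
    double num = 0.0;
    for (int i = 0; i < F; ++i) num += D(i, v);
    X[v] = denom[v] > 0 ? num * num / denom[v] : 0.0;
  }
  RegionStats obs;
  eval_stats(X, ord, rare, gate, obs);

  // contiguous per-chromosome blocks of D
  std::vector<std::vector<int> > cols(nchrom);
  for (int v = 0; v < V; ++v) cols[chrom[v]].push_back(v);
  std::vector<std::vector<double> > Dblk(nchrom);
  for (int c = 0; c < nchrom; ++c) {
    int Vc = (int)cols[c].size();
    Dblk[c].resize((size_t)F * Vc);
    for (int j = 0; j < Vc; ++j)
      for (int i = 0; i < F; ++i)
        Dblk[c][(size_t)j * F + i] = D(i, cols[c][j]);
  }

  std::vector<double> pm;  // permuted M_t, row-major K x T
  pm.reserve((size_t)std::min(max_K, 100000) * T);
  std::vector<double> signs, numer, numall;
  RegionStats per;
  int K = 0, exceed = 0;
  double M_obs = 0.0;
  std::vector<double> mu(T, 0.0), sd(T, 0.0), z(T, 0.0);

  while (K < max_K) {
    int B = std::min(batch, max_K - K);
    signs.resize((size_t)B * F);
    numall.resize((size_t)B * V);  // numerators, column-major by variant
    for (int c = 0; c < nchrom; ++c) {
      int Vc = (int)cols[c].size();
      if (Vc == 0) continue;
      for (size_t q = 0; q < signs.size(); ++q)
        signs[q] = R::unif_rand() < 0.5 ? -1.0 : 1.0;
      numer.resize((size_t)B * Vc);
      const double one = 1.0, zero = 0.0;
      F77_CALL(dgemm)("N", "N", &B, &Vc, &F, &one, signs.data(), &B,
                      Dblk[c].data(), &F, &zero, numer.data(), &B
                      FCONE FCONE);
      for (int j = 0; j < Vc; ++j)
        std::copy(numer.begin() + (size_t)j * B,
                  numer.begin() + (size_t)(j + 1) * B,
                  numall.begin() + (size_t)cols[c][j] * B);
    }
    for (int b = 0; b < B; ++b) {
      for (int v = 0; v < V; ++v) {
        double n = numall[(size_t)v * B + b];
        X[v] = denom[v] > 0 ? n * n / denom[v] : 0.0;
      }
      eval_stats(X, ord, rare, gate, per);
      for (int t = 0; t < T; ++t) pm.push_back(per.M_t[t]);
    }
    K += B;

    // restandardise from the full permutation history
    for (int t = 0; t < T; ++t) { mu[t] = 0.0; sd[t] = 0.0; }
    for (int k = 0; k < K; ++k)
      for (int t = 0; t < T; ++t) mu[t] += pm[(size_t)k * T + t];
    for (int t = 0; t < T; ++t) mu[t] /= K;
    for (int k = 0; k < K; ++k)
      for (int t = 0; t < T; ++t) {
        double d = pm[(size_t)k * T + t] - mu[t];
        sd[t] += d * d;
      }
    for (int t = 0; t < T; ++t)
      sd[t] = K > 1 ? std::sqrt(sd[t] / (K - 1)) : 0.0;

    M_obs = R_NegInf;
    for (int t = 0; t < T; ++t) {
      z[t] = sd[t] > 0 ? (obs.M_t[t] - mu[t]) / sd[t] : 0.0;
      if (z[t] > M_obs) M_obs = z[t];
    }
    exceed = 0;
    for (int k = 0; k < K; ++k) {
      double Mi = R_NegInf;
      for (int t = 0; t < T; ++t) {
        double zi = sd[t] > 0 ? (pm[(size_t)k * T + t] - mu[t]) / sd[t] : 0.0;
        if (zi > Mi) Mi = zi;
      }
      if (Mi > M_obs) ++exceed;
    }
    if (exceed >= target_exc && K >= min_K) break;
  }

  int best_t = 0;
  for (int t = 1; t < T; ++t) if (z[t] > z[best_t]) best_t = t;
  return List::create(
      _["p_value"] = (exceed + 1.0) / (K + 1.0), _["K"] = K,
      _["exceedances"] = exceed, _["C"] = obs.C, _["min_p"] = obs.min_p,
      _["subset_size"] = obs.subset_size, _["R_t"] = obs.R_t,
      _["M_t"] = obs.M_t, _["std_M_t"] = std::vector<double>(z),
      _["M"] = M_obs, _["best_t"] = best_t + 1);
}
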