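#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Kingman coalescent haplotype pools under a three-epoch demographic model:
// exponential expansion (relative size exp(-growth*t), looking backward)
// until t_growth, a constant bottleneck size until t_anc, and a constant
// ancient size (anc_scale x bottleneck) beyond. Time is scaled in units of
// 2*N0 generations.
//
// A region is simulated as a set of recombination segments, each with an
// independent genealogy (the ancestral recombination graph collapsed to
// independent marginal trees). Mutations are dropped on branches
// proportionally to length (infinite sites); each mutation defines one
// polymorphic site whose derived carriers are the tips below the branch.
// Sites are returned as contiguous ranges in the segment's DFS tip
// ordering, so a carrier lookup is two integer comparisons against the
// haplotype's per-segment tip position.

// waiting time to the next coalescence from time t with k lineages, under
// three epochs: exponential growth on [0, t_growth], a constant bottleneck
// size on (t_growth, t_anc], and a constant ancient size (anc_scale times
// the bottleneck size) beyond t_anc
static double next_coal_time(double t, int k, double growth, double t_growth,
                             double t_anc, double anc_scale) {
  double C = k * (k - 1.0) / 2.0;
  double E = R::exp_rand();
  if (growth <= 0.0) return t + E / C;
  double lam_b = std::exp(-growth * t_growth);
  if (t < t_growth) {
    // integrated hazard over the growth phase: C*(e^{g(t+w)} - e^{gt})/g
    double h_to_end = C * (std::exp(growth * t_growth) - std::exp(growth * t)) / growth;
    if (E <= h_to_end) {
      double w = std::log(std::exp(growth * t) + E * growth / C) / growth - t;
      return t + w;
    }
    E -= h_to_end;
    t = t_growth;
  }
  if (t < t_anc) {
    double h_to_end = C * (t_anc - t) / lam_b;
    if (E <= h_to_end) return t + E * lam_b / C;
    E -= h_to_end;
    t = t_anc;
  }
  return t + E * (anc_scale * lam_b) / C;
}

// one marginal tree: fills the segment's tip ordering and appends its sites
static double simulate_tree(int n_hap, double theta, double growth,
                            double t_growth, double t_anc, double anc_scale,
                            int *tip_index_col,
                            std::vector<int> &site_lo,
                            std::vector<int> &site_hi) {
  int n_nodes = 2 * n_hap - 1;
  std::vector<int> left(n_nodes, -1), right(n_nodes, -1);
  std::vector<double> time(n_nodes, 0.0), blen(n_nodes, 0.0);
  std::vector<int> active(n_hap);
  for (int i = 0; i < n_hap; ++i) active[i] = i;

  double t = 0.0;
  int next_node = n_hap;
  int k = n_hap;
  while (k > 1) {
    t = next_coal_time(t, k, growth, t_growth, t_anc, anc_scale);
    int i = (int)std::floor(R::unif_rand() * k);
    if (i >= k) i = k - 1;
    int a = active[i];
    active[i] = active[k - 1];
    int j = (int)std::floor(R::unif_rand() * (k - 1));
    if (j >= k - 1) j = k - 2;
    int b = active[j];
    int p = next_node++;
    time[p] = t;
    left[p] = a;
    right[p] = b;
    active[j] = p;
    --k;
  }
  int root = n_nodes - 1;

  double total_len = 0.0;
  std::vector<int> parent(n_nodes, -1);
  for (int p = n_hap; p < n_nodes; ++p) {
    parent[left[p]] = p;
    parent[right[p]] = p;
  }
  for (int v = 0; v < n_nodes; ++v) {
    if (v == root) continue;
    blen[v] = time[parent[v]] - time[v];
    total_len += blen[v];
  }

  // DFS tip ordering with contiguous [lo, hi] per node (1-based)
  std::vector<int> lo(n_nodes), hi(n_nodes);
  {
    std::vector<int> stack;
    std::vector<int> state(n_nodes, 0);
    stack.reserve(n_nodes);
    stack.push_back(root);
    int tip_at = 0;
    while (!stack.empty()) {
      int v = stack.back();
      if (v < n_hap) {
        tip_index_col[v] = ++tip_at;
        lo[v] = hi[v] = tip_at;
        stack.pop_back();
        continue;
      }
      if (state[v] == 0) {
        state[v] = 1;
        stack.push_back(left[v]);
      } else if (state[v] == 1) {
        state[v] = 2;
        stack.push_back(right[v]);
      } else {
        lo[v] = std::min(lo[left[v]], lo[right[v]]);
        hi[v] = std::max(hi[left[v]], hi[right[v]]);
        stack.pop_back();
      }
    }
  }

  // mutations: Poisson(theta/2 * L), branch chosen proportional to length
  int n_mut = (int)R::rpois(0.5 * theta * total_len);
  std::vector<double> cum(n_nodes, 0.0);
  double acc = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    acc += blen[v];
    cum[v] = acc;
  }
  for (int m = 0; m < n_mut; ++m) {
    double u = R::unif_rand() * total_len;
    int a = 0, b = n_nodes - 1;
    while (a < b) {
      int mid = (a + b) / 2;
      if (cum[mid] < u) a = mid + 1; else b = mid;
    }
    site_lo.push_back(lo[a]);
    site_hi.push_back(hi[a]);
  }
  return total_len;
}

// thetas: mutation parameter per segment (region theta split by segment
// length); one independent tree per segment
// [[Rcpp::export]]
List cpp_coalescent_pool(int n_hap, NumericVector thetas, double growth,
                         double t_growth, double t_anc, double anc_scale) {
  int n_seg = thetas.size();
  IntegerMatrix tip_index(n_hap, n_seg);
  std::vector<int> site_lo, site_hi, site_seg;
  NumericVector lengths(n_seg);
  for (int s = 0; s < n_seg; ++s) {
    size_t before = site_lo.size();
    lengths[s] = simulate_tree(n_hap, thetas[s], growth, t_growth, t_anc,
                               anc_scale, &tip_index(0, s), site_lo, site_hi);
    for (size_t m = before; m < site_lo.size(); ++m) site_seg.push_back(s + 1);
  }
  return List::create(_["lo"] = wrap(site_lo), _["hi"] = wrap(site_hi),
                      _["seg"] = wrap(site_seg), _["tip_index"] = tip_index,
                      _["tree_lengths"] = lengths);
}

// Ascertained nuclear families from a haplotype pool. Parents are random
// pool haplotype pairs (with replacement); each child inherits one whole
// haplotype from each parent (no meiotic recombination at this scale);
// affection is Bernoulli(plogis(alpha + sum beta*g)) over the causal sites
// (beta in derived-allele dosage coding); the whole family is redrawn until
// the required affection pattern holds exactly.
// [[Rcpp::export]]
List cpp_simulate_families(IntegerVector lo, IntegerVector hi,
                           IntegerVector seg, IntegerMatrix tip_index,
                           int n_hap, NumericVector beta,
                           IntegerVector causal, double alpha, int n_fam,
                           LogicalVector pattern, int max_tries) {
  int S = lo.size();
  int n_child = pattern.size();
  int fam_rows = 2 + n_child;
  int nc = causal.size();
  IntegerMatrix geno(n_fam * fam_rows, S);
  std::vector<int> child_h1(n_child), child_h2(n_child);

#define CARRIES(h, s) \
  (tip_index((h), seg[(s)] - 1) >= lo[(s)] && tip_index((h), seg[(s)] - 1) <= hi[(s)])

  for (int f = 0; f < n_fam; ++f) {
    bool ok = false;
    int f1 = 0, f2 = 0, m1 = 0, m2 = 0;
    for (int tries = 0; tries < max_tries && !ok; ++tries) {
      f1 = (int)(R::unif_rand() * n_hap); if (f1 >= n_hap) f1 = n_hap - 1;
      f2 = (int)(R::unif_rand() * n_hap); if (f2 >= n_hap) f2 = n_hap - 1;
      m1 = (int)(R::unif_rand() * n_hap); if (m1 >= n_hap) m1 = n_hap - 1;
      m2 = (int)(R::unif_rand() * n_hap); if (m2 >= n_hap) m2 = n_hap - 1;
      ok = true;
      for (int c = 0; c < n_child; ++c) {
        int hf = (R::unif_rand() < 0.5) ? f1 : f2;
        int hm = (R::unif_rand() < 0.5) ? m1 : m2;
        child_h1[c] = hf;
        child_h2[c] = hm;
        double score = alpha;
        for (int q = 0; q < nc; ++q) {
          int s = causal[q];
          int g = CARRIES(hf, s) + CARRIES(hm, s);
          if (g) score += beta[s] * g;
        }
        bool aff = R::unif_rand() < 1.0 / (1.0 + std::exp(-score));
        if (aff != (bool)pattern[c]) { ok = false; break; }
      }
    }
    if (!ok) stop("family rejection sampling exceeded max_tries; "
                  "check the disease model calibration");
    int base = f * fam_rows;
    for (int s = 0; s < S; ++s) {
      geno(base, s) = CARRIES(f1, s) + CARRIES(f2, s);
      geno(base + 1, s) = CARRIES(m1, s) + CARRIES(m2, s);
      for (int c = 0; c < n_child; ++c)
        geno(base + 2 + c, s) = CARRIES(child_h1[c], s) + CARRIES(child_h2[c], s);
    }
  }
#undef CARRIES
  return List::create(_["geno"] = geno);
}
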