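#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Uses R's RNG throughout so that results are reproducible via set.seed()
// on the R side. u_pin (when not NA) freezes the stochastic factor of the
// neighborhood function, used for degeneracy tests.

static inline double draw_u(double u_pin) {
  if (ISNA(u_pin)) return 0.5 + 0.5 * unif_rand();
  return u_pin;
}

// pairwise adjacency accuracy of a clustering given as contingency groups,
// with a vertex permutation applied to the predicted side.
// gd/gv: true-domain and predicted-vertex index per nonzero group, gN counts.
static double perm_accuracy(const std::vector<int>& gd,
                            const std::vector<int>& gv,
                            const std::vector<double>& gN,
                            const NumericMatrix& adj,
                            const std::vector<int>& perm,
                            double within_correct, double total_pairs) {
  double correct = within_correct;
  const int G = gd.size();
  for (int a = 0; a < G; ++a) {
    const double Na = gN[a];
    const int da = gd[a], va = perm[gv[a]];
    for (int b = a + 1; b < G; ++b) {
      if (adj(da, gd[b]) == adj(va, perm[gv[b]])) correct += Na * gN[b];
    }
  }
  return correct / total_pairs;
}

static double ari_from_ct(const std::vector<double>& ct, int m, int k, double n) {
  std::vector<double> a(m, 0.0), b(k, 0.0);
  double sum_ij = 0.0;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < k; ++j) {
      double v = ct[i * k + j];
      a[i] += v;
      b[j] += v;
      sum_ij += v * (v - 1) / 2;
    }
  }
  double sum_a = 0.0, sum_b = 0.0;
  for (int i = 0; i < m; ++i) sum_a += a[i] * (a[i] - 1) / 2;
  for (int j = 0; j < k; ++j) sum_b += b[j] * (b[j] - 1) / 2;
  double expected = sum_a * sum_b / (n * (n - 1) / 2);
  double denom = (sum_a + sum_b) / 2 - expected;
  if (denom == 0.0) {
    // degenerate: 1 iff partitions identical up to relabeling
    for (int i = 0; i < m; ++i) {
      int nz = 0;
      for (int j = 0; j < k; ++j) if (ct[i * k + j] > 0) ++nz;
      if (nz > 1) return 0.0;
    }
    for (int j = 0; j < k; ++j) {
      int nz = 0;
      for (int i = 0; i < m; ++i) if (ct[i * k + j] > 0) ++nz;
      if (nz > 1) return 0.0;
    }
    return 1.0;
  }
  return (sum_ij - expected) / denom;
}

// Batch-learning stochastic graph-SOM fit with simulated-annealing
// optimization of the cluster-to-vertex allocation, then scoring.
//
// X: cells x genes; dist: k x k graph distances (sentinel for unreachable);
// adj: k x k adjacency; true_idx: 0-based true-domain vertex index per cell.
// [[Rcpp::export]]
List gsom_fit_cpp(NumericMatrix X, NumericMatrix dist, NumericMatrix adj,
                  IntegerVector true_idx, int som_steps,
                  double sigma0, double sigma_final,
                  int alloc_steps, double weight_a, double u_pin,
                  Nullable<NumericMatrix> init) {
  const int n = X.nrow(), p = X.ncol(), k = dist.nrow();
  if (n < 1 || p < 1) stop("need at least one cell and one gene");
  if (sigma0 <= 0 || sigma_final <= 0) stop("sigma must be positive");

  // squared unit distances
  std::vector<double> d2(k * k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) d2[i * k + j] = dist(i, j) * dist(i, j);

  // centroid initialization: uniform within per-gene observed range
  NumericMatrix M(k, p);
  if (init.isNotNull()) {
    NumericMatrix M0(init);
    if (M0.nrow() != k || M0.ncol() != p) stop("init centroid dimensions wrong");
    M = clone(M0);
  } else {
    for (int d = 0; d < p; ++d) {
      double lo = X(0, d), hi = X(0, d);
      for (int j = 1; j < n; ++j) {
        if (X(j, d) < lo) lo = X(j, d);
        if (X(j, d) > hi) hi = X(j, d);
      }
      for (int i = 0; i < k; ++i) M(i, d) = lo + (hi - lo) * unif_rand();
    }
  }

  std::vector<int> bmu(n);
  std::vector<double> num(k * p), den(k);

  for (int t = 0; t < som_steps; ++t) {
    double frac = som_steps > 1 ? (double)t / (som_steps - 1) : 0.0;
    double sigma = sigma0 * std::pow(sigma_final / sigma0, frac);
    double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    // best matching units (ties -> lowest index)
    for (int j = 0; j < n; ++j) {
      int best = 0;
      double bestd = R_PosInf;
      for (int i = 0; i < k; ++i) {
        double s = 0.0;
        for (int d = 0; d < p; ++d) {
          double diff = X(j, d) - M(i, d);
          s += diff * diff;
        }
        if (s < bestd) { bestd = s; best = i; }
      }
      bmu[j] = best;
    }
    // weighted batch update; one fresh stochastic draw per (cell, vertex)
    std::fill(num.begin(), num.end(), 0.0);
    std::fill(den.begin(), den.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const int c = bmu[j];
      for (int i = 0; i < k; ++i) {
        double w = std::exp(-draw_u(u_pin) * d2[c * k + i] * inv2s2);
        den[i] += w;
        for (int d = 0; d < p; ++d) num[i * p + d] += w * X(j, d);
      }
    }
    for (int i = 0; i < k; ++i) {
      if (den[i] <= 0.0) stop("zero weight sum for a vertex");
      for (int d = 0; d < p; ++d) M(i, d) = num[i * p + d] / den[i];
    }
  }

  // final assignment
  for (int j = 0; j < n; ++j) {
    int best = 0;
    double bestd = R_PosInf;
    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      for (int d = 0; d < p; ++d) {
        double diff = X(j, d) - M(i, d);
        s += diff * diff;
      }
      if (s < bestd) { bestd = s; best = i; }
    }
    bmu[j] = best;
  }

  // contingency table true domain x predicted vertex
  std::vector<double> ct(k * k, 0.0);
  for (int j = 0; j < n; ++j) ct[true_idx[j] * k + bmu[j]] += 1.0;

  double ari = n >= 2 ? ari_from_ct(ct, k, k, (double)n) : 1.0;

  std::vector<int> gd, gv;
  std::vector<double> gN;
  double within_correct = 0.0;
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j < k; ++j) {
      double v = ct[i * k + j];
      if (v > 0) {
        gd.push_back(i);
        gv.push_back(j);
        gN.push_back(v);
        within_correct += v * (v - 1) / 2;
      }
    }
  }
  double total_pairs = (double)n * (n - 1) / 2.0;
  if (total_pairs < 1) total_pairs = 1;  // single cell: vacuous accuracy 1

  std::vector<int> perm(k), best_perm(k);
  for (int i = 0; i < k; ++i) perm[i] = i;
  best_perm = perm;
  double acc_cur = perm_accuracy(gd, gv, gN, adj, perm, within_correct, total_pairs);
  const double acc_identity = acc_cur;
  double best_acc = acc_cur;

  if (alloc_steps > 0 && k >= 2) {
    const int npairs = k * (k - 1) / 2;
    std::vector<int> pi_(npairs), pj_(npairs);
    {
      int q = 0;
      for (int i = 0; i < k - 1; ++i)
        for (int j = i + 1; j < k; ++j) { pi_[q] = i; pj_[q] = j; ++q; }
    }
    const double cexp = std::sqrt((double)k / 2.0);
    std::vector<double> accs(npairs), probs(npairs);
    std::vector<int> tmp(k);
    for (int t = 0; t < alloc_steps; ++t) {
      double T_t = std::pow(0.001, (double)t / alloc_steps);
      for (int q = 0; q < npairs; ++q) {
        tmp = perm;
        std::swap(tmp[pi_[q]], tmp[pj_[q]]);
        accs[q] = perm_accuracy(gd, gv, gN, adj, tmp, within_correct, total_pairs);
      }
      // standardized softmax, population SD; uniform fallback when flat
      double mu = 0.0;
      for (int q = 0; q < npairs; ++q) mu += accs[q];
      mu /= npairs;
      double var = 0.0;
      for (int q = 0; q < npairs; ++q) var += (accs[q] - mu) * (accs[q] - mu);
      double sd = std::sqrt(var / npairs);
      if (sd == 0.0) {
        for (int q = 0; q < npairs; ++q) probs[q] = 1.0 / npairs;
      } else {
        double zmax = R_NegInf;
        for (int q = 0; q < npairs; ++q) {
          probs[q] = cexp * (accs[q] - mu) / sd;
          if (probs[q] > zmax) zmax = probs[q];
        }
        double tot = 0.0;
        for (int q = 0; q < npairs; ++q) {
          probs[q] = std::exp(probs[q] - zmax);
          tot += probs[q];
        }
        for (int q = 0; q < npairs; ++q) probs[q] /= tot;
      }
      // sample a pair
      double r = unif_rand(), cum = 0.0;
      int sel = npairs - 1;
      for (int q = 0; q < npairs; ++q) {
        cum += probs[q];
        if (r < cum) { sel = q; break; }
      }
      double delta_f = acc_cur - accs[sel];
      double p_sa = delta_f <= 0 ? 1.0 : std::exp(-delta_f / T_t);
      if (p_sa >= 1.0 || unif_rand() < p_sa) {
        std::swap(perm[pi_[sel]], perm[pj_[sel]]);
        acc_cur = accs[sel];
        if (acc_cur > best_acc) { best_acc = acc_cur; best_perm = perm; }
      }
    }
  }

  IntegerVector assignment(n);
  for (int j = 0; j < n; ++j) assignment[j] = best_perm[bmu[j]] + 1;
  NumericMatrix Mout(k, p);
  for (int i = 0; i < k; ++i)
    for (int d = 0; d < p; ++d) Mout(best_perm[i], d) = M(i, d);

  double score = best_acc + weight_a * ari;
  return List::create(_["assignment"] = assignment,
                      _["accuracy"] = best_acc,
                      _["accuracy_raw"] = acc_identity,
                      _["ari"] = ari,
                      _["score"] = score,
                      _["centroids"] = Mout);
}
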