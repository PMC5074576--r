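#include <Rcpp.h>
#include <vector>
#include <set>
#include <utility>
using namespace Rcpp;

// Null distribution of the size-preference overlap statistic T under
// matrix randomization: the 120 unique off-diagonal values are permuted
// uniformly, mirrored to symmetry, and the top-k (or bottom-k, for the
// avoidance variant) partners of each row are intersected with the
// preference mask. Ties inside top-k selection are broken by the random
// placement of the permuted values, so tie order is itself random.
// Uses R's RNG (RNGScope injected by Rcpp attributes), so results are
// reproducible under set.seed().

// [[Rcpp::export]]
IntegerVector cpp_null_stats(NumericMatrix m, LogicalMatrix pref, int k_if,
                             bool lowest, IntegerVector rows, int iters) {
  const int n = m.nrow();
  const int nu = n * (n - 1) / 2;
  std::vector<double> vals(nu);
  std::vector<int> ui(nu), uj(nu);
  int k = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      vals[k] = m(i, j);
      ui[k] = i;
      uj[k] = j;
      ++k;
    }
  NumericMatrix w(n, n);
  IntegerVector out(iters);
  std::vector<bool> used(n);
  for (int it = 0; it < iters; ++it) {
    for (int a = nu - 1; a > 0; --a) {
      int b = (int)(unif_rand() * (a + 1));
      if (b > a) b = a;
      std::swap(vals[a], vals[b]);
    }
    for (int q = 0; q < nu; ++q) {
      w(ui[q], uj[q]) = vals[q];
      w(uj[q], ui[q]) = vals[q];
    }
    int T = 0;
    for (int ri = 0; ri < rows.size(); ++ri) {
      int r = rows[ri];
      std::fill(used.begin(), used.end(), false);
      used[r] = true;
      for (int s = 0; s < k_if; ++s) {
        int best = -1;
        double bv = 0.0;
        for (int j = 0; j < n; ++j) {
          if (used[j]) continue;
          double v = w(r, j);
          if (best < 0 || (lowest ? v < bv : v > bv)) {
            best = j;
            bv = v;
          }
        }
        used[best] = true;
        if (pref(r, best)) ++T;
      }
    }
    out[it] = T;
  }
  return out;
}

// Alternative randomization mode: permute the chromosome labels of the
// matrix instead of its values. Per-row top-k sets are fixed, only their
// identities move.

// [[Rcpp::export]]
IntegerVector cpp_label_null_stats(IntegerMatrix topk, LogicalMatrix pref,
                                   IntegerVector rows, int iters) {
  const int n = pref.nrow();
  const int kk = topk.ncol();
  IntegerVector out(iters);
  std::vector<int> s(n), sinv(n);
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < n; ++i) s[i] = i;
    for (int a = n - 1; a > 0; --a) {
      int b = (int)(unif_rand() * (a + 1));
      if (b > a) b = a;
      std::swap(s[a], s[b]);
    }
    for (int i = 0; i < n; ++i) sinv[s[i]] = i;
    int T = 0;
    for (int ri = 0; ri < rows.size(); ++ri) {
      int r = rows[ri];
      int orig = sinv[r];
      for (int q = 0; q < kk; ++q) {
        int t = topk(orig, q);
        if (pref(r, s[t])) ++T;
      }
    }
    out[it] = T;
  }
  return out;
}

// Sequential weighted pairing of chromosomes into couples, one perfect
// matching per cell. An unmatched entity is drawn uniformly; its partner
// is drawn among the remaining unmatched entities with probability
// proportional to w(chrom_u, chrom_v). Dead ends (all remaining weights
// zero, e.g. the last two entities are homologs in diploid mode) restart
// the cell. Each unordered chromosome pair is counted at most once per
// cell, matching what a 3C primer pair can distinguish.

// [[Rcpp::export]]
IntegerMatrix cpp_simulate_cells(NumericMatrix w, IntegerVector chrom_of,
                                 int n_chrom, int n_cells) {
  const int ne = chrom_of.size();
  IntegerMatrix counts(n_chrom, n_chrom);
  std::vector<int> pool;
  std::vector<std::pair<int, int> > pairs;
  for (int cell = 0; cell < n_cells; ++cell) {
    bool ok = false;
    int attempts = 0;
    while (!ok) {
      if (++attempts > 10000)
        stop("pairing repeatedly dead-ends; check the weight matrix");
      pool.clear();
      for (int e = 0; e < ne; ++e) pool.push_back(e);
      pairs.clear();
      ok = true;
      while ((int)pool.size() >= 2) {
        int iu = (int)(unif_rand() * pool.size());
        if (iu >= (int)pool.size()) iu = pool.size() - 1;
        int u = pool[iu];
        pool.erase(pool.begin() + iu);
        double tot = 0.0;
        for (size_t q = 0; q < pool.size(); ++q)
          tot += w(chrom_of[u], chrom_of[pool[q]]);
        if (tot <= 0.0) {
          ok = false;
          break;
        }
        double r = unif_rand() * tot, acc = 0.0;
        int iv = -1;
        for (size_t q = 0; q < pool.size(); ++q) {
          acc += w(chrom_of[u], chrom_of[pool[q]]);
          if (r <= acc) {
            iv = (int)q;
            break;
          }
        }
        if (iv < 0) iv = pool.size() - 1;
        int v = pool[iv];
        pool.erase(pool.begin() + iv);
        int a = chrom_of[u], b = chrom_of[v];
        if (a > b) std::swap(a, b);
        pairs.push_back(std::make_pair(a, b));
      }
    }
    std::set<std::pair<int, int> > seen(pairs.begin(), pairs.end());
    for (std::set<std::pair<int, int> >::iterator it = seen.begin();
         it != seen.end(); ++it) {
      counts(it->first, it->second) += 1;
      counts(it->second, it->first) += 1;
    }
  }
  return counts;
}
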