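#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Minimum-switch alignment of an estimated K-haplotype block to the truth.
// DP over sites; the state is the permutation mapping estimated rows to truth
// rows. Transition cost between consecutive permutations is their
// transposition distance (K minus the number of cycles of the relative
// permutation) -- one switch exchanges two haplotype assignments, so a single
// two-row swap costs 1 and the diploid case reduces to the classic phase
// scan. Emission cost charges per-row allele mismatches under the current
// permutation (genotype errors), reported separately from switches.

static int transposition_distance(const std::vector<int>& p,
                                  const std::vector<int>& q) {
  int K = p.size();
  // relative permutation rho = q o p^{-1}; distance = K - #cycles(rho)
  std::vector<int> pinv(K), rho(K);
  for (int k = 0; k < K; ++k) pinv[p[k]] = k;
  for (int k = 0; k < K; ++k) rho[k] = q[pinv[k]];
  std::vector<char> seen(K, 0);
  int cycles = 0;
  for (int k = 0; k < K; ++k) {
    if (seen[k]) continue;
    ++cycles;
    int c = k;
    while (!seen[c]) { seen[c] = 1; c = rho[c]; }
  }
  return K - cycles;
}

// [[Rcpp::export]]
List cpp_swer_dp(IntegerMatrix est, IntegerMatrix truth) {
  int K = est.nrow(), n = est.ncol();
  if (truth.nrow() != K || truth.ncol() != n)
    stop("estimate and truth must have identical dimensions");
  if (K > 8) stop("permutation DP refused for K > 8");
  if (n == 0)
    return List::create(_["switches"] = 0.0, _["mismatches"] = 0.0,
                        _["total"] = 0.0);

  // enumerate permutations of 0..K-1
  std::vector<int> base(K);
  for (int k = 0; k < K; ++k) base[k] = k;
  std::vector<std::vector<int> > perms;
  {
    std::vector<int> p = base;
    do { perms.push_back(p); } while (std::next_permutation(p.begin(), p.end()));
  }
  int P = perms.size();

  std::vector<int> D((size_t)P * P);
  for (int a = 0; a < P; ++a)
    for (int b = 0; b < P; ++b)
      D[(size_t)a * P + b] = transposition_distance(perms[a], perms[b]);

  // DP state: (total cost, mismatch share). Among equal-cost paths the one
  // with fewer mismatches (more switches) wins, so an isolated phase flip
  // is charged as two switches -- exactly the diploid scan convention.
  std::vector<double> f(P), fn(P), fm(P), fmn(P);
  std::vector<double> emis(P);

  for (int j = 0; j < n; ++j) {
    for (int a = 0; a < P; ++a) {
      int c = 0;
      for (int l = 0; l < K; ++l) {
        int t = truth(l, j), e = est(perms[a][l], j);
        if (t == NA_INTEGER || e == NA_INTEGER) continue;
        if (t != e) ++c;
      }
      emis[a] = c;
    }
    if (j == 0) {
      for (int a = 0; a < P; ++a) { f[a] = emis[a]; fm[a] = emis[a]; }
      continue;
    }
    for (int a = 0; a < P; ++a) {
      double best = f[a], bestm = fm[a];
      for (int b = 0; b < P; ++b) {
        if (b == a) continue;
        double cand = f[b] + D[(size_t)b * P + a];
        double candm = fm[b];
        if (cand < best || (cand == best && candm < bestm)) {
          best = cand; bestm = candm;
        }
      }
      fn[a] = best + emis[a];
      fmn[a] = bestm + emis[a];
    }
    std::swap(f, fn);
    std::swap(fm, fmn);
  }

  int arg = 0;
  for (int a = 1; a < P; ++a)
    if (f[a] < f[arg] || (f[a] == f[arg] && fm[a] < fm[arg])) arg = a;
  double total = f[arg];
  double mism = fm[arg];

  return List::create(_["switches"] = total - mism,
                      _["mismatches"] = mism,
                      _["total"] = total);
}
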