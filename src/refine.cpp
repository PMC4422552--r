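#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Reads are passed in CSR form: read_ptr (length m+1, 0-based offsets into
// call_snp/call_allele), call_snp 0-based site indices, call_allele codes.

static void hamming_table(const IntegerVector& read_ptr,
                          const IntegerVector& call_snp,
                          const IntegerVector& call_allele,
                          const IntegerMatrix& hap,  // K x n
                          std::vector<int>& hd) {    // m x K, row-major
  int m = read_ptr.size() - 1;
  int K = hap.nrow();
  std::fill(hd.begin(), hd.end(), 0);
  for (int i = 0; i < m; ++i) {
    for (int p = read_ptr[i]; p < read_ptr[i + 1]; ++p) {
      int j = call_snp[p], a = call_allele[p];
      for (int l = 0; l < K; ++l)
        if (hap(l, j) != a) hd[(size_t)i * K + l]++;
    }
  }
}

static long total_mec(const std::vector<int>& hd, int m, int K) {
  long z = 0;
  for (int i = 0; i < m; ++i) {
    int best = INT_MAX;
    for (int l = 0; l < K; ++l) best = std::min(best, hd[(size_t)i * K + l]);
    z += best;
  }
  return z;
}

// [[Rcpp::export]]
double cpp_mec(IntegerVector read_ptr, IntegerVector call_snp,
               IntegerVector call_allele, IntegerMatrix hap) {
  int m = read_ptr.size() - 1, K = hap.nrow();
  std::vector<int> hd((size_t)m * K);
  hamming_table(read_ptr, call_snp, call_allele, hap, hd);
  return (double)total_mec(hd, m, K);
}

// Greedy refinement: sweep sites left to right; at each site try every
// single-haplotype allele alteration (O(K n) candidates per sweep) and accept
// a move iff the block MEC strictly decreases. Repeats until a full sweep
// makes no change or max_sweeps is reached.
// [[Rcpp::export]]
List cpp_greedy_refine(IntegerVector read_ptr, IntegerVector call_snp,
                       IntegerVector call_allele, IntegerMatrix hap0,
                       int alphabet, int max_sweeps) {
  IntegerMatrix hap = clone(hap0);
  int m = read_ptr.size() - 1, K = hap.nrow(), n = hap.ncol();
  int ncalls = call_snp.size();

  // per-site read lists (which calls cover each site)
  std::vector<int> col_ptr(n + 1, 0), col_read(ncalls), col_allele(ncalls);
  for (int p = 0; p < ncalls; ++p) col_ptr[call_snp[p] + 1]++;
  for (int j = 0; j < n; ++j) col_ptr[j + 1] += col_ptr[j];
  {
    std::vector<int> pos(col_ptr.begin(), col_ptr.end() - 1);
    for (int i = 0; i < m; ++i)
      for (int p = read_ptr[i]; p < read_ptr[i + 1]; ++p) {
        int j = call_snp[p];
        col_read[pos[j]] = i;
        col_allele[pos[j]++] = call_allele[p];
      }
  }

  std::vector<int> hd((size_t)m * K);
  hamming_table(read_ptr, call_snp, call_allele, hap, hd);
  long mec = total_mec(hd, m, K);
  int changes = 0, sweep = 0;

  for (; sweep < max_sweeps; ++sweep) {
    bool any = false;
    for (int j = 0; j < n; ++j) {
      bool improved = true;
      while (improved) {
        improved = false;
        long best_delta = 0;
        int best_l = -1, best_a = -1;
        for (int l = 0; l < K; ++l) {
          int cur = hap(l, j);
          for (int a = 0; a < alphabet; ++a) {
            if (a == cur) continue;
            long delta = 0;
            for (int p = col_ptr[j]; p < col_ptr[j + 1]; ++p) {
              int i = col_read[p], obs = col_allele[p];
              int* row = &hd[(size_t)i * K];
              int old_min = INT_MAX, new_min = INT_MAX;
              int dl = ((obs != a) ? 1 : 0) - ((obs != cur) ? 1 : 0);
              for (int k = 0; k < K; ++k) {
                int h = row[k];
                if (h < old_min) old_min = h;
                int h2 = (k == l) ? h + dl : h;
                if (h2 < new_min) new_min = h2;
              }
              delta += new_min - old_min;
            }
            if (delta < best_delta) { best_delta = delta; best_l = l; best_a = a; }
          }
        }
        if (best_l >= 0) {
          int cur = hap(best_l, j);
          for (int p = col_ptr[j]; p < col_ptr[j + 1]; ++p) {
            int i = col_read[p], obs = col_allele[p];
            hd[(size_t)i * K + best_l] +=
              ((obs != best_a) ? 1 : 0) - ((obs != cur) ? 1 : 0);
          }
          hap(best_l, j) = best_a;
          mec += best_delta;
          ++changes;
          any = true;
          improved = true;
        }
      }
    }
    if (!any) { break; }
  }
  return List::create(_["hap"] = hap, _["mec"] = (double)mec,
                      _["sweeps"] = std::min(sweep + 1, max_sweeps),
                      _["changes"] = changes);
}

// Switch-move (recombination) refinement: for every boundary between
// consecutive sites, consider permuting the haplotype tails from the
// boundary onward by a small permutation (a transposition, a 3-cycle or a
// double transposition). Only reads straddling the boundary change their
// score -- reads entirely on one side see a permuted haplotype set, which
// leaves their min-Hamming distance unchanged -- so a move is scored over
// straddling reads only and accepted iff the block MEC strictly decreases.
// These moves escape the mosaic local optima that single-site alterations
// cannot fix (two haplotypes identical over a stretch can swap phase at
// zero local cost; only distant mate pairs reveal the error).

struct TailPerm {
  std::vector<int> perm;   // perm[l] = row whose tail moves to slot l
  std::vector<int> moved;  // slots with perm[l] != l
};                         // perm need not be a bijection: a tail may be
                           // copied over another (dosage repair)

static void add_perm(std::vector<TailPerm>& out, const std::vector<int>& p) {
  TailPerm tp;
  tp.perm = p;
  for (int l = 0; l < (int)p.size(); ++l)
    if (p[l] != l) tp.moved.push_back(l);
  if (!tp.moved.empty()) out.push_back(tp);
}

static std::vector<TailPerm> small_perms(int K) {
  std::vector<TailPerm> out;
  std::vector<int> id(K);
  for (int l = 0; l < K; ++l) id[l] = l;
  // transpositions
  for (int a = 0; a < K; ++a)
    for (int b = a + 1; b < K; ++b) {
      std::vector<int> p = id; std::swap(p[a], p[b]);
      add_perm(out, p);
    }
  // 3-cycles (both orientations)
  for (int a = 0; a < K; ++a)
    for (int b = a + 1; b < K; ++b)
      for (int c = b + 1; c < K; ++c) {
        std::vector<int> p = id;
        p[a] = b; p[b] = c; p[c] = a; add_perm(out, p);
        p = id;
        p[a] = c; p[c] = b; p[b] = a; add_perm(out, p);
      }
  // double transpositions
  for (int a = 0; a < K; ++a)
    for (int b = a + 1; b < K; ++b)
      for (int c = a + 1; c < K; ++c)
        for (int d = c + 1; d < K; ++d) {
          if (c == b || d == b) continue;
          std::vector<int> p = id;
          std::swap(p[a], p[b]); std::swap(p[c], p[d]);
          add_perm(out, p);
        }
  // tail copies: slot a takes a duplicate of tail b (non-bijective)
  for (int a = 0; a < K; ++a)
    for (int b = 0; b < K; ++b) {
      if (a == b) continue;
      std::vector<int> p = id;
      p[a] = b;
      add_perm(out, p);
    }
  return out;
}

// [[Rcpp::export]]
List cpp_switch_refine(IntegerVector read_ptr, IntegerVector call_snp,
                       IntegerVector call_allele, IntegerMatrix hap0,
                       int max_sweeps) {
  IntegerMatrix hap = clone(hap0);
  int m = read_ptr.size() - 1, K = hap.nrow(), n = hap.ncol();
  int ncalls = call_snp.size();
  if (n < 2 || m == 0 || K < 2)
    return List::create(_["hap"] = hap,
                        _["mec"] = cpp_mec(read_ptr, call_snp, call_allele, hap),
                        _["sweeps"] = 0, _["changes"] = 0);

  // per-site call lists and per-read spans
  std::vector<int> col_ptr(n + 1, 0), col_read(ncalls), col_allele(ncalls);
  for (int p = 0; p < ncalls; ++p) col_ptr[call_snp[p] + 1]++;
  for (int j = 0; j < n; ++j) col_ptr[j + 1] += col_ptr[j];
  {
    std::vector<int> pos(col_ptr.begin(), col_ptr.end() - 1);
    for (int i = 0; i < m; ++i)
      for (int p = read_ptr[i]; p < read_ptr[i + 1]; ++p) {
        int j = call_snp[p];
        col_read[pos[j]] = i;
        col_allele[pos[j]++] = call_allele[p];
      }
  }
  std::vector<int> first(m, n), last(m, -1);
  for (int i = 0; i < m; ++i) {
    if (read_ptr[i] < read_ptr[i + 1]) {
      first[i] = call_snp[read_ptr[i]];
      last[i] = call_snp[read_ptr[i + 1] - 1];
    }
  }
  std::vector<int> by_first(m);
  for (int i = 0; i < m; ++i) by_first[i] = i;
  std::sort(by_first.begin(), by_first.end(),
            [&](int x, int y) { return first[x] < first[y]; });

  std::vector<TailPerm> perms = small_perms(K);
  int npm = perms.size();

  std::vector<int> hdL((size_t)m * K, 0), hdR((size_t)m * K);
  std::vector<double> delta(npm);
  std::vector<int> tmp(K);
  int changes = 0, sweep = 0;
  for (; sweep < max_sweeps; ++sweep) {
    bool any = false;
    hamming_table(read_ptr, call_snp, call_allele, hap, hdR);
    std::fill(hdL.begin(), hdL.end(), 0);
    std::vector<int> active;
    size_t next_first = 0;
    for (int j = 0; j + 1 < n; ++j) {
      for (int p = col_ptr[j]; p < col_ptr[j + 1]; ++p) {
        int i = col_read[p], obs = col_allele[p];
        for (int l = 0; l < K; ++l) {
          int d = (hap(l, j) != obs) ? 1 : 0;
          hdL[(size_t)i * K + l] += d;
          hdR[(size_t)i * K + l] -= d;
        }
      }
      while (next_first < by_first.size() && first[by_first[next_first]] <= j)
        active.push_back(by_first[next_first++]);
      {
        size_t w = 0;
        for (size_t q = 0; q < active.size(); ++q)
          if (last[active[q]] > j) active[w++] = active[q];
        active.resize(w);
      }
      if (active.empty()) continue;
      bool retry = true;
      while (retry) {
        retry = false;
        std::fill(delta.begin(), delta.end(), 0.0);
        for (int i_ : active) {
          const int* L = &hdL[(size_t)i_ * K];
          const int* R = &hdR[(size_t)i_ * K];
          // five smallest identity scores, to exclude up to 4 moved rows
          int v[5] = {INT_MAX, INT_MAX, INT_MAX, INT_MAX, INT_MAX};
          int ai[5] = {-1, -1, -1, -1, -1};
          for (int l = 0; l < K; ++l) {
            int f = L[l] + R[l];
            for (int q = 0; q < 5; ++q) {
              if (f < v[q]) {
                for (int z = 4; z > q; --z) { v[z] = v[z-1]; ai[z] = ai[z-1]; }
                v[q] = f; ai[q] = l;
                break;
              }
            }
          }
          for (int pm = 0; pm < npm; ++pm) {
            const TailPerm& tp = perms[pm];
            int nm = INT_MAX;
            // best unmoved row
            for (int q = 0; q < 5; ++q) {
              if (ai[q] < 0) break;
              bool moved = false;
              for (int l : tp.moved) if (l == ai[q]) { moved = true; break; }
              if (!moved) { nm = v[q]; break; }
            }
            for (int l : tp.moved) {
              int f = L[l] + R[tp.perm[l]];
              if (f < nm) nm = f;
            }
            delta[pm] += nm - v[0];
          }
        }
        int bestp = -1;
        double bestd = 0.0;
        for (int pm = 0; pm < npm; ++pm)
          if (delta[pm] < bestd) { bestd = delta[pm]; bestp = pm; }
        if (bestp >= 0) {
          const TailPerm& tp = perms[bestp];
          for (int jj = j + 1; jj < n; ++jj) {
            for (int l = 0; l < K; ++l) tmp[l] = hap(tp.perm[l], jj);
            for (int l = 0; l < K; ++l) hap(l, jj) = tmp[l];
          }
          for (int i = 0; i < m; ++i) {
            int* R = &hdR[(size_t)i * K];
            for (int l = 0; l < K; ++l) tmp[l] = R[tp.perm[l]];
            for (int l = 0; l < K; ++l) R[l] = tmp[l];
          }
          ++changes;
          any = true;
          retry = true;   // compositions may improve further at this boundary
        }
      }
    }
    if (!any) break;
  }
  return List::create(_["hap"] = hap,
                      _["mec"] = cpp_mec(read_ptr, call_snp, call_allele, hap),
                      _["sweeps"] = std::min(sweep + 1, max_sweeps),
                      _["changes"] = changes);
}
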