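#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Compressed adjacency over an undirected edge list (1-based i/j from R).
// Every undirected edge appears twice; eid maps each directed entry back to
// its undirected edge index so per-edge state (weights, multipliers) is shared.
struct Adj {
  std::vector<int> ptr;   // m + 1
  std::vector<int> nbr;   // 2 * n_edges, 0-based neighbour
  std::vector<int> eid;   // 2 * n_edges
};

static Adj build_adj(int m, const IntegerVector& ei, const IntegerVector& ej) {
  int ne = ei.size();
  Adj a;
  a.ptr.assign(m + 1, 0);
  for (int e = 0; e < ne; ++e) {  // ei/ej are 1-based
    a.ptr[ei[e]]++;
    a.ptr[ej[e]]++;
  }
  for (int v = 0; v < m; ++v) a.ptr[v + 1] += a.ptr[v];
  a.nbr.assign(2 * (size_t)ne, 0);
  a.eid.assign(2 * (size_t)ne, 0);
  std::vector<int> pos(m);
  for (int v = 0; v < m; ++v) pos[v] = a.ptr[v];
  for (int e = 0; e < ne; ++e) {
    int u = ei[e] - 1, v = ej[e] - 1;
    a.nbr[pos[u]] = v; a.eid[pos[u]++] = e;
    a.nbr[pos[v]] = u; a.eid[pos[v]++] = e;
  }
  return a;
}

// Row-major copy of V for cache-friendly row updates.
static std::vector<double> to_rowmajor(const NumericMatrix& V) {
  int m = V.nrow(), r = V.ncol();
  std::vector<double> out((size_t)m * r);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < r; ++k) out[(size_t)i * r + k] = V(i, k);
  return out;
}

static NumericMatrix from_rowmajor(const std::vector<double>& v, int m, int r) {
  NumericMatrix V(m, r);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < r; ++k) V(i, k) = v[(size_t)i * r + k];
  return V;
}

// One Gauss-Seidel sweep of V_i <- sum_k w_ik V_k, row-normalized.
// eff_dir[p] is the effective weight of adjacency entry p (w, or w + |lambda|),
// laid out in adjacency order so the sweep streams memory sequentially.
// Returns the squared norm of the stacked Riemannian (tangent) gradient,
// evaluated at the pre-update row.
template <int R>
static double sweep_once_t(std::vector<double>& V, int m,
                           const Adj& a, const std::vector<double>& eff_dir) {
  double s[R];
  double gnorm2 = 0.0;
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < R; ++k) s[k] = 0.0;
    for (int p = a.ptr[i]; p < a.ptr[i + 1]; ++p) {
      double w = eff_dir[p];
      if (w == 0.0) continue;
      const double* Vj = &V[(size_t)a.nbr[p] * R];
      for (int k = 0; k < R; ++k) s[k] += w * Vj[k];
    }
    double* Vi = &V[(size_t)i * R];
    double dot = 0.0, ns2 = 0.0;
    for (int k = 0; k < R; ++k) { dot += Vi[k] * s[k]; ns2 += s[k] * s[k]; }
    for (int k = 0; k < R; ++k) {
      double g = s[k] - dot * Vi[k];
      gnorm2 += g * g;
    }
    if (ns2 > 0.0) {
      double inv = 1.0 / std::sqrt(ns2);
      for (int k = 0; k < R; ++k) Vi[k] = s[k] * inv;
    } // s == 0: keep the previous (unit-norm) row
  }
  return gnorm2;
}

static double sweep_once(std::vector<double>& V, int m, int r,
                         const Adj& a, const std::vector<double>& eff_dir) {
  switch (r) {
  case 2: return sweep_once_t<2>(V, m, a, eff_dir);
  case 3: return sweep_once_t<3>(V, m, a, eff_dir);
  case 4: return sweep_once_t<4>(V, m, a, eff_dir);
  case 5: return sweep_once_t<5>(V, m, a, eff_dir);
  case 6: return sweep_once_t<6>(V, m, a, eff_dir);
  case 7: return sweep_once_t<7>(V, m, a, eff_dir);
  case 8: return sweep_once_t<8>(V, m, a, eff_dir);
  case 9: return sweep_once_t<9>(V, m, a, eff_dir);
  case 10: return sweep_once_t<10>(V, m, a, eff_dir);
  case 11: return sweep_once_t<11>(V, m, a, eff_dir);
  case 12: return sweep_once_t<12>(V, m, a, eff_dir);
  }
  // generic fallback for larger rank budgets
  std::vector<double> s(r);
  double gnorm2 = 0.0;
  for (int i = 0; i < m; ++i) {
    std::fill(s.begin(), s.end(), 0.0);
    for (int p = a.ptr[i]; p < a.ptr[i + 1]; ++p) {
      double w = eff_dir[p];
      if (w == 0.0) continue;
      const double* Vj = &V[(size_t)a.nbr[p] * r];
      for (int k = 0; k < r; ++k) s[k] += w * Vj[k];
    }
    double* Vi = &V[(size_t)i * r];
    double dot = 0.0, ns2 = 0.0;
    for (int k = 0; k < r; ++k) { dot += Vi[k] * s[k]; ns2 += s[k] * s[k]; }
    for (int k = 0; k < r; ++k) {
      double g = s[k] - dot * Vi[k];
      gnorm2 += g * g;
    }
    if (ns2 > 0.0) {
      double inv = 1.0 / std::sqrt(ns2);
      for (int k = 0; k < r; ++k) Vi[k] = s[k] * inv;
    }
  }
  return gnorm2;
}

// Sweep with effective weights w[e] - lam[e] read through the edge-id map
// (single pass; no materialized per-entry weight array).
template <int R>
static void sweep_once_lam_t(std::vector<double>& V, int m, const Adj& a,
                             const double* ew, const double* lam) {
  double s[R];
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < R; ++k) s[k] = 0.0;
    for (int p = a.ptr[i]; p < a.ptr[i + 1]; ++p) {
      int e = a.eid[p];
      double w = ew[e] - lam[e];
      if (w == 0.0) continue;
      const double* Vj = &V[(size_t)a.nbr[p] * R];
      for (int k = 0; k < R; ++k) s[k] += w * Vj[k];
    }
    double* Vi = &V[(size_t)i * R];
    double ns2 = 0.0;
    for (int k = 0; k < R; ++k) ns2 += s[k] * s[k];
    if (ns2 > 0.0) {
      double inv = 1.0 / std::sqrt(ns2);
      for (int k = 0; k < R; ++k) Vi[k] = s[k] * inv;
    }
  }
}

static void sweep_once_lam(std::vector<double>& V, int m, int r, const Adj& a,
                           const double* ew, const double* lam) {
  switch (r) {
  case 2: return sweep_once_lam_t<2>(V, m, a, ew, lam);
  case 3: return sweep_once_lam_t<3>(V, m, a, ew, lam);
  case 4: return sweep_once_lam_t<4>(V, m, a, ew, lam);
  case 5: return sweep_once_lam_t<5>(V, m, a, ew, lam);
  case 6: return sweep_once_lam_t<6>(V, m, a, ew, lam);
  case 7: return sweep_once_lam_t<7>(V, m, a, ew, lam);
  case 8: return sweep_once_lam_t<8>(V, m, a, ew, lam);
  case 9: return sweep_once_lam_t<9>(V, m, a, ew, lam);
  case 10: return sweep_once_lam_t<10>(V, m, a, ew, lam);
  default: break;
  }
  std::vector<double> s(r);
  for (int i = 0; i < m; ++i) {
    std::fill(s.begin(), s.end(), 0.0);
    for (int p = a.ptr[i]; p < a.ptr[i + 1]; ++p) {
      int e = a.eid[p];
      double w = ew[e] - lam[e];
      if (w == 0.0) continue;
      const double* Vj = &V[(size_t)a.nbr[p] * r];
      for (int k = 0; k < r; ++k) s[k] += w * Vj[k];
    }
    double* Vi = &V[(size_t)i * r];
    double ns2 = 0.0;
    for (int k = 0; k < r; ++k) ns2 += s[k] * s[k];
    if (ns2 > 0.0) {
      double inv = 1.0 / std::sqrt(ns2);
      for (int k = 0; k < r; ++k) Vi[k] = s[k] * inv;
    }
  }
}

// Fused outer pass: edge inner products, primal and Lagrangian values,
// minimum slack, and the in-place multiplier update, in one sweep over the
// undirected edge list.
template <int R>
static void outer_pass_t(const std::vector<double>& V,
                         const IntegerVector& ei, const IntegerVector& ej,
                         const double* ew, double* lam,
                         double bound, double alpha, double eps_g, double mu,
                         double& M, double& L, double& slack) {
  int ne = ei.size();
  M = 0.0; L = 0.0; slack = 1e300;
  for (int e = 0; e < ne; ++e) {
    const double* a = &V[(size_t)(ei[e] - 1) * R];
    const double* b = &V[(size_t)(ej[e] - 1) * R];
    double d = 0.0;
    for (int k = 0; k < R; ++k) d += a[k] * b[k];
    M += ew[e] * d;
    double s = d - bound;
    L -= lam[e] * s;
    if (s < slack) slack = s;
    if (lam[e] < -eps_g) {
      lam[e] = lam[e] * std::exp2(-mu * s);
    } else {
      lam[e] = std::min(lam[e] + alpha * s, 0.0);
    }
    if (lam[e] > 0.0) lam[e] = 0.0;
  }
  L += M;
}

static void outer_pass(int r, const std::vector<double>& V,
                       const IntegerVector& ei, const IntegerVector& ej,
                       const double* ew, double* lam,
                       double bound, double alpha, double eps_g, double mu,
                       double& M, double& L, double& slack) {
  switch (r) {
  case 2: return outer_pass_t<2>(V, ei, ej, ew, lam, bound, alpha, eps_g, mu, M, L, slack);
  case 3: return outer_pass_t<3>(V, ei, ej, ew, lam, bound, alpha, eps_g, mu, M, L, slack);
  case 4: return outer_pass_t<4>(V, ei, ej, ew, lam, bound, alpha, eps_g, mu, M, L, slack);
  case 5: return outer_pass_t<5>(V, ei, ej, ew, lam, bound, alpha, eps_g, mu, M, L, slack);
  case 6: return outer_pass_t<6>(V, ei, ej, ew, lam, bound, alpha, eps_g, mu, M, L, slack);
  case 7: return outer_pass_t<7>(V, ei, ej, ew, lam, bound, alpha, eps_g, mu, M, L, slack);
  case 8: return outer_pass_t<8>(V, ei, ej, ew, lam, bound, alpha, eps_g, mu, M, L, slack);
  case 9: return outer_pass_t<9>(V, ei, ej, ew, lam, bound, alpha, eps_g, mu, M, L, slack);
  case 10: return outer_pass_t<10>(V, ei, ej, ew, lam, bound, alpha, eps_g, mu, M, L, slack);
  }
  int ne = ei.size();
  M = 0.0; L = 0.0; slack = 1e300;
  for (int e = 0; e < ne; ++e) {
    const double* a = &V[(size_t)(ei[e] - 1) * r];
    const double* b = &V[(size_t)(ej[e] - 1) * r];
    double d = 0.0;
    for (int k = 0; k < r; ++k) d += a[k] * b[k];
    M += ew[e] * d;
    double s = d - bound;
    L -= lam[e] * s;
    if (s < slack) slack = s;
    if (lam[e] < -eps_g) {
      lam[e] = lam[e] * std::exp2(-mu * s);
    } else {
      lam[e] = std::min(lam[e] + alpha * s, 0.0);
    }
    if (lam[e] > 0.0) lam[e] = 0.0;
  }
  L += M;
}

// Inner products V_i . V_j over undirected edges.
template <int R>
static void edge_dots_t(const std::vector<double>& V,
                        const IntegerVector& ei, const IntegerVector& ej,
                        std::vector<double>& dots) {
  int ne = ei.size();
  for (int e = 0; e < ne; ++e) {
    const double* a = &V[(size_t)(ei[e] - 1) * R];
    const double* b = &V[(size_t)(ej[e] - 1) * R];
    double d = 0.0;
    for (int k = 0; k < R; ++k) d += a[k] * b[k];
    dots[e] = d;
  }
}

static void edge_dots(const std::vector<double>& V, int r,
                      const IntegerVector& ei, const IntegerVector& ej,
                      std::vector<double>& dots) {
  switch (r) {
  case 2: return edge_dots_t<2>(V, ei, ej, dots);
  case 3: return edge_dots_t<3>(V, ei, ej, dots);
  case 4: return edge_dots_t<4>(V, ei, ej, dots);
  case 5: return edge_dots_t<5>(V, ei, ej, dots);
  case 6: return edge_dots_t<6>(V, ei, ej, dots);
  case 7: return edge_dots_t<7>(V, ei, ej, dots);
  case 8: return edge_dots_t<8>(V, ei, ej, dots);
  }
  int ne = ei.size();
  for (int e = 0; e < ne; ++e) {
    const double* a = &V[(size_t)(ei[e] - 1) * r];
    const double* b = &V[(size_t)(ej[e] - 1) * r];
    double d = 0.0;
    for (int k = 0; k < r; ++k) d += a[k] * b[k];
    dots[e] = d;
  }
}

// [[Rcpp::export]]
List cpp_lowrank_ascent(int m, IntegerVector ei, IntegerVector ej, NumericVector ew,
                        NumericMatrix V0, double eps_tol, int max_sweeps) {
  int r = V0.ncol();
  int ne = ei.size();
  std::vector<double> V = to_rowmajor(V0);
  Adj a = build_adj(m, ei, ej);
  std::vector<double> eff_dir(2 * (size_t)ne);
  for (size_t p = 0; p < eff_dir.size(); ++p) eff_dir[p] = ew[a.eid[p]];
  std::vector<double> dots(ne);
  std::vector<double> Mtrace;
  double grad_ratio = NA_REAL;
  bool converged = false;
  int sweep = 0;
  for (; sweep < max_sweeps; ++sweep) {
    double g2 = sweep_once(V, m, r, a, eff_dir);
    edge_dots(V, r, ei, ej, dots);
    double M = 0.0;
    for (int e = 0; e < ne; ++e) M += ew[e] * dots[e];
    Mtrace.push_back(M);
    grad_ratio = std::sqrt(g2) / std::max(std::fabs(M), 1e-12);
    if (grad_ratio < eps_tol) { converged = true; ++sweep; break; }
  }
  return List::create(_["V"] = from_rowmajor(V, m, r),
                      _["M_trace"] = wrap(Mtrace),
                      _["grad_ratio"] = grad_ratio,
                      _["sweeps"] = sweep,
                      _["converged"] = converged);
}

// Correlation-clustering objective of a labeling: intra-cluster edge weight
// minus inter-cluster edge weight (equals the MAX-CUT value sum w x_i x_j
// for two clusters).
// [[Rcpp::export]]
double cpp_cluster_objective(IntegerVector ei, IntegerVector ej,
                             NumericVector ew, IntegerVector labels) {
  int ne = ei.size();
  double obj = 0.0;
  for (int e = 0; e < ne; ++e) {
    bool same = labels[ei[e] - 1] == labels[ej[e] - 1];
    obj += same ? ew[e] : -ew[e];
  }
  return obj;
}

// Lagrangian minorize-maximize for the K-cluster constrained program:
// inner cyclic sweeps with effective weights w + lambda, outer subgradient
// updates of the non-positive multipliers on V_i.V_j >= -1/(K-1).
// Multiplier rule: additive clipped step; if lambda is already below the
// guard interval -eps_g, the exponential damping rule applies instead.
// [[Rcpp::export]]
List cpp_lagrangian_ascent(int m, IntegerVector ei, IntegerVector ej, NumericVector ew,
                           NumericMatrix V0, NumericVector lambda0, int K,
                           double alpha, double eps_g, double mu,
                           double eps_tol, int window, int max_outer) {
  int r = V0.ncol();
  int ne = ei.size();
  double bound = -1.0 / (double)(K - 1);
  std::vector<double> V = to_rowmajor(V0);
  Adj a = build_adj(m, ei, ej);
  std::vector<double> lam(lambda0.begin(), lambda0.end());
  std::vector<double> Mtrace, Ltrace;
  bool converged = false;
  int iter = 0;
  double min_slack = NA_REAL;
  const double* ewp = &ew[0];
  for (; iter < max_outer; ++iter) {
    // lam <= 0 encodes the multiplier -lam >= 0 of V_i.V_j >= -1/(K-1);
    // a violated edge must become MORE attractive, hence w - lam = w + |lam|
    sweep_once_lam(V, m, r, a, ewp, lam.data());
    double M, L, slack;
    outer_pass(r, V, ei, ej, ewp, lam.data(), bound, alpha, eps_g, mu,
               M, L, slack);
    min_slack = slack;
    Mtrace.push_back(M);
    Ltrace.push_back(L);
    // smoothed convergence on the Lagrangian value
    int t = (int)Ltrace.size();
    if (t >= 2 * window) {
      double m1 = 0.0, m2 = 0.0;
      for (int q = t - window; q < t; ++q) m1 += Ltrace[q];
      for (int q = t - 2 * window; q < t - window; ++q) m2 += Ltrace[q];
      m1 /= window; m2 /= window;
      if (std::fabs(m1 - m2) / (std::fabs(m1) + 1.0) < eps_tol) {
        converged = true; ++iter; break;
      }
    }
  }
  return List::create(_["V"] = from_rowmajor(V, m, r),
                      _["lambda"] = wrap(lam),
                      _["M_trace"] = wrap(Mtrace),
                      _["L_trace"] = wrap(Ltrace),
                      _["min_slack"] = min_slack,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}

// Greedy single-vertex label improvement of the clustering objective:
// repeatedly move a read to the cluster maximizing its adjacent
// intra-cluster weight (strict improvement only), until a full pass makes
// no move or max_passes is reached. Hill-climbs exactly the objective the
// randomized rounding maximizes.
// [[Rcpp::export]]
List cpp_label_local_search(int m, IntegerVector ei, IntegerVector ej,
                            NumericVector ew, IntegerVector labels0, int K,
                            int max_passes) {
  Adj a = build_adj(m, ei, ej);
  std::vector<double> w_dir(2 * (size_t)ei.size());
  for (size_t p = 0; p < w_dir.size(); ++p) w_dir[p] = ew[a.eid[p]];
  std::vector<int> lab(labels0.begin(), labels0.end());
  std::vector<double> acc(K);
  long moves = 0;
  int pass = 0;
  for (; pass < max_passes; ++pass) {
    bool any = false;
    for (int i = 0; i < m; ++i) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int p = a.ptr[i]; p < a.ptr[i + 1]; ++p)
        acc[lab[a.nbr[p]]] += w_dir[p];
      int best = lab[i];
      double bestv = acc[best];
      for (int c = 0; c < K; ++c)
        if (acc[c] > bestv) { bestv = acc[c]; best = c; }
      if (best != lab[i]) { lab[i] = best; ++moves; any = true; }
    }
    if (!any) break;
  }
  return List::create(_["labels"] = wrap(lab), _["moves"] = (double)moves,
                      _["passes"] = pass);
}
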