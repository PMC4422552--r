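#include <Rcpp.h>
using namespace Rcpp;

// Merge the sparse overlap-count matrix (total) with the agreement-count
// matrix (sim): both are column-compressed upper triangles with sorted row
// indices (dsCMatrix slots); sim's pattern is a subset of total's. Returns
// the strict upper-triangle edge list with total and agreeing counts.
// [[Rcpp::export]]
List cpp_edge_counts(IntegerVector Tp, IntegerVector Ti, NumericVector Tx,
                     IntegerVector Sp, IntegerVector Si, NumericVector Sx,
                     int m) {
  // count strict upper entries first
  R_xlen_t ne = 0;
  for (int col = 0; col < m; ++col)
    for (int p = Tp[col]; p < Tp[col + 1]; ++p)
      if (Ti[p] < col) ++ne;
  IntegerVector ei(ne), ej(ne), kt(ne), ks(ne);
  R_xlen_t out = 0;
  for (int col = 0; col < m; ++col) {
    int sp = Sp[col], se = Sp[col + 1];
    for (int p = Tp[col]; p < Tp[col + 1]; ++p) {
      int row = Ti[p];
      if (row >= col) continue;
      while (sp < se && Si[sp] < row) ++sp;
      double s = (sp < se && Si[sp] == row) ? Sx[sp] : 0.0;
      ei[out] = row + 1;
      ej[out] = col + 1;
      kt[out] = (int)Tx[p];
      ks[out] = (int)s;
      ++out;
    }
  }
  return List::create(_["i"] = ei, _["j"] = ej,
                      _["k_total"] = kt, _["k_sim"] = ks);
}
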