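#include <Rcpp.h>
using namespace Rcpp;

// Fast assembly of the sparse posterior precision P = C' W C + B for the
// Gibbs location update. All index mappings are precomputed once in R
// (0-based): B entries map into P@x via bmap; each within-row pair of
// nonzeros of C contributes w[row] * Cv[a] * Cv[b] to one entry of P@x.

// [[Rcpp::export(assemble_precision_cpp)]]
NumericVector assemble_precision_cpp(int np, IntegerVector bmap,
                                     NumericVector Bx, IntegerVector pa,
                                     IntegerVector pb, IntegerVector prow,
                                     IntegerVector ptar, NumericVector Cv,
                                     NumericVector w) {
  NumericVector Px(np);
  int nb = bmap.size();
  for (int k = 0; k < nb; ++k) Px[bmap[k]] += Bx[k];
  int m = pa.size();
  const double *cv = Cv.begin(), *wp = w.begin();
  const int *a = pa.begin(), *b = pb.begin(), *r = prow.begin(),
            *t = ptar.begin();
  double *px = Px.begin();
  for (int k = 0; k < m; ++k) px[t[k]] += wp[r[k]] * cv[a[k]] * cv[b[k]];
  return Px;
}
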