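#include <Rcpp.h>
using namespace Rcpp;

// Exact inbreeding coefficients by the Meuwissen & Luo (1992) algorithm.
// Individuals must be in topological order (parents before offspring);
// sire/dam are 1-based indices, 0 = unknown. Also returns the Mendelian
// sampling variance scalars d_i used to assemble the A-inverse:
//   both parents known:  d_i = 0.5 - 0.25 (f_s + f_d)
//   one parent known:    d_i = 0.75 - 0.25 f_known
//   founder:             d_i = 1
// These are the diagonal of D in A = L D L'.

// [[Rcpp::export(inbreeding_cpp)]]
List inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n), D(n);
  std::vector<double> L(n, 0.0);

  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i) stop("pedigree not in topological order");
    double fs = (s >= 0) ? F[s] : 0.0;
    double fd = (d >= 0) ? F[d] : 0.0;
    if (s >= 0 && d >= 0)
      D[i] = 0.5 - 0.25 * (fs + fd);
    else if (s >= 0)
      D[i] = 0.75 - 0.25 * fs;
    else if (d >= 0)
      D[i] = 0.75 - 0.25 * fd;
    else
      D[i] = 1.0;

    if (s < 0 || d < 0) {
      F[i] = 0.0; // at least one phantom founder parent
      continue;
    }
    // A_ii = sum_j L_ij^2 D_j over the ancestor closure of i
    double Aii = 0.0;
    L[i] = 1.0;
    for (int j = i; j >= 0; --j) {
      if (L[j] == 0.0) continue;
      double lj = L[j];
      L[j] = 0.0;
      int sj = sire[j] - 1, dj = dam[j] - 1;
      if (sj >= 0) L[sj] += 0.5 * lj;
      if (dj >= 0) L[dj] += 0.5 * lj;
      Aii += lj * lj * D[j];
    }
    F[i] = Aii - 1.0;
  }
  return List::create(Named("f") = F, Named("d") = D);
}
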