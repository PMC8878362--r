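#include <Rcpp.h>
using namespace Rcpp;

// Causal IIR difference equation in direct form II transposed.
// b, a are the numerator/denominator coefficients with a[0] == 1 (already
// normalised); zi is the carried delay-line state of length
// max(length(b), length(a)) - 1. Returns the filtered block and the final
// state so that block-wise streaming is bit-identical to one batch call.
// [[Rcpp::export(name = ".iir_df2t")]]
List iir_df2t(NumericVector b, NumericVector a, NumericVector x,
              NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  if (zi.size() != nz) stop("state length must be %d", nz);
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector z = clone(zi);
  int n = x.size();
  NumericVector y(n);
  for (int k = 0; k < n; ++k) {
    double xk = x[k];
    double yk = bb[0] * xk + z[0];
    for (int i = 0; i < nz - 1; ++i)
      z[i] = bb[i + 1] * xk + z[i + 1] - aa[i + 1] * yk;
    if (nz > 0) z[nz - 1] = bb[nz] * xk - aa[nz] * yk;
    y[k] = yk;
  }
  return List::create(_["y"] = y, _["state"] = z);
}
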