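#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-site direct distribution and its mutual information, for all listed
// column pairs.
//
// invC: (q-1)N square matrix, block (i,a),(j,b) = -e_ij(a,b); the gap is
//       the reference state q with zero couplings and fields.
// fi:   q x N single-site frequencies (pseudocounted, strictly positive).
// pi, pj: 1-based local column indices of the pairs.
//
// For each pair, iterate auxiliary fields h_i, h_j (kept as positive
// multipliers mu1, mu2) so that the marginals of
//   P(a,b) = W(a,b) mu1(a) mu2(b) / Z,  W(a,b) = exp(e_ij(a,b))
// match f_i and f_j; damped fixed point, convergence measured as the
// maximum absolute marginal mismatch.
// [[Rcpp::export]]
List di_pairs_cpp(NumericMatrix invC, NumericMatrix fi,
                  IntegerVector pi, IntegerVector pj, int q,
                  double tol, int max_iter, double damp) {
  const int r = q - 1;
  const int npair = pi.size();
  NumericVector di(npair);
  LogicalVector converged(npair);
  std::vector<double> W(q * q), mu1(q), mu2(q), new1(q), new2(q),
      P(q * q), m1(q), m2(q);

  for (int k = 0; k < npair; ++k) {
    const int i = pi[k] - 1, j = pj[k] - 1;
    // W(a,b) = exp(e_ij(a,b)); gap row/column have e = 0
    for (int a = 0; a < q; ++a)
      for (int b = 0; b < q; ++b) {
        double e = 0.0;
        if (a < r && b < r) e = -invC(i * r + a, j * r + b);
        W[a * q + b] = std::exp(e);
      }
    // deterministic initialisation from the marginals
    for (int a = 0; a < q; ++a) { mu1[a] = fi(a, i); mu2[a] = fi(a, j); }

    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      // update mu1 given mu2, then mu2 given mu1
      double s1 = 0.0;
      for (int a = 0; a < q; ++a) {
        double scra = 0.0;
        for (int b = 0; b < q; ++b) scra += W[a * q + b] * mu2[b];
        new1[a] = fi(a, i) / scra;
        s1 += new1[a];
      }
      for (int a = 0; a < q; ++a)
        mu1[a] = damp * mu1[a] + (1.0 - damp) * new1[a] / s1;
      double s2 = 0.0;
      for (int b = 0; b < q; ++b) {
        double scra = 0.0;
        for (int a = 0; a < q; ++a) scra += W[a * q + b] * mu1[a];
        new2[b] = fi(b, j) / scra;
        s2 += new2[b];
      }
      for (int b = 0; b < q; ++b)
        mu2[b] = damp * mu2[b] + (1.0 - damp) * new2[b] / s2;

      // current two-site distribution and its marginal mismatch
      double Z = 0.0;
      for (int a = 0; a < q; ++a)
        for (int b = 0; b < q; ++b) {
          P[a * q + b] = W[a * q + b] * mu1[a] * mu2[b];
          Z += P[a * q + b];
        }
      std::fill(m1.begin(), m1.end(), 0.0);
      std::fill(m2.begin(), m2.end(), 0.0);
      double eps = 0.0;
      for (int a = 0; a < q; ++a)
        for (int b = 0; b < q; ++b) {
          const double p = P[a * q + b] / Z;
          P[a * q + b] = p;
          m1[a] += p; m2[b] += p;
        }
      for (int a = 0; a < q; ++a) {
        eps = std::max(eps, std::fabs(m1[a] - fi(a, i)));
        eps = std::max(eps, std::fabs(m2[a] - fi(a, j)));
      }
      if (eps < tol) { ok = true; break; }
    }
    converged[k] = ok;
    if (ok) {
      double s = 0.0;
      for (int a = 0; a < q; ++a)
        for (int b = 0; b < q; ++b) {
          const double p = P[a * q + b];
          if (p > 0.0) s += p * std::log(p / (fi(a, i) * fi(b, j)));
        }
      di[k] = s;
    } else {
      di[k] = NA_REAL;
    }
  }
  return List::create(_["di"] = di, _["converged"] = converged);
}
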