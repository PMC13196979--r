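#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Clamped log(1 - x): probabilities of exactly 1 would give -Inf products;
// clamping at 1 - 1e-12 keeps the log-space accumulators finite.
static inline double log1m(double x) {
  if (x > 1.0 - 1e-12) x = 1.0 - 1e-12;
  return std::log1p(-x);
}

// Core ND property sweep over a sparse ensemble table.
//
// Pt is the transposed probability matrix (n_p x N) in compressed
// column-major form: column g holds genotype g's stored ensemble entries.
// nbr is the N x d matrix of 0-based neighbour indices.
//
// Returns, per genotype: robustness rho_g, evolvability eps_g and the top
// ensemble probability; per phenotype: the shared double sum
// sum_g P(p|g) sum_{g' in N(g)} P(p|g') (numerator of both robustness
// flavours); and, when want_A, the log-space accumulator
// A[p, p2] = sum_g sum_{g' in N(g)} log(1 - P(p|g) P(p2|g'))
// from which phenotypic evolvability follows.
// [[Rcpp::export]]
List nd_props_kernel(IntegerVector Pt_p, IntegerVector Pt_i,
                     NumericVector Pt_x, int n_p,
                     IntegerMatrix nbr, bool want_A) {
  const int N = nbr.nrow();
  const int d = nbr.ncol();
  NumericVector rho_g(N), eps_g(N), top_prob(N), rr_num(n_p);
  NumericMatrix A(want_A ? n_p : 1, want_A ? n_p : 1);

  std::vector<double> s(n_p, 0.0), la(n_p, 0.0), q(n_p, 1.0);
  std::vector<int> touched;
  touched.reserve(n_p);
  std::vector<char> seen(n_p, 0);

  for (int g = 0; g < N; ++g) {
    // neighbour sums and log-products over the mutational neighbourhood
    for (int t = 0; t < d; ++t) {
      int gp = nbr(g, t);
      for (int k = Pt_p[gp]; k < Pt_p[gp + 1]; ++k) {
        int p2 = Pt_i[k];
        double v2 = Pt_x[k];
        if (!seen[p2]) { seen[p2] = 1; touched.push_back(p2); }
        s[p2] += v2;
        la[p2] += log1m(v2);
      }
    }
    double sum1mQ = 0.0;
    for (size_t u = 0; u < touched.size(); ++u) {
      int p2 = touched[u];
      q[p2] = std::exp(la[p2]);
      sum1mQ += 1.0 - q[p2];
    }
    double rg = 0.0, eg = 0.0, tp = 0.0;
    for (int k = Pt_p[g]; k < Pt_p[g + 1]; ++k) {
      int p = Pt_i[k];
      double v = Pt_x[k];
      double qp = seen[p] ? q[p] : 1.0;
      rg += v * s[p];
      rr_num[p] += v * s[p];
      eg += v * (sum1mQ - (1.0 - qp));
      if (v > tp) tp = v;
      if (want_A) {
        for (int t = 0; t < d; ++t) {
          int gp = nbr(g, t);
          for (int k2 = Pt_p[gp]; k2 < Pt_p[gp + 1]; ++k2) {
            A(p, Pt_i[k2]) += log1m(v * Pt_x[k2]);
          }
        }
      }
    }
    rho_g[g] = rg / d;
    eps_g[g] = eg;
    top_prob[g] = tp;
    // reset temporaries
    for (size_t u = 0; u < touched.size(); ++u) {
      int p2 = touched[u];
      s[p2] = 0.0; la[p2] = 0.0; q[p2] = 1.0; seen[p2] = 0;
    }
    touched.clear();
  }

  return List::create(_["rho_g"] = rho_g, _["eps_g"] = eps_g,
                      _["top_prob"] = top_prob, _["rr_num"] = rr_num,
                      _["A"] = A);
}
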