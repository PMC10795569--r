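#include <Rcpp.h>
using namespace Rcpp;

// E-step accumulator for marginal-ML EM.
//
// resp: n x J integer responses in 1..K (NA = structurally missing,
//       skipped, i.e. marginalized out of the person likelihood).
// logP: Q x (J*K) log category probabilities at the Q quadrature nodes,
//       item-major (columns (j-1)*K + 1 .. (j-1)*K + K belong to item j).
// logw: Q log prior weights of the nodes (sum of exp = 1).
//
// Returns per-person log marginal likelihoods, the posterior mass
// accumulated at each node (Nq), and expected per-node category counts
// R (Q x J*K), everything computed on the log scale with log-sum-exp.
// [[Rcpp::export]]
List estep_counts(IntegerMatrix resp, NumericMatrix logP,
                  NumericVector logw, int K) {
  const int n = resp.nrow(), J = resp.ncol(), Q = logP.nrow();
  if (logP.ncol() != J * K) stop("logP has wrong number of columns");
  if (logw.size() != Q) stop("logw length must match logP rows");
  NumericVector ll(n), Nq(Q);
  NumericMatrix R(Q, J * K);
  std::vector<double> acc(Q);

  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < Q; ++q) acc[q] = logw[q];
    for (int j = 0; j < J; ++j) {
      const int y = resp(i, j);
      if (y == NA_INTEGER) continue;
      const double* p = &logP(0, j * K + (y - 1));
      for (int q = 0; q < Q; ++q) acc[q] += p[q];
    }
    double m = acc[0];
    for (int q = 1; q < Q; ++q) if (acc[q] > m) m = acc[q];
    double s = 0.0;
    for (int q = 0; q < Q; ++q) { acc[q] = std::exp(acc[q] - m); s += acc[q]; }
    ll[i] = m + std::log(s);
    const double inv = 1.0 / s;
    for (int q = 0; q < Q; ++q) { acc[q] *= inv; Nq[q] += acc[q]; }
    for (int j = 0; j < J; ++j) {
      const int y = resp(i, j);
      if (y == NA_INTEGER) continue;
      double* rp = &R(0, j * K + (y - 1));
      for (int q = 0; q < Q; ++q) rp[q] += acc[q];
    }
  }
  return List::create(_["ll"] = ll, _["Nq"] = Nq, _["R"] = R);
}
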