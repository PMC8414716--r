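#include <Rcpp.h>
using namespace Rcpp;

// Stochastic-gradient-ascent inner loops of the bipartite embedding trainer.
// All randomness (edge/pair shuffling, negative sampling) happens on the R
// side before these kernels run, so results are reproducible from the R seed.

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// One epoch of skip-gram updates with negative sampling. `centers` and
// `contexts` are 1-based vertex indices in processing order; `negs` holds ns
// negatives per pair (0 = dropped draw). Updates are simultaneous per pair:
// sigmoids and both sides' deltas are evaluated at the pair's entry state.
// [[Rcpp::export]]
List sgd_implicit_epoch_cpp(NumericMatrix emb_, NumericMatrix ctx_,
                            IntegerVector centers, IntegerVector contexts,
                            IntegerMatrix negs, double weight, double lr) {
  NumericMatrix emb = clone(emb_);
  NumericMatrix ctx = clone(ctx_);
  const int dim = emb.ncol();
  const int npairs = centers.size();
  const int ns = negs.ncol();
  std::vector<int> zs(ns + 1);
  std::vector<double> coef(ns + 1);
  std::vector<double> ubuf(dim), demb(dim);
  std::vector<double> old_rows((ns + 1) * dim);
  for (int p = 0; p < npairs; ++p) {
    const int c = centers[p] - 1;
    int K = 0;
    zs[K++] = contexts[p] - 1;
    for (int q = 0; q < ns; ++q) {
      const int z = negs(p, q);
      if (z > 0) zs[K++] = z - 1;
    }
    for (int j = 0; j < dim; ++j) {
      ubuf[j] = emb(c, j);
      demb[j] = 0.0;
    }
    for (int k = 0; k < K; ++k) {
      const int z = zs[k];
      double dot = 0.0;
      for (int j = 0; j < dim; ++j) {
        old_rows[k * dim + j] = ctx(z, j);
        dot += ctx(z, j) * ubuf[j];
      }
      const double ind = (k == 0) ? 1.0 : 0.0;
      coef[k] = lr * weight * (ind - sigmoid(dot));
    }
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < dim; ++j)
        demb[j] += coef[k] * old_rows[k * dim + j];
    // duplicate negatives overwrite sequentially, matching the R matrix-
    // assignment semantics of the reference implementation
    for (int k = 0; k < K; ++k) {
      const int z = zs[k];
      for (int j = 0; j < dim; ++j)
        ctx(z, j) = old_rows[k * dim + j] + coef[k] * ubuf[j];
    }
    for (int j = 0; j < dim; ++j)
      emb(c, j) = ubuf[j] + demb[j];
  }
  return List::create(_["emb"] = emb, _["ctx"] = ctx);
}

// One epoch of explicit-edge updates: for each edge (i, j) in order,
// u_i += lr*gamma*w*(1-sigma(u_i'v_j))*v_j and symmetrically for v_j,
// both evaluated at the entry state.
// [[Rcpp::export]]
List sgd_explicit_epoch_cpp(NumericMatrix U_, NumericMatrix V_,
                            IntegerVector drugs, IntegerVector targets,
                            double gamma, double lr) {
  NumericMatrix U = clone(U_);
  NumericMatrix V = clone(V_);
  const int dim = U.ncol();
  std::vector<double> ubuf(dim);
  for (int e = 0; e < drugs.size(); ++e) {
    const int i = drugs[e] - 1;
    const int j = targets[e] - 1;
    double dot = 0.0;
    for (int d = 0; d < dim; ++d) dot += U(i, d) * V(j, d);
    const double g = lr * gamma * (1.0 - sigmoid(dot));
    for (int d = 0; d < dim; ++d) {
      ubuf[d] = U(i, d);
      U(i, d) += g * V(j, d);
    }
    for (int d = 0; d < dim; ++d) V(j, d) += g * ubuf[d];
  }
  return List::create(_["U"] = U, _["V"] = V);
}
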