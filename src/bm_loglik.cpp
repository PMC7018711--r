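#include <Rcpp.h>
using namespace Rcpp;

// Brownian-motion log-likelihood by Felsenstein's pruning (independent
// contrasts): the product of the n-1 contrast densities, which profiles
// out the root state at its ML value. Edges must be supplied in postorder
// (children before parents); `elen` are effective branch lengths (duration
// times rate scalar) in the same order. Node ids are 1-based with tips
// 1..n_tip holding `tipvals`.
// [[Rcpp::export]]
double bm_contrast_loglik_cpp(IntegerVector post_parent,
                              IntegerVector post_child,
                              NumericVector elen,
                              int n_nodes, int n_tip,
                              NumericVector tipvals, double sigma2) {
  if (sigma2 <= 0.0) return R_NegInf;
  std::vector<double> mean(n_nodes, 0.0), var(n_nodes, 0.0);
  std::vector<char> seen(n_nodes, 0);
  for (int i = 0; i < n_tip; i++) mean[i] = tipvals[i];
  double ll = 0.0;
  const int nE = post_parent.size();
  for (int e = 0; e < nE; e++) {
    const int par = post_parent[e] - 1, chd = post_child[e] - 1;
    const double v = var[chd] + elen[e];
    if (!seen[par]) {
      mean[par] = mean[chd];
      var[par] = v;
      seen[par] = 1;
    } else {
      const double contrast = mean[par] - mean[chd];
      const double vsum = var[par] + v;
      ll += -0.5 * (std::log(2.0 * M_PI * sigma2 * vsum) +
                    contrast * contrast / (sigma2 * vsum));
      mean[par] = (mean[par] * v + mean[chd] * var[par]) / vsum;
      var[par] = var[par] * v / vsum;
    }
  }
  return ll;
}
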