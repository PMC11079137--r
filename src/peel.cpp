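// Inner loop of the pruning likelihood: post-order accumulation of scaled
// conditional likelihoods over site patterns. Only the plain evaluation
// path lives here; passes that must retain per-node partials (gradients,
// ancestral reconstruction) use the R implementation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(rng = false)]]
NumericVector peelCore(List Plist, IntegerMatrix edge, List childEdges,
                       IntegerVector postNodes, IntegerMatrix tipStates,
                       NumericVector pi, int ntip) {
  const int npat = tipStates.ncol();
  const int ns = pi.size();
  const int nnode = childEdges.size();
  std::vector<arma::mat> partial(nnode + 1);
  arma::vec logscale(npat, arma::fill::zeros);

  for (int vi = 0; vi < postNodes.size(); ++vi) {
    const int v = postNodes[vi];              // 1-based node id
    IntegerVector kids = childEdges[v - 1];   // 1-based edge indices
    arma::mat M;
    bool first = true;
    for (int k = 0; k < kids.size(); ++k) {
      const int e = kids[k] - 1;
      NumericMatrix PR = Plist[e];
      const arma::mat P(PR.begin(), ns, ns, false);
      const int child = edge(e, 1);
      arma::mat C(ns, npat);
      if (child <= ntip) {
        arma::vec rs;
        bool haveRs = false;
        for (int s = 0; s < npat; ++s) {
          const int st = tipStates(child - 1, s);
          if (st == NA_INTEGER) {
            // missing state: partial of ones, contribution = row sums
            if (!haveRs) { rs = arma::sum(P, 1); haveRs = true; }
            C.col(s) = rs;
          } else {
            C.col(s) = P.col(st - 1);
          }
        }
      } else {
        C = P * partial[child];
      }
      if (first) { M = std::move(C); first = false; }
      else       { M %= C; }
    }
    for (int s = 0; s < npat; ++s) {
      const double sv = arma::accu(M.col(s));
      if (!(sv > 0.0) || !std::isfinite(sv))
        stop("non-finite likelihood at pattern %d", s + 1);
      M.col(s) /= sv;
      logscale[s] += std::log(sv);
    }
    partial[v] = std::move(M);
  }

  const arma::vec piv(const_cast<double*>(pi.begin()), ns, false);
  const arma::rowvec rootsum = piv.t() * partial[ntip + 1];
  NumericVector out(npat);
  for (int s = 0; s < npat; ++s)
    out[s] = std::log(rootsum[s]) + logscale[s];
  return out;
}
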