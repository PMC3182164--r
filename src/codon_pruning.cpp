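// Felsenstein pruning for mixture codon models, with the generator held as
// the eigendecomposition of its reversible (symmetrized) form so that
// P(t) = D^{-1/2} V exp(Lambda t) V' D^{1/2} with D = diag(pi).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat pmat_from_decomp(const arma::mat& V, const arma::vec& lam,
                                  const arma::vec& sqpi, double t) {
  arma::mat E = V * arma::diagmat(arma::exp(lam * t)) * V.t();
  E.each_col() /= sqpi;       // D^{-1/2} on the left
  E.each_row() %= sqpi.t();   // D^{1/2} on the right
  E.elem(arma::find(E < 0.0)).zeros();  // clamp eigen round-off
  return E;
}

// [[Rcpp::export]]
arma::mat cpp_pmat(const arma::mat& V, const arma::vec& lam,
                   const arma::vec& sqpi, double t) {
  return pmat_from_decomp(V, lam, sqpi, t);
}

// eigendecomposition of the symmetrized generator
// [[Rcpp::export]]
List cpp_sym_eig(const arma::mat& B) {
  arma::vec lam;
  arma::mat V;
  arma::eig_sym(lam, V, arma::symmatu((B + B.t()) / 2));
  return List::create(_["values"] = lam, _["vectors"] = V);
}

// tipstate: ntip x npat, 0-based sense-codon index, -1 = missing/gap
// edge:     nedge x 2 (parent, child), 1-based node ids, postorder
// dmap:     nclass x nedge, 1-based index into decomps
// decomps:  list of list(V, lambda, sqpi, pi)
// Returns the total log-likelihood (pattern-weighted) and the per-pattern,
// per-class conditional site likelihoods f(x_h | class k).
// [[Rcpp::export]]
List cpp_prune_mix(const IntegerMatrix& tipstate,
                   const IntegerMatrix& edge,
                   const NumericVector& blen,
                   const int nnode,
                   const int root,
                   const List& decomps,
                   const IntegerMatrix& dmap,
                   const NumericVector& clwt,
                   const NumericVector& patwt) {
  const int ntip = tipstate.nrow();
  const int npat = tipstate.ncol();
  const int nedge = edge.nrow();
  const int nclass = dmap.nrow();

  // unpack decompositions once
  const int ndec = decomps.size();
  std::vector<arma::mat> Vs(ndec);
  std::vector<arma::vec> lams(ndec), sqpis(ndec), pis(ndec);
  for (int d = 0; d < ndec; ++d) {
    List dd = decomps[d];
    Vs[d] = as<arma::mat>(dd["V"]);
    lams[d] = as<arma::vec>(dd["lambda"]);
    sqpis[d] = as<arma::vec>(dd["sqpi"]);
    pis[d] = as<arma::vec>(dd["pi"]);
  }
  const int ns = Vs[0].n_rows;

  arma::mat sitelik(npat, nclass, arma::fill::zeros);

  // P(t) depends only on (decomposition, edge); classes often share both
  std::vector<arma::mat> pcache((size_t)ndec * nedge);
  std::vector<bool> pdone((size_t)ndec * nedge, false);

  for (int k = 0; k < nclass; ++k) {
    std::vector<arma::mat> partial(nnode + 1);
    std::vector<bool> seen(nnode + 1, false);
    for (int e = 0; e < nedge; ++e) {
      const int par = edge(e, 0);
      const int ch = edge(e, 1);
      const int d = dmap(k, e) - 1;
      const size_t ckey = (size_t)d * nedge + e;
      if (!pdone[ckey]) {
        pcache[ckey] = pmat_from_decomp(Vs[d], lams[d], sqpis[d], blen[e]);
        pdone[ckey] = true;
      }
      const arma::mat& P = pcache[ckey];
      arma::mat cond(ns, npat);
      if (ch <= ntip) {
        for (int h = 0; h < npat; ++h) {
          const int s = tipstate(ch - 1, h);
          if (s < 0) cond.col(h).ones();
          else cond.col(h) = P.col(s);
        }
      } else {
        cond = P * partial[ch];
        partial[ch].reset();
      }
      if (!seen[par]) {
        partial[par] = cond;
        seen[par] = true;
      } else {
        partial[par] %= cond;
      }
    }
    sitelik.col(k) = (pis[dmap(k, 0) - 1].t() * partial[root]).t();
  }

  arma::vec mix = sitelik * as<arma::vec>(clwt);
  double lnL = 0.0;
  bool ok = true;
  for (int h = 0; h < npat; ++h) {
    if (mix[h] <= 0.0 || !std::isfinite(mix[h])) { ok = false; break; }
    lnL += patwt[h] * std::log(mix[h]);
  }
  if (!ok) lnL = -std::numeric_limits<double>::infinity();
  return List::create(_["lnL"] = lnL, _["sitelik"] = sitelik);
}
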