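// Felsenstein pruning for reversible codon models, with analytic
// branch-length gradients, plus a specialised objective for the three-branch
// (triplet) Ka/Ks parameterization. Eigendecomposition of the symmetrized
// generator gives P(t) = D^{-1/2} V exp(Lambda t) V' D^{1/2} for all t.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Eigendecomposition of a reversible generator Q with stationary
// distribution pi. Returns left/right factors and eigenvalues such that
// expm(Q t) = left * diag(exp(lam t)) * right.
// [[Rcpp::export]]
List cpp_eig_rev(const arma::mat& Q, const arma::vec& pi) {
  arma::vec d = arma::sqrt(pi);
  arma::mat S = arma::diagmat(d) * Q * arma::diagmat(1.0 / d);
  S = 0.5 * (S + S.t()); // clean roundoff asymmetry
  arma::vec lam;
  arma::mat V;
  if (!arma::eig_sym(lam, V, S)) stop("eigendecomposition failed");
  arma::mat left = arma::diagmat(1.0 / d) * V;
  arma::mat right = V.t() * arma::diagmat(d);
  return List::create(_["left"] = left, _["right"] = right, _["lam"] = lam);
}

// Assemble Q = sum_k mult[k] * parts[,,k] (off-diagonal blocks), fill the
// diagonal, optionally rescale to unit equilibrium rate, and return its
// eigendecomposition — one fused call per rate-parameter change.
// [[Rcpp::export]]
List cpp_build_eig(const arma::cube& parts, const arma::vec& mult,
                   const arma::vec& pi, bool scale) {
  const int ns = pi.n_elem;
  arma::mat Q(ns, ns, arma::fill::zeros);
  for (arma::uword k = 0; k < parts.n_slices; ++k) {
    Q += mult(k) * parts.slice(k);
  }
  Q.diag() = -arma::sum(Q, 1);
  double rate = -arma::dot(pi, Q.diag());
  if (scale) {
    if (!(rate > 0)) stop("degenerate rate matrix: zero total rate");
    Q /= rate;
  }
  arma::vec d = arma::sqrt(pi);
  arma::mat S = arma::diagmat(d) * Q * arma::diagmat(1.0 / d);
  S = 0.5 * (S + S.t());
  arma::vec lam;
  arma::mat V;
  if (!arma::eig_sym(lam, V, S, "dc")) stop("eigendecomposition failed");
  arma::mat left = arma::diagmat(1.0 / d) * V;
  arma::mat right = V.t() * arma::diagmat(d);
  return List::create(_["left"] = left, _["right"] = right, _["lam"] = lam,
                      _["rate"] = rate);
}

static arma::mat prob_matrix(const arma::mat& left, const arma::mat& right,
                             const arma::vec& lam, double t) {
  arma::mat P = left * arma::diagmat(arma::exp(lam * t)) * right;
  P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return P;
}

// Pruning log-likelihood over site patterns, optionally with the gradient of
// lnL with respect to every branch length.
//
// edge:      E x 2 matrix (parent, child), 1-based, in postorder.
// tipcodes:  npat x ntip integer matrix, 0-based codon states, -1 = missing.
// eclass:    1-based class index per edge into the eigen cubes.
// [[Rcpp::export]]
List cpp_tree_lnl(const arma::imat& edge, int ntip,
                  const arma::imat& tipcodes, const arma::vec& weights,
                  const arma::vec& pi, const arma::cube& left,
                  const arma::cube& right, const arma::mat& lam,
                  const arma::ivec& eclass, const arma::vec& tvec,
                  bool grad) {
  const int E = edge.n_rows;
  const int npat = tipcodes.n_rows;
  const int ns = pi.n_elem;
  const int nnode = edge.max();

  std::vector<arma::mat> down(nnode + 1); // partials per node
  arma::mat scale(nnode + 1, npat, arma::fill::zeros); // log-scale per node
  std::vector<arma::mat> Tedge(grad ? E : 0);
  std::vector<arma::rowvec> divs(grad ? E : 0);
  std::vector<int> rootcand(nnode + 1, 1);

  for (int k = 0; k < E; ++k) {
    int p = edge(k, 0), c = edge(k, 1);
    rootcand[c] = 0;
    int cl = eclass(k) - 1;
    arma::mat P = prob_matrix(left.slice(cl), right.slice(cl),
                              lam.col(cl), tvec(k));
    arma::mat T(ns, npat);
    if (c <= ntip) {
      for (int s = 0; s < npat; ++s) {
        int x = tipcodes(s, c - 1);
        if (x < 0) T.col(s).ones();
        else T.col(s) = P.col(x);
      }
    } else {
      T = P * down[c];
    }
    arma::rowvec m = arma::max(T, 0);
    m.transform([](double v) { return v <= 0.0 ? 1.0 : v; });
    T.each_row() /= m;
    if (down[p].n_elem == 0) down[p] = arma::mat(ns, npat, arma::fill::ones);
    down[p] %= T;
    scale.row(p) += arma::log(m);
    if (c > ntip) scale.row(p) += scale.row(c);
    if (grad) {
      Tedge[k] = T;
      divs[k] = m;
    }
  }

  int root = -1;
  for (int v = ntip + 1; v <= nnode; ++v) {
    if (rootcand[v]) { root = v; break; }
  }
  if (root < 0) stop("malformed edge matrix: no root found");

  arma::rowvec sitelik = pi.t() * down[root]; // scaled site likelihoods
  for (int s = 0; s < npat; ++s) {
    if (!(sitelik(s) > 0.0)) stop("non-finite site likelihood at pattern %d",
                                  s + 1);
  }
  double lnl = arma::dot(weights,
                         (arma::log(sitelik) + scale.row(root)).t());

  if (!grad) return List::create(_["lnl"] = lnl);

  // Up (outside) pass: O[v] holds the likelihood contribution of everything
  // outside the subtree below v, including the root prior.
  std::vector<arma::mat> outside(nnode + 1);
  outside[root] = arma::repmat(pi, 1, npat);
  std::vector<std::vector<int>> kids(nnode + 1);
  for (int k = 0; k < E; ++k) kids[edge(k, 0)].push_back(k);
  std::vector<int> expanded(nnode + 1, 0);
  arma::vec gradient(E, arma::fill::zeros);

  for (int k = E - 1; k >= 0; --k) {
    int p = edge(k, 0);
    if (expanded[p]) continue;
    expanded[p] = 1;
    const std::vector<int>& ke = kids[p];
    int nk = ke.size();
    // prefix/suffix products of sibling T arrays
    std::vector<arma::mat> pre(nk + 1), suf(nk + 1);
    pre[0] = arma::mat(ns, npat, arma::fill::ones);
    for (int m2 = 0; m2 < nk; ++m2) pre[m2 + 1] = pre[m2] % Tedge[ke[m2]];
    suf[nk] = arma::mat(ns, npat, arma::fill::ones);
    for (int m2 = nk - 1; m2 >= 0; --m2) suf[m2] = suf[m2 + 1] % Tedge[ke[m2]];
    for (int m2 = 0; m2 < nk; ++m2) {
      int e = ke[m2];
      int c = edge(e, 1);
      arma::mat W = outside[p] % pre[m2] % suf[m2 + 1];
      int cl = eclass(e) - 1;
      // d/dt expm(Qt) = left diag(lam exp(lam t)) right, same column scaling
      arma::vec el = lam.col(cl) % arma::exp(lam.col(cl) * tvec(e));
      arma::mat Pd = left.slice(cl) * arma::diagmat(el) * right.slice(cl);
      arma::mat Td(ns, npat);
      if (c <= ntip) {
        for (int s = 0; s < npat; ++s) {
          int x = tipcodes(s, c - 1);
          if (x < 0) Td.col(s).zeros(); // row sums of Q-like matrix are 0
          else Td.col(s) = Pd.col(x);
        }
      } else {
        Td = Pd * down[c];
      }
      Td.each_row() /= divs[e];
      arma::rowvec denom = arma::sum(W % Tedge[e], 0);
      arma::rowvec numer = arma::sum(W % Td, 0);
      gradient(e) = arma::dot(weights, (numer / denom).t());
      if (c > ntip) {
        int cl2 = eclass(e) - 1;
        arma::mat P = prob_matrix(left.slice(cl2), right.slice(cl2),
                                  lam.col(cl2), tvec(e));
        arma::mat Oc = P.t() * W;
        arma::rowvec m = arma::max(Oc, 0);
        m.transform([](double v) { return v <= 0.0 ? 1.0 : v; });
        Oc.each_row() /= m;
        outside[c] = Oc;
      }
    }
  }

  return List::create(_["lnl"] = lnl, _["grad"] = gradient);
}

// Negative log-likelihood of a three-sequence star tree under branch-specific
// (Ka, Ks). par = log(kappa), then log(Ka_b), log(Ks_b) for b = 1..3.
// Qs_tv/Qs_ts/Qn_tv/Qn_ts are off-diagonal-only MG rate parts
// (synonymous/nonsynonymous x transversion/transition), zero diagonal.
// [[Rcpp::export]]
double cpp_triplet_nll(const arma::vec& par, const arma::imat& tipcodes,
                       const arma::vec& weights, const arma::vec& pi,
                       const arma::mat& Qs_tv, const arma::mat& Qs_ts,
                       const arma::mat& Qn_tv, const arma::mat& Qn_ts) {
  const int ns = pi.n_elem;
  const int npat = tipcodes.n_rows;
  double kappa = std::exp(par(0));
  arma::mat Qs = Qs_tv + kappa * Qs_ts;
  arma::mat Qn = Qn_tv + kappa * Qn_ts;
  // total mutational flux per codon under the neutral (Ka = Ks) model
  double etot = arma::as_scalar(pi.t() * arma::sum(Qs + Qn, 1));
  arma::vec d = arma::sqrt(pi);

  arma::mat cols[3];
  for (int b = 0; b < 3; ++b) {
    double Ka = std::exp(par(1 + 2 * b));
    double Ks = std::exp(par(2 + 2 * b));
    arma::mat G = (3.0 / etot) * (Ka * Qn + Ks * Qs);
    G.diag() = -arma::sum(G, 1);
    arma::mat S = arma::diagmat(d) * G * arma::diagmat(1.0 / d);
    S = 0.5 * (S + S.t());
    arma::vec lam;
    arma::mat V;
    if (!arma::eig_sym(lam, V, S)) stop("eigendecomposition failed");
    arma::mat P = arma::diagmat(1.0 / d) * V * arma::diagmat(arma::exp(lam)) *
      V.t() * arma::diagmat(d);
    P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    cols[b] = P;
  }

  double nll = 0.0;
  for (int s = 0; s < npat; ++s) {
    arma::vec acc = pi;
    for (int b = 0; b < 3; ++b) {
      int x = tipcodes(s, b);
      if (x >= 0) acc %= cols[b].col(x);
    }
    double L = arma::accu(acc);
    if (!(L > 0.0)) stop("non-finite site likelihood at pattern %d", s + 1);
    nll -= weights(s) * std::log(L);
  }
  return nll;
}
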