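// Likelihood and Metropolis-Hastings core for the six expression-evolution
// models. Species means are integrated out analytically, so per-gene state is
// just (xbar_j, SS_j, n_j) per species plus tree precomputations done in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093453;

struct TreeC {
  int S;
  arma::mat Sb;      // shared root-path lengths over background edges
  arma::mat Sf;      // shared root-path lengths over foreground edges
  arma::ivec parent; // preorder, 0-based, root = -1
  arma::vec  elen;   // branch length to parent
  arma::ivec isfg;   // parent edge is foreground
  arma::ivec tippos; // preorder position of tip i (0-based)
  arma::imat mrcapos;
  arma::vec  height; // time from root
};

static TreeC unpack_tree(const List& tl) {
  TreeC t;
  t.S = as<int>(tl["S"]);
  t.Sb = as<arma::mat>(tl["Sb"]);
  t.Sf = as<arma::mat>(tl["Sf"]);
  t.parent = as<arma::ivec>(tl["parent"]) - 1;
  t.elen = as<arma::vec>(tl["elen"]);
  t.isfg = as<arma::ivec>(tl["isfg"]);
  t.tippos = as<arma::ivec>(tl["tippos"]) - 1;
  t.mrcapos = as<arma::imat>(tl["mrcapos"]) - 1;
  t.height = as<arma::vec>(tl["height"]);
  return t;
}

struct GeneC {
  arma::vec xbar, ss, n;
  arma::mat Bt; // (S-1) x S replicate-weighted orthonormal contrasts
};

static GeneC unpack_gene(const List& gl) {
  GeneC g;
  g.xbar = as<arma::vec>(gl["xbar"]);
  g.ss = as<arma::vec>(gl["ss"]);
  g.n = as<arma::vec>(gl["n"]);
  g.Bt = as<arma::mat>(gl["Bt"]);
  return g;
}

// log density of y ~ MVN(0, S); -Inf if S is not positive definite
static double dmvn0(const arma::vec& y, const arma::mat& S) {
  arma::mat L;
  if (!arma::chol(L, arma::symmatu(S), "lower")) return R_NegInf;
  arma::vec z = arma::solve(arma::trimatl(L), y);
  double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  return -0.5 * (double)y.n_elem * LOG2PI - 0.5 * logdet - 0.5 * arma::dot(z, z);
}

// within-species likelihood factor shared by all phylogenetic models;
// reml = TRUE drops the 0.5*log(n_j) that belongs to the species-mean block
static double within_part(const GeneC& g, const arma::vec& d, bool reml) {
  double ll = 0.0;
  for (arma::uword j = 0; j < g.n.n_elem; ++j) {
    ll += -0.5 * (g.n[j] - 1.0) * (LOG2PI + std::log(d[j])) - g.ss[j] / (2.0 * d[j]);
    if (!reml) ll += -0.5 * std::log(g.n[j]);
  }
  return ll;
}

// OU first two moments of tip species-means; stationary root (mean theta_root,
// variance s2_root/(2 alpha)); theta/sigma^2 piecewise constant per edge.
static void ou_moments(const TreeC& t, double s2B, double s2F, double alpha,
                       double thB, double thF, arma::vec& M, arma::mat& V) {
  int nn = t.parent.n_elem;
  arma::vec m(nn), v(nn);
  m[0] = thB;
  v[0] = s2B / (2.0 * alpha);
  for (int k = 1; k < nn; ++k) {
    int p = t.parent[k];
    double L = t.elen[k];
    double th = t.isfg[k] ? thF : thB;
    double s2 = t.isfg[k] ? s2F : s2B;
    double e1 = std::exp(-alpha * L);
    m[k] = th + (m[p] - th) * e1;
    // (1 - exp(-2 a L)) / (2 a), stable for small alpha
    double bv = -std::expm1(-2.0 * alpha * L) / (2.0 * alpha);
    v[k] = v[p] * e1 * e1 + s2 * bv;
  }
  int S = t.S;
  M.set_size(S);
  V.set_size(S, S);
  for (int i = 0; i < S; ++i) {
    int ti = t.tippos[i];
    M[i] = m[ti];
    V(i, i) = v[ti];
    for (int j = i + 1; j < S; ++j) {
      int a = t.mrcapos(i, j);
      double di = t.height[t.tippos[i]] - t.height[a];
      double dj = t.height[t.tippos[j]] - t.height[a];
      double c = v[a] * std::exp(-alpha * (di + dj));
      V(i, j) = c;
      V(j, i) = c;
    }
  }
}

// p layouts (natural scale):
// 1 EQUAL_MEANS:   mu, d[1..S]
// 2 UNEQUAL_MEANS: mu[1..S], d[1..S]
// 3 BM:            s2, d
// 4 BM_SHIFT:      s2B, s2F, d
// 5 OU:            s2, alpha, theta, d
// 6 OU_SHIFT:      s2B, s2F, alpha, thB, thF, d
static double loglik_model(int model, const TreeC& t, const GeneC& g,
                           const arma::vec& p) {
  int S = t.S;
  arma::vec d;
  double ll = 0.0;
  switch (model) {
  case 1: case 2: {
    d = p.subvec(model == 1 ? 1 : S, p.n_elem - 1);
    for (int j = 0; j < S; ++j) {
      double mu = (model == 1) ? p[0] : p[j];
      ll += -0.5 * g.n[j] * (LOG2PI + std::log(d[j]))
            - (g.ss[j] + g.n[j] * std::pow(g.xbar[j] - mu, 2)) / (2.0 * d[j]);
    }
    return ll;
  }
  case 3: case 4: {
    double s2B = p[0];
    double s2F = (model == 3) ? p[0] : p[1];
    d = p.subvec(model == 3 ? 1 : 2, p.n_elem - 1);
    arma::mat W = s2B * t.Sb + s2F * t.Sf;
    W.diag() += d / g.n;
    arma::vec y = g.Bt * g.xbar;   // contrasts kill the unknown root state
    arma::mat Sy = g.Bt * W * g.Bt.t();
    double lm = dmvn0(y, Sy);
    if (!std::isfinite(lm)) return R_NegInf;
    return lm + within_part(g, d, true);
  }
  case 5: case 6: {
    double s2B, s2F, alpha, thB, thF;
    if (model == 5) {
      s2B = s2F = p[0]; alpha = p[1]; thB = thF = p[2];
      d = p.subvec(3, p.n_elem - 1);
    } else {
      s2B = p[0]; s2F = p[1]; alpha = p[2]; thB = p[3]; thF = p[4];
      d = p.subvec(5, p.n_elem - 1);
    }
    arma::vec M; arma::mat V;
    ou_moments(t, s2B, s2F, alpha, thB, thF, M, V);
    V.diag() += d / g.n;
    double lm = dmvn0(g.xbar - M, V);
    if (!std::isfinite(lm)) return R_NegInf;
    return lm + within_part(g, d, false);
  }
  }
  return R_NegInf;
}

// [[Rcpp::export]]
double cpp_model_loglik(int model, List tree, List gene, NumericVector p) {
  TreeC t = unpack_tree(tree);
  GeneC g = unpack_gene(gene);
  return loglik_model(model, t, g, as<arma::vec>(p));
}

// [[Rcpp::export]]
NumericVector cpp_ou_moments(List tree, double s2B, double s2F, double alpha,
                             double thB, double thF) {
  TreeC t = unpack_tree(tree);
  arma::vec M; arma::mat V;
  ou_moments(t, s2B, s2F, alpha, thB, thF, M, V);
  NumericVector out(t.S + t.S * t.S);
  for (int i = 0; i < t.S; ++i) out[i] = M[i];
  for (int i = 0; i < t.S * t.S; ++i) out[t.S + i] = V(i / t.S, i % t.S);
  return out;
}

static double reflect(double z, double lo, double hi) {
  if (!(hi > lo)) return lo;
  while (z < lo || z > hi) {
    if (z < lo) z = 2.0 * lo - z; else z = 2.0 * hi - z;
  }
  return z;
}

// Metropolis-Hastings chain on the power posterior prior(x) * L(x)^beta.
// Positive (log-uniform prior) parameters are updated on the log scale where
// their prior is flat, so all proposals are symmetric sliding windows with
// reflection at the prior bounds; acceptance reduces to beta * delta-loglik.
// [[Rcpp::export]]
List cpp_mh_chain(int model, List tree, List gene,
                  NumericVector lo, NumericVector hi, IntegerVector ptype,
                  LogicalVector is_free, NumericVector init,
                  int burnin, int tune_interval, int iters, int thin,
                  int updates_per_param, double beta, double target_accept,
                  NumericVector scales_init) {
  TreeC t = unpack_tree(tree);
  GeneC g = unpack_gene(gene);
  int P = init.size();

  arma::vec zlo(P), zhi(P), z(P), w = as<arma::vec>(scales_init);
  arma::vec p = as<arma::vec>(init);
  for (int k = 0; k < P; ++k) {
    zlo[k] = ptype[k] == 1 ? std::log(lo[k]) : lo[k];
    zhi[k] = ptype[k] == 1 ? std::log(hi[k]) : hi[k];
    z[k] = ptype[k] == 1 ? std::log(p[k]) : p[k];
  }

  std::vector<int> freeidx;
  for (int k = 0; k < P; ++k) if (is_free[k]) freeidx.push_back(k);
  int nf = (int)freeidx.size();

  double ll = loglik_model(model, t, g, p);
  int nret = iters / thin;
  arma::mat samples(nret, P);
  arma::vec llout(nret);
  arma::vec acc_win(P, arma::fill::zeros), prop_win(P, arma::fill::zeros);
  arma::vec acc_tot(P, arma::fill::zeros), prop_tot(P, arma::fill::zeros);

  std::vector<int> order(nf * std::max(updates_per_param, 0));
  int row = 0;
  for (int iter = 1; iter <= burnin + iters; ++iter) {
    if (nf > 0) {
      for (int u = 0; u < updates_per_param; ++u)
        for (int k = 0; k < nf; ++k) order[u * nf + k] = freeidx[k];
      for (int i = (int)order.size() - 1; i > 0; --i) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
      for (size_t oi = 0; oi < order.size(); ++oi) {
        int k = order[oi];
        double zold = z[k], pold = p[k];
        double znew = reflect(zold + (2.0 * unif_rand() - 1.0) * w[k], zlo[k], zhi[k]);
        z[k] = znew;
        p[k] = ptype[k] == 1 ? std::exp(znew) : znew;
        double llnew = loglik_model(model, t, g, p);
        prop_win[k] += 1.0;
        bool accept = std::isfinite(llnew) &&
          (beta * (llnew - ll) >= 0.0 || std::log(unif_rand()) < beta * (llnew - ll));
        if (accept) {
          ll = llnew;
          acc_win[k] += 1.0;
        } else {
          z[k] = zold; p[k] = pold;
        }
        if (iter > burnin) {
          prop_tot[k] += 1.0;
          if (accept) acc_tot[k] += 1.0;
        }
      }
    }
    if (iter <= burnin && tune_interval > 0 && iter % tune_interval == 0) {
      for (int i = 0; i < nf; ++i) {
        int k = freeidx[i];
        if (prop_win[k] > 0) {
          double rate = acc_win[k] / prop_win[k];
          double f = std::exp(2.0 * (rate - target_accept));
          if (f < 0.5) f = 0.5;
          if (f > 2.0) f = 2.0;
          w[k] = std::min(std::max(w[k] * f, 1e-8), zhi[k] - zlo[k]);
        }
        acc_win[k] = 0.0; prop_win[k] = 0.0;
      }
    }
    if (iter > burnin && (iter - burnin) % thin == 0) {
      samples.row(row) = p.t();
      llout[row] = ll;
      ++row;
    }
  }

  arma::vec acc_rate(P);
  for (int k = 0; k < P; ++k)
    acc_rate[k] = prop_tot[k] > 0 ? acc_tot[k] / prop_tot[k] : NA_REAL;

  return List::create(_["samples"] = samples, _["loglik"] = llout,
                      _["accept"] = acc_rate, _["scales"] = w,
                      _["last"] = p, _["last_loglik"] = ll);
}
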