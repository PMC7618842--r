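// Core numerical engine for k-state continuous-time Markov (Mk) models on
// phylogenies: pruning likelihood, power-posterior MCMC and stepping-stone
// marginal likelihoods. Trees arrive as ape-style postorder edge matrices
// (tips 1..ntip, root ntip+1). All randomness uses R's RNG so set.seed()
// in R fully determines every run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Transition probabilities P(t) = exp(Qt). A complex eigendecomposition is
// computed once per Q; if Q is defective (reconstruction error too large)
// every call falls back to arma::expmat.
class TransProb {
public:
  arma::mat Q;
  bool spectral_ok;
  arma::cx_vec eval;
  arma::cx_mat evec, evec_inv;

  explicit TransProb(const arma::mat& Q_) : Q(Q_), spectral_ok(false) {
    arma::cx_vec ev;
    arma::cx_mat V;
    if (arma::eig_gen(ev, V, arma::cx_mat(Q, arma::mat(Q.n_rows, Q.n_cols, arma::fill::zeros)))) {
      arma::cx_mat Vi;
      if (arma::inv(Vi, V)) {
        arma::mat recon = arma::real(V * arma::diagmat(ev) * Vi);
        double qn = arma::norm(Q, "fro");
        double err = arma::norm(recon - Q, "fro");
        if (err <= 1e-9 * std::max(1.0, qn)) {
          eval = ev; evec = V; evec_inv = Vi;
          spectral_ok = true;
        }
      }
    }
  }

  arma::mat at(double t) const {
    const arma::uword k = Q.n_rows;
    if (t <= 0.0) return arma::eye(k, k);
    arma::mat P;
    if (spectral_ok) {
      arma::cx_vec e = arma::exp(eval * t);
      P = arma::real(evec * arma::diagmat(e) * evec_inv);
    } else {
      P = arma::expmat(Q * t);
    }
    P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    return P;
  }

  // out_i = sum_j P(t)(i, j) x_j without forming P(t): spectral fast path
  // with no heap allocation (k is small). Falls back to at(t) otherwise.
  void apply(double t, const double* x, double* out) const {
    const arma::uword k = Q.n_rows;
    if (!spectral_ok) {
      arma::mat P = at(t);
      for (arma::uword i = 0; i < k; ++i) {
        double s = 0.0;
        for (arma::uword j = 0; j < k; ++j) s += P(i, j) * x[j];
        out[i] = s;
      }
      return;
    }
    std::complex<double> w[16];
    for (arma::uword a = 0; a < k; ++a) {
      std::complex<double> s(0.0, 0.0);
      for (arma::uword j = 0; j < k; ++j) s += evec_inv(a, j) * x[j];
      w[a] = s * std::exp(eval(a) * t);
    }
    for (arma::uword i = 0; i < k; ++i) {
      std::complex<double> s(0.0, 0.0);
      for (arma::uword a = 0; a < k; ++a) s += evec(i, a) * w[a];
      double v = s.real();
      out[i] = v < 0.0 ? 0.0 : v;
    }
  }
};

// Pruning (post-order dynamic program). tipp holds per-tip partial
// likelihoods (rows = tips in node order 1..ntip; ambiguity = several 1s).
static double loglik_core(const arma::imat& edge, const arma::vec& el,
                          int ntip, int nnode, const arma::mat& tipp,
                          const TransProb& tp, const arma::vec& rootfreq) {
  const arma::uword k = tp.Q.n_rows;
  if (k > 16) stop("state space too large (k > 16)");
  const int ntot = ntip + nnode;
  arma::mat L(ntot, k, arma::fill::ones);
  L.rows(0, ntip - 1) = tipp;
  double logscale = 0.0;

  double xbuf[16], dbuf[16];
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    for (arma::uword j = 0; j < k; ++j) xbuf[j] = L(c, j);
    tp.apply(el(e), xbuf, dbuf);            // dbuf_i = sum_j P(i,j) L_c(j)
    double m = 0.0;
    for (arma::uword i = 0; i < k; ++i) {
      L(p, i) *= dbuf[i];
      if (L(p, i) > m) m = L(p, i);
    }
    if (m <= 0.0) return R_NegInf;
    if (m < 1e-100) { L.row(p) /= m; logscale += std::log(m); }
  }
  // final rescale guard for the root row
  const int root = ntip;  // node ntip+1, 0-based index ntip
  double lik = arma::dot(L.row(root).t(), rootfreq);
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + logscale;
}

// [[Rcpp::export]]
double mk_loglik_cpp(const arma::imat& edge, const arma::vec& el,
                     int ntip, int nnode, const arma::mat& tipp,
                     const arma::mat& Q, const arma::vec& rootfreq) {
  TransProb tp(Q);
  return loglik_core(edge, el, ntip, nnode, tipp, tp, rootfreq);
}

// Build Q from a parameter vector via the constraint map:
// map(i,j) == 0 -> structural zero, g >= 1 -> rates[g-1]; diagonal completes.
static arma::mat build_Q(const arma::imat& map, const arma::vec& rates) {
  const arma::uword k = map.n_rows;
  arma::mat Q(k, k, arma::fill::zeros);
  for (arma::uword i = 0; i < k; ++i)
    for (arma::uword j = 0; j < k; ++j)
      if (i != j && map(i, j) > 0) Q(i, j) = rates(map(i, j) - 1);
  for (arma::uword i = 0; i < k; ++i) Q(i, i) = -arma::accu(Q.row(i)) + Q(i, i);
  return Q;
}

static double logsumexp(const std::vector<double>& v) {
  double m = R_NegInf;
  for (double x : v) if (x > m) m = x;
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// One MCMC sweep over (log-rates, hyper mean m). Prior: r_g ~ Exp(mean m),
// m ~ Uniform(0, hyper_upper). Likelihood tempered by beta.
struct ChainState {
  arma::vec rates;
  double m;
  double logL;
  long n_prop = 0, n_acc = 0;
};

static double rate_logprior(const arma::vec& r, double m) {
  // Exponential with mean m: sum(-r/m - log m)
  double s = 0.0;
  for (arma::uword g = 0; g < r.n_elem; ++g) s += -r(g) / m - std::log(m);
  return s;
}

static void sweep(ChainState& st, double beta, double prop_sd,
                  double hyper_upper,
                  const arma::imat& edge, const arma::vec& el, int ntip,
                  int nnode, const arma::mat& tipp, const arma::imat& map,
                  const arma::vec& rootfreq) {
  const int G = st.rates.n_elem;
  // rate update: one randomly chosen group, multiplicative log-walk
  int g = (int)std::floor(R::runif(0.0, 1.0) * G);
  if (g >= G) g = G - 1;
  arma::vec prop = st.rates;
  prop(g) = st.rates(g) * std::exp(R::rnorm(0.0, prop_sd));
  TransProb tp(build_Q(map, prop));
  double logL_new = loglik_core(edge, el, ntip, nnode, tipp, tp, rootfreq);
  // prior ratio + log-scale Jacobian (dr = r dlogr)
  double lp = beta * (logL_new - st.logL)
    + (-prop(g) / st.m) - (-st.rates(g) / st.m)
    + std::log(prop(g)) - std::log(st.rates(g));
  st.n_prop++;
  if (std::isfinite(logL_new) && std::log(R::runif(0.0, 1.0)) < lp) {
    st.rates = prop; st.logL = logL_new; st.n_acc++;
  }
  // hyper-mean update: independence proposal from its uniform prior
  double m_new = R::runif(0.0, hyper_upper);
  double lr = rate_logprior(st.rates, m_new) - rate_logprior(st.rates, st.m);
  if (std::log(R::runif(0.0, 1.0)) < lr) st.m = m_new;
}

// Stepping-stone estimator of the log marginal likelihood. betas has K+1
// entries 0 = b_0 < ... < b_K = 1; the chain samples at b_s and the stone
// contribution is log mean exp((b_{s+1}-b_s) logL).
// [[Rcpp::export]]
List ss_run_cpp(const arma::imat& edge, const arma::vec& el, int ntip,
                int nnode, const arma::mat& tipp, const arma::imat& map,
                int ngroups, double hyper_upper, const arma::vec& betas,
                int iter_per_stone, double burn_frac, double prop_sd,
                const arma::vec& rootfreq) {
  ChainState st;
  st.m = R::runif(0.0, hyper_upper);
  st.rates.set_size(ngroups);
  for (int g = 0; g < ngroups; ++g) st.rates(g) = R::rexp(st.m);
  {
    TransProb tp(build_Q(map, st.rates));
    st.logL = loglik_core(edge, el, ntip, nnode, tipp, tp, rootfreq);
    // prior draws can land in a zero-likelihood region; nudge until finite
    int tries = 0;
    while (!std::isfinite(st.logL) && tries++ < 200) {
      for (int g = 0; g < ngroups; ++g) st.rates(g) = R::rexp(st.m);
      TransProb tp2(build_Q(map, st.rates));
      st.logL = loglik_core(edge, el, ntip, nnode, tipp, tp2, rootfreq);
    }
  }
  const int K = betas.n_elem - 1;
  const int nburn = (int)std::ceil(burn_frac * iter_per_stone);
  arma::vec contrib(K);
  double logml = 0.0;
  for (int s = 0; s < K; ++s) {
    const double b = betas(s), db = betas(s + 1) - betas(s);
    std::vector<double> terms;
    terms.reserve(iter_per_stone);
    for (int it = 0; it < nburn + iter_per_stone; ++it) {
      sweep(st, b, prop_sd, hyper_upper, edge, el, ntip, nnode, tipp, map,
            rootfreq);
      if (it >= nburn) terms.push_back(db * st.logL);
    }
    double c = logsumexp(terms) - std::log((double)terms.size());
    if (!std::isfinite(c))
      stop("non-finite stepping-stone contribution at stone %d", s);
    contrib(s) = c;
    logml += c;
  }
  return List::create(
    _["log_marginal"] = logml, _["stone_contributions"] = contrib,
    _["acceptance_rate"] = (double)st.n_acc / std::max(1L, st.n_prop),
    _["final_rates"] = st.rates, _["final_hyper_mean"] = st.m);
}

// Posterior MCMC over rates, hyper mean and (uniform) tree index across a
// tree set. Trees are passed as parallel lists of edge matrices, lengths and
// tip partial matrices.
// [[Rcpp::export]]
List mcmc_run_cpp(List edges, List els, List tipps, IntegerVector ntips,
                  IntegerVector nnodes, const arma::imat& map, int ngroups,
                  double hyper_upper, int iterations, int burn_in, int thin,
                  double prop_sd, const arma::vec& rootfreq) {
  const int ntree = edges.size();
  std::vector<arma::imat> E(ntree);
  std::vector<arma::vec> L(ntree);
  std::vector<arma::mat> T(ntree);
  for (int i = 0; i < ntree; ++i) {
    E[i] = as<arma::imat>(edges[i]);
    L[i] = as<arma::vec>(els[i]);
    T[i] = as<arma::mat>(tipps[i]);
  }
  ChainState st;
  st.m = R::runif(0.0, hyper_upper);
  st.rates.set_size(ngroups);
  for (int g = 0; g < ngroups; ++g) st.rates(g) = R::rexp(st.m);
  int tr = 0;
  {
    TransProb tp(build_Q(map, st.rates));
    st.logL = loglik_core(E[tr], L[tr], ntips[tr], nnodes[tr], T[tr], tp,
                          rootfreq);
    int tries = 0;
    while (!std::isfinite(st.logL) && tries++ < 200) {
      for (int g = 0; g < ngroups; ++g) st.rates(g) = R::rexp(st.m);
      TransProb tp2(build_Q(map, st.rates));
      st.logL = loglik_core(E[tr], L[tr], ntips[tr], nnodes[tr], T[tr], tp2,
                            rootfreq);
    }
  }
  const int nsamp = (iterations - burn_in) / thin;
  arma::mat out(nsamp, ngroups + 3);
  int row = 0;
  long tree_prop = 0, tree_acc = 0;
  for (int it = 1; it <= iterations; ++it) {
    sweep(st, 1.0, prop_sd, hyper_upper, E[tr], L[tr], ntips[tr], nnodes[tr],
          T[tr], map, rootfreq);
    if (ntree > 1) {
      int tr_new = (int)std::floor(R::runif(0.0, 1.0) * ntree);
      if (tr_new >= ntree) tr_new = ntree - 1;
      if (tr_new != tr) {
        TransProb tp(build_Q(map, st.rates));
        double l_new = loglik_core(E[tr_new], L[tr_new], ntips[tr_new],
                                   nnodes[tr_new], T[tr_new], tp, rootfreq);
        tree_prop++;
        if (std::isfinite(l_new) &&
            std::log(R::runif(0.0, 1.0)) < (l_new - st.logL)) {
          tr = tr_new; st.logL = l_new; tree_acc++;
        }
      }
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && row < nsamp) {
      for (int g = 0; g < ngroups; ++g) out(row, g) = st.rates(g);
      out(row, ngroups) = st.m;
      out(row, ngroups + 1) = st.logL;
      out(row, ngroups + 2) = tr;   // 0-based tree index
      row++;
    }
  }
  return List::create(
    _["samples"] = out,
    _["acceptance_rate"] = (double)st.n_acc / std::max(1L, st.n_prop),
    _["tree_acceptance_rate"] =
      tree_prop > 0 ? (double)tree_acc / tree_prop : NA_REAL);
}
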