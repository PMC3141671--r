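// Felsenstein pruning and branch-length optimization for amino-acid models.
//
// Trees arrive as an ape-style postorder edge matrix over node indices
// (tips 1..ntip, internals above).  The substitution model arrives as the
// spectral decomposition Q = U diag(lambda) Uinv with stationary
// frequencies pi, plus discrete rate-category multipliers and an optional
// invariant-sites proportion.  Partial likelihoods are not rescaled; this
// is intended for the small trees (<= ~20 tips) used in constrained
// placement analysis, where per-site likelihoods stay far above the
// double-precision underflow threshold.

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct TreeLik {
  int ntip, nnode, root;
  std::vector<std::vector<int>> children;  // per node (0-based)
  std::vector<int> parent;
  std::vector<int> postorder_nodes;        // internal nodes in postorder
  vec el;                                  // branch length, indexed by child
  mat U, Uinv;
  vec lambda, pi;
  vec rates;                               // category rate multipliers
  double pinv;
  int K, npat;
  mat tippart;                             // 20 x (npat*ntip) tip partials
  vec patw;                                // pattern weights
  vec invconst;                            // pinv * pi[state] for constant patterns
  std::vector<cube> down;                  // per node: 20 x npat x K

  mat pmat(double t, int k) const {
    return U * diagmat(exp(lambda * (t * rates[k]))) * Uinv;
  }

  mat tip(int node) const {
    return tippart.cols(node * npat, (node + 1) * npat - 1);
  }

  void compute_down(int node) {
    cube& D = down[node];
    for (int k = 0; k < K; ++k) {
      mat acc(20, npat, fill::ones);
      for (int c : children[node]) {
        if (c < ntip) acc %= pmat(el[c], k) * tip(c);
        else          acc %= pmat(el[c], k) * down[c].slice(k);
      }
      D.slice(k) = acc;
    }
  }

  void full_postorder() {
    for (int node : postorder_nodes) compute_down(node);
  }

  // per-pattern log-likelihood from root partials
  vec pattern_loglik() {
    mat L(npat, K);
    for (int k = 0; k < K; ++k)
      L.col(k) = (down[root].slice(k).t() * pi);
    vec mix = sum(L, 1) * ((1.0 - pinv) / K) + invconst;
    mix.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
    return log(mix);
  }

  double total_loglik() { return dot(pattern_loglik(), patw); }
};

TreeLik build(const Rcpp::IntegerMatrix& edge, int ntip, int nnode,
              const Rcpp::NumericVector& el,
              const Rcpp::IntegerMatrix& tipstate,
              const Rcpp::NumericVector& patw,
              const Rcpp::NumericMatrix& U, const Rcpp::NumericMatrix& Uinv,
              const Rcpp::NumericVector& lambda, const Rcpp::NumericVector& pi,
              const Rcpp::NumericVector& rates, double pinv) {
  TreeLik T;
  T.ntip = ntip;
  T.nnode = nnode;
  T.pinv = pinv;
  T.K = rates.size();
  T.npat = tipstate.ncol();
  T.U = mat(U.begin(), 20, 20);
  T.Uinv = mat(Uinv.begin(), 20, 20);
  T.lambda = vec(lambda.begin(), 20);
  T.pi = vec(pi.begin(), 20);
  T.rates = vec(rates.begin(), T.K);
  T.el = vec(el.begin(), el.size());
  T.patw = vec(patw.begin(), T.npat);
  T.children.assign(nnode, {});
  T.parent.assign(nnode, -1);

  std::vector<bool> ischild(nnode, false);
  for (int e = 0; e < edge.nrow(); ++e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    T.children[p].push_back(c);
    T.parent[c] = p;
    ischild[c] = true;
  }
  T.root = -1;
  for (int i = ntip; i < nnode; ++i)
    if (!ischild[i]) T.root = i;
  std::function<void(int)> rec = [&](int node) {
    for (int c : T.children[node])
      if (c >= ntip) rec(c);
    T.postorder_nodes.push_back(node);
  };
  rec(T.root);

  // tip partials: indicator columns, ones for missing (-1)
  T.tippart.zeros(20, T.npat * ntip);
  for (int i = 0; i < ntip; ++i) {
    for (int s = 0; s < T.npat; ++s) {
      int st = tipstate(i, s);
      if (st < 0)
        T.tippart.col(i * T.npat + s).ones();
      else
        T.tippart(st, i * T.npat + s) = 1.0;
    }
  }
  // invariant-class constants: pinv * pi[state] when all observed tip
  // states agree (all-missing pattern -> pinv * 1)
  T.invconst.zeros(T.npat);
  if (pinv > 0) {
    for (int s = 0; s < T.npat; ++s) {
      int st = -1;
      bool constant = true;
      for (int i = 0; i < ntip && constant; ++i) {
        int x = tipstate(i, s);
        if (x < 0) continue;
        if (st < 0) st = x;
        else if (x != st) constant = false;
      }
      if (constant) T.invconst[s] = pinv * (st < 0 ? 1.0 : T.pi[st]);
    }
  }
  T.down.assign(nnode, cube());
  for (int node : T.postorder_nodes) T.down[node].set_size(20, T.npat, T.K);
  T.full_postorder();
  return T;
}

// Edge-specific likelihood via the spectral ("H") representation:
// L_s(t) = sum_k w_k sum_j H_k(s,j) exp(lambda_j r_k t) + invconst_s
struct EdgeObjective {
  const TreeLik& T;
  std::vector<mat> H;     // per category: npat x 20
  double wcat;

  EdgeObjective(const TreeLik& T_, const std::vector<mat>& up, int child)
      : T(T_) {
    H.resize(T.K);
    for (int k = 0; k < T.K; ++k) {
      mat A = T.U.t() * up[k];                       // 20 x npat
      mat B = T.Uinv * ((child < T.ntip) ? T.tip(child)
                                          : T.down[child].slice(k));
      H[k] = (A % B).t();                            // npat x 20
    }
    wcat = (1.0 - T.pinv) / T.K;
  }

  double loglik(double t) const {
    vec mix(T.npat, fill::zeros);
    for (int k = 0; k < T.K; ++k)
      mix += H[k] * exp(T.lambda * (t * T.rates[k]));
    mix = mix * wcat + T.invconst;
    mix.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
    return dot(log(mix), T.patw);
  }
};

// bounded Brent maximization of f over [lo, hi]
template <typename F>
double brent_max(F f, double lo, double hi, double tol, double* fbest) {
  const double gold = 0.3819660112501051;
  double a = lo, b = hi;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (!(std::fabs(p) >= std::fabs(0.5 * q * etemp) || p <= q * (a - x) ||
            p >= q * (b - x))) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu >= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw;
      w = x; fw = fx;
      x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || w == x) {
        v = w; fv = fw;
        w = u; fw = fu;
      } else if (fu >= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  *fbest = fx;
  return x;
}

const double BL_MIN = 1e-8, BL_MAX = 20.0;

// one optimization sweep: DFS from the root, optimizing each branch with
// current up/down partials, then refreshing down partials on the way up
void sweep_node(TreeLik& T, int node, std::vector<mat>& up) {
  // optimize branch above `node` given up (for that branch) and down[node]
  EdgeObjective obj(T, up, node);
  double fbest;
  double t = brent_max([&](double x) { return obj.loglik(x); },
                       BL_MIN, BL_MAX, 1e-6, &fbest);
  T.el[node] = t;
  if (node < T.ntip) return;
  int n_ch = T.children[node].size();
  for (int ci = 0; ci < n_ch; ++ci) {
    int c = T.children[node][ci];
    std::vector<mat> upc(T.K);
    for (int k = 0; k < T.K; ++k) {
      mat through = T.pmat(T.el[node], k).t() * up[k];   // 20 x npat
      for (int cj = 0; cj < n_ch; ++cj) {
        if (cj == ci) continue;
        int sib = T.children[node][cj];
        const mat& Ds = (sib < T.ntip) ? T.tip(sib) : T.down[sib].slice(k);
        through %= T.pmat(T.el[sib], k) * Ds;
      }
      upc[k] = through;
    }
    sweep_node(T, c, upc);
  }
  T.compute_down(node);
}

void sweep(TreeLik& T) {
  int n_ch = T.children[T.root].size();
  for (int ci = 0; ci < n_ch; ++ci) {
    int c = T.children[T.root][ci];
    std::vector<mat> upc(T.K);
    for (int k = 0; k < T.K; ++k) {
      mat through = repmat(T.pi, 1, T.npat);             // 20 x npat
      for (int cj = 0; cj < n_ch; ++cj) {
        if (cj == ci) continue;
        int sib = T.children[T.root][cj];
        const mat& Ds = (sib < T.ntip) ? T.tip(sib) : T.down[sib].slice(k);
        through %= T.pmat(T.el[sib], k) * Ds;
      }
      upc[k] = through;
    }
    sweep_node(T, c, upc);
  }
  T.compute_down(T.root);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List site_loglik_cpp(Rcpp::IntegerMatrix edge, int ntip, int nnode,
                           Rcpp::NumericVector el,
                           Rcpp::IntegerMatrix tipstate,
                           Rcpp::NumericVector patw,
                           Rcpp::NumericMatrix U, Rcpp::NumericMatrix Uinv,
                           Rcpp::NumericVector lambda, Rcpp::NumericVector pi,
                           Rcpp::NumericVector rates, double pinv) {
  TreeLik T = build(edge, ntip, nnode, el, tipstate, patw, U, Uinv, lambda,
                    pi, rates, pinv);
  vec pl = T.pattern_loglik();
  return Rcpp::List::create(
      Rcpp::Named("pattern_loglik") = Rcpp::NumericVector(pl.begin(), pl.end()),
      Rcpp::Named("loglik") = dot(pl, T.patw));
}

// [[Rcpp::export]]
Rcpp::List optimize_bl_cpp(Rcpp::IntegerMatrix edge, int ntip, int nnode,
                           Rcpp::NumericVector el,
                           Rcpp::IntegerMatrix tipstate,
                           Rcpp::NumericVector patw,
                           Rcpp::NumericMatrix U, Rcpp::NumericMatrix Uinv,
                           Rcpp::NumericVector lambda, Rcpp::NumericVector pi,
                           Rcpp::NumericVector rates, double pinv,
                           double tol, int max_sweeps) {
  TreeLik T = build(edge, ntip, nnode, el, tipstate, patw, U, Uinv, lambda,
                    pi, rates, pinv);
  double ll = T.total_loglik();
  int it = 0;
  bool converged = false;
  for (; it < max_sweeps; ++it) {
    sweep(T);
    double llnew = T.total_loglik();
    if (llnew < ll - 1e-6) {
      // a sweep should never decrease the likelihood beyond noise
      llnew = std::max(llnew, ll);
    }
    if (llnew - ll < tol) {
      ll = std::max(ll, llnew);
      converged = true;
      ++it;
      break;
    }
    ll = llnew;
  }
  vec pl = T.pattern_loglik();
  return Rcpp::List::create(
      Rcpp::Named("el") = Rcpp::NumericVector(T.el.begin(), T.el.end()),
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("pattern_loglik") = Rcpp::NumericVector(pl.begin(), pl.end()),
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged);
}
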