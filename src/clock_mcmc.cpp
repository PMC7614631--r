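#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Poisson log-likelihood term for one branch (factorial dropped).
static inline double edge_ll(double c, double d, double r) {
  if (d <= 0.0) return R_NegInf;
  return c * std::log(r * d) - r * d;
}

// Metropolis-Hastings sampler for a strict molecular clock on a fixed
// rooted topology: unknowns are the mutation rate r and the free (internal)
// node dates; the likelihood is a product over branches of
// Poisson(count | r * duration). Priors: r uniform on (0, r_max), node dates
// uniform subject to parent <= child (root bounded below by root_lb).
// parent is 0-based with -1 at the root; count[v] is the mutation count on
// the edge above v. Returns kept samples as rows: r, then all node dates.
// [[Rcpp::export]]
NumericMatrix clock_mcmc_cpp(IntegerVector parent, NumericVector count,
                             NumericVector date, LogicalVector free_node,
                             double r_init, double r_max, double root_lb,
                             int n_iter, int burn_in, int thin,
                             double r_step, double t_step) {
  const int n = parent.size();
  std::vector<std::vector<int> > children(n);
  int root = -1;
  for (int v = 0; v < n; ++v) {
    if (parent[v] < 0) root = v;
    else children[parent[v]].push_back(v);
  }
  NumericVector t = clone(date);
  double r = r_init;
  double S_c = 0.0, S_d = 0.0;
  for (int v = 0; v < n; ++v) {
    if (v == root) continue;
    S_c += count[v];
    S_d += t[v] - t[parent[v]];
  }
  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  NumericMatrix out(n_keep, n + 1);
  int row = 0;
  for (int it = 0; it < n_iter; ++it) {
    // multiplicative random-walk update of the rate
    double rp = r * std::exp(r_step * (unif_rand() * 2.0 - 1.0));
    if (rp > 0.0 && rp < r_max) {
      double dll = S_c * (std::log(rp) - std::log(r)) - (rp - r) * S_d;
      double la = dll + std::log(rp) - std::log(r);  // log-scale proposal Jacobian
      if (la >= 0.0 || unif_rand() < std::exp(la)) r = rp;
    }
    // single-site date updates
    for (int v = 0; v < n; ++v) {
      if (!free_node[v]) continue;
      double lo = (v == root) ? root_lb : t[parent[v]];
      double hi = R_PosInf;
      for (size_t k = 0; k < children[v].size(); ++k)
        hi = std::min(hi, t[children[v][k]]);
      double tp = t[v] + t_step * (unif_rand() * 2.0 - 1.0);
      if (tp <= lo || tp >= hi) continue;  // outside prior support
      double dll = 0.0;
      if (v != root)
        dll += edge_ll(count[v], tp - t[parent[v]], r)
             - edge_ll(count[v], t[v] - t[parent[v]], r);
      for (size_t k = 0; k < children[v].size(); ++k) {
        int c = children[v][k];
        dll += edge_ll(count[c], t[c] - tp, r)
             - edge_ll(count[c], t[c] - t[v], r);
      }
      if (dll >= 0.0 || unif_rand() < std::exp(dll)) {
        double delta = tp - t[v];
        S_d += (v == root ? 0.0 : delta) - (double)children[v].size() * delta;
        t[v] = tp;
      }
    }
    if (it >= burn_in && (it - burn_in) % thin == 0 && row < n_keep) {
      out(row, 0) = r;
      for (int v = 0; v < n; ++v) out(row, v + 1) = t[v];
      ++row;
    }
  }
  return out;
}
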