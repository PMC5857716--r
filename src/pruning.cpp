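// Felsenstein pruning for the K=20 equal-rate (Poisson) amino-acid model.
//
// The equal-exchangeability model admits a closed-form transition kernel:
// along a branch of expected length d (substitutions/site),
//   P(same)      = 1/20 + (19/20) exp(-(20/19) d)
//   P(any other) = 1/20 - (1/20)  exp(-(20/19) d)
// so a child's message to its parent collapses to
//   msg[s] = pd * sum(L) + E * L[s],  E = exp(-(20/19) d).
// This keeps the per-branch cost linear in states x patterns.
//
// The persistent Pruner object caches per-node conditional likelihoods so
// an MCMC proposal that touches one node only recomputes the path to the
// root; rejected proposals never corrupt the cached state (proposals are
// written to a shadow buffer and copied in only on acceptance).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Pruner {
  int ntip;
  int nnode;  // total nodes = 2*ntip - 1
  int npat;
  int ncat;
  int root;                            // 0-based id of the root
  std::vector<int> states;             // npat x ntip, 0 = missing, 1..20
  std::vector<double> weights;         // pattern weights
  std::vector<int> postorder;          // internal nodes, children first
  std::vector<std::vector<int>> kids;  // children (0-based) per node
  std::vector<double> cur;             // cached partials
  std::vector<double> prop;            // shadow buffer for proposals
  std::vector<int> last_dirty;

  std::size_t block(int cat, int node) const {
    return (static_cast<std::size_t>(cat) * nnode + node) * 20 * npat;
  }
};

// Partials are stored pattern-major: entry (pattern p, state s) lives at
// p * 20 + s, so the 20-state inner loops run over contiguous memory.

// Multiply a tip's message into the parent partial P.
void mult_tip_message(double* P, const int* tipstates, int npat, double pd,
                      double E) {
  for (int p = 0; p < npat; ++p) {
    int s0 = tipstates[p];
    if (s0 == 0) continue;  // missing: message is all ones
    double* col = P + p * 20;
    double hit = col[s0 - 1];
    for (int s = 0; s < 20; ++s) col[s] *= pd;
    col[s0 - 1] = hit * (pd + E);
  }
}

// Multiply an internal child's message into the parent partial.
void mult_internal_message(double* P, const double* L, int npat, double pd,
                           double E) {
  for (int p = 0; p < npat; ++p) {
    const double* Lp = L + p * 20;
    double* Pp = P + p * 20;
    double tot = 0.0;
    for (int s = 0; s < 20; ++s) tot += Lp[s];
    double base = pd * tot;
    for (int s = 0; s < 20; ++s) Pp[s] *= base + E * Lp[s];
  }
}

// Recompute the partial of `node` for category `cat` into `out`, reading
// child partials from `prop` when the child is flagged dirty, else `cur`.
void compute_node(Pruner& pr, int cat, int node, double rate,
                  const double* elen, const std::vector<char>& dirty,
                  bool use_prop) {
  double* out = (use_prop ? pr.prop.data() : pr.cur.data()) +
                pr.block(cat, node);
  std::fill(out, out + 20 * pr.npat, 1.0);
  for (int c : pr.kids[node]) {
    double d = elen[c] * rate;
    double E = std::exp(-(20.0 / 19.0) * d);
    double pd = (1.0 - E) / 20.0;
    if (c < pr.ntip) {
      mult_tip_message(out, pr.states.data() + static_cast<std::size_t>(c) *
                                                   pr.npat,
                       pr.npat, pd, E);
    } else {
      const double* L = (dirty[c] ? pr.prop.data() : pr.cur.data()) +
                        pr.block(cat, c);
      mult_internal_message(out, L, pr.npat, pd, E);
    }
  }
}

double root_loglik(const Pruner& pr, bool use_prop) {
  const double* buf = use_prop ? pr.prop.data() : pr.cur.data();
  double ll = 0.0;
  for (int p = 0; p < pr.npat; ++p) {
    double site = 0.0;
    for (int cat = 0; cat < pr.ncat; ++cat) {
      const double* L = buf + pr.block(cat, pr.root) + p * 20;
      double tot = 0.0;
      for (int s = 0; s < 20; ++s) tot += L[s];
      site += tot / 20.0;
    }
    site /= pr.ncat;
    if (site <= 0.0) return R_NegInf;
    ll += pr.weights[p] * std::log(site);
  }
  return ll;
}

}  // namespace

// [[Rcpp::export]]
SEXP pruner_create(IntegerMatrix states, NumericVector weights,
                   List children, int ntip, IntegerVector postorder,
                   int ncat) {
  Pruner* pr = new Pruner();
  pr->ntip = ntip;
  pr->nnode = children.size();
  pr->npat = states.nrow();
  pr->ncat = ncat;
  pr->states.assign(states.begin(), states.end());
  pr->weights.assign(weights.begin(), weights.end());
  pr->postorder.assign(postorder.begin(), postorder.end());
  pr->root = pr->postorder.back();
  pr->kids.resize(pr->nnode);
  for (int i = 0; i < pr->nnode; ++i) {
    IntegerVector k = children[i];
    pr->kids[i].assign(k.begin(), k.end());
  }
  std::size_t sz =
      static_cast<std::size_t>(ncat) * pr->nnode * 20 * pr->npat;
  pr->cur.assign(sz, 0.0);
  pr->prop.assign(sz, 0.0);
  XPtr<Pruner> ptr(pr, true);
  return ptr;
}

// [[Rcpp::export]]
double pruner_full(SEXP xp, NumericVector edge_len, NumericVector cat_rates) {
  XPtr<Pruner> pr(xp);
  std::vector<char> dirty(pr->nnode, 0);
  for (int cat = 0; cat < pr->ncat; ++cat) {
    for (int node : pr->postorder) {
      compute_node(*pr, cat, node, cat_rates[cat], edge_len.begin(), dirty,
                   false);
    }
  }
  pr->last_dirty.clear();
  return root_loglik(*pr, false);
}

// [[Rcpp::export]]
double pruner_propose(SEXP xp, NumericVector edge_len, NumericVector cat_rates,
                      IntegerVector dirty_nodes) {
  XPtr<Pruner> pr(xp);
  std::vector<char> dirty(pr->nnode, 0);
  for (int i = 0; i < dirty_nodes.size(); ++i) dirty[dirty_nodes[i]] = 1;
  for (int cat = 0; cat < pr->ncat; ++cat) {
    for (int node : pr->postorder) {
      if (!dirty[node]) continue;
      compute_node(*pr, cat, node, cat_rates[cat], edge_len.begin(), dirty,
                   true);
    }
  }
  pr->last_dirty.assign(dirty_nodes.begin(), dirty_nodes.end());
  return root_loglik(*pr, true);
}

// [[Rcpp::export]]
void pruner_accept(SEXP xp) {
  XPtr<Pruner> pr(xp);
  std::size_t blk = static_cast<std::size_t>(20) * pr->npat;
  for (int node : pr->last_dirty) {
    for (int cat = 0; cat < pr->ncat; ++cat) {
      std::size_t off = pr->block(cat, node);
      std::copy(pr->prop.begin() + off, pr->prop.begin() + off + blk,
                pr->cur.begin() + off);
    }
  }
  pr->last_dirty.clear();
}

// One-shot likelihood without a persistent cache (library API).
// [[Rcpp::export]]
double poisson_pruning_loglik(IntegerMatrix states, NumericVector weights,
                              List children, int ntip,
                              IntegerVector postorder, NumericVector edge_len,
                              NumericVector cat_rates) {
  SEXP xp = pruner_create(states, weights, children, ntip, postorder,
                          cat_rates.size());
  XPtr<Pruner> pr(xp);
  double ll = pruner_full(xp, edge_len, cat_rates);
  return ll;
}
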