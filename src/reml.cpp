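#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Restricted maximum likelihood for Brownian motion on a tree, computed by
// Felsenstein-style pruning.  The tree is an edge list (parent, child) with
// arbitrary positive node ids; tip nodes are mapped to rows of the data
// matrix X through tip_row (1-based, 0 for internal nodes).  p is the
// effective number of characters entering the log-determinant term: when X
// is the full tips-by-characters matrix, p == ncol(X); when X is a reduced
// n-by-n square root of the scatter matrix X X', p stays the original
// character count while the quadratic term is unchanged.

static const double LOG2PI = 1.8378770664093454836;
static const double LEN_EPS = 1e-8;

struct PruneWork {
  std::vector< std::vector<int> > kids;      // child edge indices per node
  std::vector<int> parent_edge;              // edge index pointing to node
  std::vector<int> postorder;                // node ids, children first
  int root;
  int nnode;
};

static void build_work(const IntegerMatrix &edge, int nnode, PruneWork &w) {
  w.nnode = nnode;
  w.kids.assign(nnode + 1, std::vector<int>());
  w.parent_edge.assign(nnode + 1, -1);
  std::vector<char> is_child(nnode + 1, 0);
  for (int e = 0; e < edge.nrow(); ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    w.kids[par].push_back(e);
    w.parent_edge[ch] = e;
    is_child[ch] = 1;
  }
  w.root = -1;
  for (int v = 1; v <= nnode; ++v)
    if ((!w.kids[v].empty()) && !is_child[v]) { w.root = v; break; }
  if (w.root < 0) stop("tree has no root node (cyclic edge list?)");
  // iterative postorder
  w.postorder.clear();
  std::vector<int> stack;
  stack.push_back(w.root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    w.postorder.push_back(v);
    for (size_t i = 0; i < w.kids[v].size(); ++i)
      stack.push_back(edge(w.kids[v][i], 1));
  }
  std::reverse(w.postorder.begin(), w.postorder.end());
}

// core pruning pass; val is nnode+1 rows by r columns workspace
static double prune_loglik(const IntegerMatrix &edge,
                           const NumericVector &elen,
                           const NumericMatrix &X,
                           const IntegerVector &tip_row,
                           double p, PruneWork &w,
                           std::vector< std::vector<double> > &val,
                           std::vector<double> &extra) {
  const int r = X.ncol();
  double ll = 0.0;
  for (size_t ii = 0; ii < w.postorder.size(); ++ii) {
    int v = w.postorder[ii];
    if (w.kids[v].empty()) {               // tip
      int row = tip_row[v - 1];
      if (row <= 0) stop("tip node %d has no data row", v);
      std::vector<double> &xv = val[v];
      xv.resize(r);
      for (int j = 0; j < r; ++j) xv[j] = X(row - 1, j);
      extra[v] = 0.0;
      continue;
    }
    // fold children sequentially: each combination yields one contrast
    int c0 = edge(w.kids[v][0], 1);
    std::vector<double> cur = val[c0];
    double lc0 = elen[w.kids[v][0]];
    double vcur = (lc0 > LEN_EPS ? lc0 : LEN_EPS) + extra[c0];
    for (size_t i = 1; i < w.kids[v].size(); ++i) {
      int ci = edge(w.kids[v][i], 1);
      double li = elen[w.kids[v][i]];
      double vi = (li > LEN_EPS ? li : LEN_EPS) + extra[ci];
      const std::vector<double> &xi = val[ci];
      double vv = vcur + vi;
      double ss = 0.0;
      double wa = vi / vv, wb = vcur / vv;
      for (int j = 0; j < r; ++j) {
        double u = cur[j] - xi[j];
        ss += u * u;
        cur[j] = wa * cur[j] + wb * xi[j];
      }
      ll += -0.5 * p * (LOG2PI + std::log(vv)) - 0.5 * ss / vv;
      vcur = vcur * vi / vv;
    }
    val[v] = cur;
    extra[v] = vcur;
  }
  return ll;
}

// [[Rcpp::export(name = ".reml_loglik_cpp")]]
double reml_loglik_cpp(IntegerMatrix edge, NumericVector elen,
                       NumericMatrix X, IntegerVector tip_row, double p) {
  int nnode = 0;
  for (int e = 0; e < edge.nrow(); ++e) {
    nnode = std::max(nnode, edge(e, 0));
    nnode = std::max(nnode, edge(e, 1));
  }
  if ((int)tip_row.size() < nnode)
    stop("tip_row must have one entry per node");
  PruneWork w;
  build_work(edge, nnode, w);
  std::vector< std::vector<double> > val(nnode + 1);
  std::vector<double> extra(nnode + 1, 0.0);
  return prune_loglik(edge, elen, X, tip_row, p, w, val, extra);
}

// Coordinate-ascent branch length optimization: golden-section search on
// each edge in turn, sweeping until the log-likelihood gain drops below
// tol.  Lengths are constrained to [0, inf); evaluation floors them at
// LEN_EPS so contrast variances stay positive.

static double eval_edge(int j, double t, NumericVector &elen,
                        const IntegerMatrix &edge, const NumericMatrix &X,
                        const IntegerVector &tip_row, double p, PruneWork &w,
                        std::vector< std::vector<double> > &val,
                        std::vector<double> &extra) {
  double old = elen[j];
  elen[j] = t;
  double ll = prune_loglik(edge, elen, X, tip_row, p, w, val, extra);
  elen[j] = old;
  return ll;
}

// [[Rcpp::export(name = ".optimize_bl_cpp")]]
List optimize_bl_cpp(IntegerMatrix edge, NumericVector elen_in,
                     NumericMatrix X, IntegerVector tip_row, double p,
                     double tol = 1e-6, int max_sweeps = 1000,
                     int golden_iter = 40) {
  NumericVector elen = clone(elen_in);
  int nnode = 0;
  for (int e = 0; e < edge.nrow(); ++e) {
    nnode = std::max(nnode, edge(e, 0));
    nnode = std::max(nnode, edge(e, 1));
  }
  PruneWork w;
  build_work(edge, nnode, w);
  std::vector< std::vector<double> > val(nnode + 1);
  std::vector<double> extra(nnode + 1, 0.0);

  const double gr = 0.61803398874989484820;
  double ll = prune_loglik(edge, elen, X, tip_row, p, w, val, extra);
  int sweeps = 0;
  for (; sweeps < max_sweeps; ++sweeps) {
    double ll_start = ll;
    for (int j = 0; j < edge.nrow(); ++j) {
      double t0 = elen[j];
      double hi = std::max(4.0 * t0, 0.1);
      // expand upper bracket while the likelihood keeps increasing
      double f_hi = eval_edge(j, hi, elen, edge, X, tip_row, p, w, val, extra);
      for (int k = 0; k < 30; ++k) {
        double f_hi2 = eval_edge(j, 2.0 * hi, elen, edge, X, tip_row, p,
                                 w, val, extra);
        if (f_hi2 <= f_hi) break;
        hi *= 2.0; f_hi = f_hi2;
      }
      double a = 0.0, b = hi;
      double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
      double f1 = eval_edge(j, x1, elen, edge, X, tip_row, p, w, val, extra);
      double f2 = eval_edge(j, x2, elen, edge, X, tip_row, p, w, val, extra);
      for (int k = 0; k < golden_iter; ++k) {
        if (f1 >= f2) {
          b = x2; x2 = x1; f2 = f1;
          x1 = b - gr * (b - a);
          f1 = eval_edge(j, x1, elen, edge, X, tip_row, p, w, val, extra);
        } else {
          a = x1; x1 = x2; f1 = f2;
          x2 = a + gr * (b - a);
          f2 = eval_edge(j, x2, elen, edge, X, tip_row, p, w, val, extra);
        }
        if (b - a < 1e-10) break;
      }
      double tbest = (f1 >= f2) ? x1 : x2;
      double fbest = (f1 >= f2) ? f1 : f2;
      // never accept a move that loses likelihood (golden search on a
      // possibly non-unimodal slice)
      if (fbest > ll) { elen[j] = tbest; ll = fbest; }
    }
    if (ll - ll_start < tol) { ++sweeps; break; }
  }
  return List::create(_["edge_length"] = elen, _["loglik"] = ll,
                      _["sweeps"] = sweeps);
}
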