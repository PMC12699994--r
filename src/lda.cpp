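#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Batch variational-Bayes estimation for latent Dirichlet allocation
// (Blei, Ng & Jordan 2003).  Documents are bags of word ids with counts;
// the variational posterior factorizes into per-document Dirichlet
// parameters gamma (topics) and a topic-word Dirichlet lambda.  All
// randomness (the lambda initialization) is drawn from R's RNG so that
// set.seed() on the R side makes the fit reproducible.

// [[Rcpp::export(name = ".lda_vb_cpp")]]
List lda_vb_cpp(List doc_ids, List doc_counts, int V, int M,
                double alpha, double eta, int passes = 50,
                int inner_iter = 100, double gamma_tol = 1e-3,
                double bound_tol = 1e-4) {
  const int D = doc_ids.size();
  if (doc_counts.size() != D) stop("doc_ids and doc_counts differ in length");

  // lambda: M x V variational Dirichlet for topic-word distributions
  std::vector<double> lambda((size_t)M * V);
  {
    RNGScope scope;
    for (size_t i = 0; i < lambda.size(); ++i)
      lambda[i] = R::rgamma(100.0, 0.01);
  }
  std::vector<double> Elogbeta((size_t)M * V);
  std::vector<double> expElogbeta((size_t)M * V);
  std::vector<double> gamma_((size_t)D * M);
  std::vector<double> doc_tot(D, 0.0);

  std::vector< std::vector<int> > ids(D);
  std::vector< std::vector<double> > cts(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector id = doc_ids[d];
    NumericVector ct = doc_counts[d];
    if (id.size() != ct.size()) stop("ids/counts mismatch in document %d", d + 1);
    ids[d].assign(id.begin(), id.end());
    cts[d].assign(ct.begin(), ct.end());
    for (size_t i = 0; i < cts[d].size(); ++i) doc_tot[d] += cts[d][i];
    for (int m = 0; m < M; ++m)
      gamma_[(size_t)d * M + m] = alpha + doc_tot[d] / M;
  }

  auto update_Elogbeta = [&]() {
    for (int m = 0; m < M; ++m) {
      double s = 0.0;
      for (int v = 0; v < V; ++v) s += lambda[(size_t)m * V + v];
      double dgs = R::digamma(s);
      for (int v = 0; v < V; ++v) {
        double e = R::digamma(lambda[(size_t)m * V + v]) - dgs;
        Elogbeta[(size_t)m * V + v] = e;
        expElogbeta[(size_t)m * V + v] = std::exp(e);
      }
    }
  };
  update_Elogbeta();

  std::vector<double> sstats((size_t)M * V);
  std::vector<double> Elogth(M), gnew(M), expE(M);
  double bound = R_NegInf;
  int pass = 0;

  for (pass = 0; pass < passes; ++pass) {
    std::fill(sstats.begin(), sstats.end(), 0.0);
    double corpus_ll = 0.0;   // E_q[log p(w|z,beta)] - style token term

    for (int d = 0; d < D; ++d) {
      const std::vector<int> &id = ids[d];
      const std::vector<double> &ct = cts[d];
      const int nd = (int)id.size();
      double *g = &gamma_[(size_t)d * M];
      if (nd == 0) { for (int m = 0; m < M; ++m) g[m] = alpha; continue; }

      for (int it = 0; it < inner_iter; ++it) {
        double gs = 0.0;
        for (int m = 0; m < M; ++m) gs += g[m];
        double dgs = R::digamma(gs);
        for (int m = 0; m < M; ++m) {
          Elogth[m] = R::digamma(g[m]) - dgs;
          gnew[m] = alpha;
          expE[m] = std::exp(Elogth[m]);
        }
        for (int i = 0; i < nd; ++i) {
          const double *eb = &expElogbeta[0] + id[i];
          double norm = 0.0;
          for (int m = 0; m < M; ++m)
            norm += expE[m] * eb[(size_t)m * V];
          double c = ct[i] / (norm > 0 ? norm : 1e-300);
          for (int m = 0; m < M; ++m)
            gnew[m] += c * expE[m] * eb[(size_t)m * V];
        }
        double change = 0.0;
        for (int m = 0; m < M; ++m) {
          change += std::fabs(gnew[m] - g[m]);
          g[m] = gnew[m];
        }
        if (change / M < gamma_tol) break;
      }
      // accumulate sufficient statistics with converged phi
      double gs = 0.0;
      for (int m = 0; m < M; ++m) gs += g[m];
      double dgs = R::digamma(gs);
      for (int m = 0; m < M; ++m)
        expE[m] = std::exp(R::digamma(g[m]) - dgs);
      for (int i = 0; i < nd; ++i) {
        const double *eb = &expElogbeta[0] + id[i];
        double norm = 0.0;
        for (int m = 0; m < M; ++m)
          norm += expE[m] * eb[(size_t)m * V];
        corpus_ll += ct[i] * std::log(norm > 0 ? norm : 1e-300);
        double c = ct[i] / (norm > 0 ? norm : 1e-300);
        for (int m = 0; m < M; ++m)
          sstats[(size_t)m * V + id[i]] += c * expE[m] * eb[(size_t)m * V];
      }
    }

    for (size_t i = 0; i < lambda.size(); ++i) lambda[i] = eta + sstats[i];
    update_Elogbeta();

    // evidence lower bound (up to the constant token term already in
    // corpus_ll, evaluated with pre-update Elogbeta; adequate for
    // convergence monitoring)
    double b = corpus_ll;
    for (int d = 0; d < D; ++d) {
      const double *g = &gamma_[(size_t)d * M];
      double gs = 0.0;
      for (int m = 0; m < M; ++m) gs += g[m];
      double dgs = R::digamma(gs);
      for (int m = 0; m < M; ++m) {
        double el = R::digamma(g[m]) - dgs;
        b += (alpha - g[m]) * el + R::lgammafn(g[m]);
      }
      b -= R::lgammafn(gs);
      b += R::lgammafn(M * alpha) - M * R::lgammafn(alpha);
    }
    for (int m = 0; m < M; ++m) {
      double ls = 0.0;
      for (int v = 0; v < V; ++v) ls += lambda[(size_t)m * V + v];
      double dls = R::digamma(ls);
      for (int v = 0; v < V; ++v) {
        double l = lambda[(size_t)m * V + v];
        b += (eta - l) * (R::digamma(l) - dls) + R::lgammafn(l);
      }
      b -= R::lgammafn(ls);
      b += R::lgammafn(V * eta) - V * R::lgammafn(eta);
    }
    double prev = bound;
    bound = b;
    if (pass > 0 && std::fabs(bound - prev) <
          bound_tol * (std::fabs(prev) + 1.0)) { ++pass; break; }
  }

  NumericMatrix theta(D, M), beta(M, V);
  for (int d = 0; d < D; ++d) {
    double s = 0.0;
    for (int m = 0; m < M; ++m) s += gamma_[(size_t)d * M + m];
    for (int m = 0; m < M; ++m) theta(d, m) = gamma_[(size_t)d * M + m] / s;
  }
  for (int m = 0; m < M; ++m) {
    double s = 0.0;
    for (int v = 0; v < V; ++v) s += lambda[(size_t)m * V + v];
    for (int v = 0; v < V; ++v) beta(m, v) = lambda[(size_t)m * V + v] / s;
  }
  return List::create(_["theta"] = theta, _["beta"] = beta,
                      _["bound"] = bound, _["passes"] = pass);
}
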