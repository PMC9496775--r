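#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA. Documents and words arrive flattened to
// one entry per token (0-based ids). theta and phi are integrated out; only
// token-topic assignments z are sampled, from
//   p(z_i = t | z_-i, w) ~ (n_dt + alpha) * (n_tw + eta) / (n_t + V * eta).
// Uses R's RNG so that set.seed() in the calling R code fixes the chain.
//
// Returns the final counts, final z, and (optionally) the z state after
// every sweep — used only for tiny exact-posterior cross-checks.
// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word, int n_docs,
                   int n_terms, int k, double alpha, double eta,
                   int n_iterations, bool record) {
  const int n_tokens = doc.size();
  IntegerVector z(n_tokens);
  IntegerMatrix n_dt(n_docs, k);   // doc-topic counts
  IntegerMatrix n_tw(k, n_terms);  // topic-word counts
  IntegerVector n_t(k);            // topic totals
  const double v_eta = n_terms * eta;

  // random initialization
  for (int i = 0; i < n_tokens; ++i) {
    int t = (int)(unif_rand() * k);
    if (t == k) t = k - 1;
    z[i] = t;
    n_dt(doc[i], t)++;
    n_tw(t, word[i])++;
    n_t[t]++;
  }

  IntegerMatrix z_trace;
  if (record) z_trace = IntegerMatrix(n_iterations, n_tokens);

  std::vector<double> p(k);
  for (int iter = 0; iter < n_iterations; ++iter) {
    for (int i = 0; i < n_tokens; ++i) {
      const int d = doc[i], w = word[i], old = z[i];
      n_dt(d, old)--; n_tw(old, w)--; n_t[old]--;
      double total = 0.0;
      for (int t = 0; t < k; ++t) {
        p[t] = (n_dt(d, t) + alpha) * (n_tw(t, w) + eta) / (n_t[t] + v_eta);
        total += p[t];
      }
      double u = unif_rand() * total;
      int t_new = 0;
      double cum = p[0];
      while (u > cum && t_new < k - 1) cum += p[++t_new];
      z[i] = t_new;
      n_dt(d, t_new)++; n_tw(t_new, w)++; n_t[t_new]++;
    }
    if (record) {
      for (int i = 0; i < n_tokens; ++i) z_trace(iter, i) = z[i];
    }
  }

  List out = List::create(_["z"] = z, _["n_dt"] = n_dt, _["n_tw"] = n_tw,
                          _["n_t"] = n_t);
  if (record) out["z_trace"] = z_trace;
  return out;
}
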