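#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampling for latent Dirichlet allocation.
//
// doc_id / word_id: 0-based token streams (one entry per token occurrence).
// Topic-word and document-topic counts are accumulated over the sampling
// iterations after burn-in to give Rao-Blackwellised estimates of beta and
// theta.  All randomness flows through R's RNG so set.seed() controls it.

static int sample_topic(const NumericVector &p, int k) {
  double u = R::unif_rand() * p[k - 1];
  for (int t = 0; t < k; ++t)
    if (u <= p[t]) return t;
  return k - 1;
}

// [[Rcpp::export]]
List lda_gibbs_fit(IntegerVector doc_id, IntegerVector word_id,
                   int n_docs, int n_words, int k,
                   double alpha, double eta,
                   int n_iter, int burnin) {
  int n_tokens = doc_id.size();
  IntegerVector z(n_tokens);
  IntegerMatrix ndk(n_docs, k), nkw(k, n_words);
  IntegerVector nk(k), nd(n_docs);
  NumericVector p(k);

  RNGScope scope;

  // random initial assignment
  for (int i = 0; i < n_tokens; ++i) {
    int t = (int)(R::unif_rand() * k);
    if (t == k) t = k - 1;
    z[i] = t;
    ndk(doc_id[i], t)++; nkw(t, word_id[i])++; nk[t]++; nd[doc_id[i]]++;
  }

  NumericMatrix theta_acc(n_docs, k);
  NumericMatrix beta_acc(k, n_words);
  int n_acc = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n_tokens; ++i) {
      int d = doc_id[i], w = word_id[i], t = z[i];
      ndk(d, t)--; nkw(t, w)--; nk[t]--;
      double cum = 0.0;
      for (int j = 0; j < k; ++j) {
        cum += (ndk(d, j) + alpha) *
               (nkw(j, w) + eta) / (nk[j] + n_words * eta);
        p[j] = cum;
      }
      t = sample_topic(p, k);
      z[i] = t;
      ndk(d, t)++; nkw(t, w)++; nk[t]++;
    }
    if (it >= burnin) {
      ++n_acc;
      for (int d = 0; d < n_docs; ++d)
        for (int j = 0; j < k; ++j)
          theta_acc(d, j) += (ndk(d, j) + alpha) / (nd[d] + k * alpha);
      for (int j = 0; j < k; ++j)
        for (int w = 0; w < n_words; ++w)
          beta_acc(j, w) += (nkw(j, w) + eta) / (nk[j] + n_words * eta);
    }
  }
  if (n_acc == 0) n_acc = 1;
  for (int d = 0; d < n_docs; ++d)
    for (int j = 0; j < k; ++j) theta_acc(d, j) /= n_acc;
  for (int j = 0; j < k; ++j)
    for (int w = 0; w < n_words; ++w) beta_acc(j, w) /= n_acc;

  return List::create(_["theta"] = theta_acc, _["beta"] = beta_acc,
                      _["nkw"] = nkw, _["nk"] = nk);
}

// Fold-in inference for held-out documents: Gibbs over the new document's
// tokens with the topic-word counts frozen at the fitted model's values.
// [[Rcpp::export]]
NumericVector lda_gibbs_infer(IntegerVector word_id, IntegerMatrix nkw,
                              IntegerVector nk, int n_words, int k,
                              double alpha, double eta,
                              int n_iter, int burnin) {
  int n_tokens = word_id.size();
  IntegerVector z(n_tokens), ndk(k);
  NumericVector p(k), theta_acc(k);
  RNGScope scope;

  for (int i = 0; i < n_tokens; ++i) {
    int t = (int)(R::unif_rand() * k);
    if (t == k) t = k - 1;
    z[i] = t; ndk[t]++;
  }
  int n_acc = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n_tokens; ++i) {
      int w = word_id[i], t = z[i];
      ndk[t]--;
      double cum = 0.0;
      for (int j = 0; j < k; ++j) {
        cum += (ndk[j] + alpha) *
               (nkw(j, w) + eta) / (nk[j] + n_words * eta);
        p[j] = cum;
      }
      t = sample_topic(p, k);
      z[i] = t; ndk[t]++;
    }
    if (it >= burnin) {
      ++n_acc;
      for (int j = 0; j < k; ++j)
        theta_acc[j] += (ndk[j] + alpha) / (n_tokens + k * alpha);
    }
  }
  if (n_acc == 0) n_acc = 1;
  for (int j = 0; j < k; ++j) theta_acc[j] /= n_acc;
  return theta_acc;
}
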