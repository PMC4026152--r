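#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs samplers for the labeled topic model. Topic and token ids
// are 0-based. Randomness comes from R's generator (unif_rand), so results
// are reproducible under set.seed().

static inline int sample_index(const std::vector<double>& p, int m, double total) {
  double u = unif_rand() * total;
  double cum = 0.0;
  for (int j = 0; j < m; ++j) {
    cum += p[j];
    if (u <= cum) return j;
  }
  return m - 1;
}

// Training sampler: resamples every token's topic within its turn's allowed
// set, and after burn-in accumulates phi-hat = (n_tw + beta)/(n_t + V beta)
// every `lag` sweeps. Optionally tracks per-token topic assignment
// frequencies across retained sweeps (for exact-enumeration checks on tiny
// corpora only: the tracking matrix is total_tokens x n_topics).
// [[Rcpp::export]]
List gibbs_train_cpp(List tokens_, List allowed_, int n_topics, int vocab_size,
                     double alpha, double beta, int n_iter, int burn_in,
                     int lag, bool track_assignments) {
  const int D = tokens_.size();
  if (allowed_.size() != D) stop("tokens and allowed must have equal length");
  std::vector<std::vector<int>> w(D), a(D);
  long total_tokens = 0;
  for (int d = 0; d < D; ++d) {
    w[d] = as<std::vector<int>>(tokens_[d]);
    a[d] = as<std::vector<int>>(allowed_[d]);
    for (size_t i = 0; i < w[d].size(); ++i) {
      if (w[d][i] < 0 || w[d][i] >= vocab_size) stop("token id out of range");
    }
    for (size_t j = 0; j < a[d].size(); ++j) {
      if (a[d][j] < 0 || a[d][j] >= n_topics) stop("topic id out of range");
    }
    if (!w[d].empty() && a[d].empty()) {
      stop("turn with tokens has an empty allowed-topic set");
    }
    total_tokens += w[d].size();
  }

  std::vector<int> ndt((size_t)D * n_topics, 0);
  std::vector<int> ntw((size_t)n_topics * vocab_size, 0);
  std::vector<int> nt(n_topics, 0);
  std::vector<std::vector<int>> z(D);

  for (int d = 0; d < D; ++d) {
    const int nd = (int)w[d].size();
    const int A = (int)a[d].size();
    z[d].resize(nd);
    for (int i = 0; i < nd; ++i) {
      int j = (int)(unif_rand() * A);
      if (j >= A) j = A - 1;
      const int t = a[d][j];
      z[d][i] = t;
      ndt[(size_t)d * n_topics + t]++;
      ntw[(size_t)t * vocab_size + w[d][i]]++;
      nt[t]++;
    }
  }

  const double vb = vocab_size * beta;
  std::vector<double> p(n_topics);
  std::vector<double> phi_sum((size_t)n_topics * vocab_size, 0.0);
  std::vector<double> zfreq;
  if (track_assignments) zfreq.assign((size_t)total_tokens * n_topics, 0.0);
  int n_samples = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      const int A = (int)a[d].size();
      const std::vector<int>& ad = a[d];
      int* ndt_d = &ndt[(size_t)d * n_topics];
      for (size_t i = 0; i < w[d].size(); ++i) {
        const int word = w[d][i];
        const int told = z[d][i];
        ndt_d[told]--;
        ntw[(size_t)told * vocab_size + word]--;
        nt[told]--;
        double total = 0.0;
        for (int j = 0; j < A; ++j) {
          const int t = ad[j];
          const double val = (ndt_d[t] + alpha) *
            (ntw[(size_t)t * vocab_size + word] + beta) / (nt[t] + vb);
          p[j] = val;
          total += val;
        }
        const int tnew = ad[sample_index(p, A, total)];
        z[d][i] = tnew;
        ndt_d[tnew]++;
        ntw[(size_t)tnew * vocab_size + word]++;
        nt[tnew]++;
      }
    }
    if (iter >= burn_in && (iter - burn_in) % lag == 0) {
      ++n_samples;
      for (int t = 0; t < n_topics; ++t) {
        const double denom = nt[t] + vb;
        const int* row = &ntw[(size_t)t * vocab_size];
        double* acc = &phi_sum[(size_t)t * vocab_size];
        for (int v = 0; v < vocab_size; ++v) acc[v] += (row[v] + beta) / denom;
      }
      if (track_assignments) {
        size_t pos = 0;
        for (int d = 0; d < D; ++d) {
          for (size_t i = 0; i < w[d].size(); ++i, ++pos) {
            zfreq[pos * n_topics + z[d][i]] += 1.0;
          }
        }
      }
    }
  }
  if (n_samples == 0) stop("no retained samples: check n_iter/burn_in/lag");

  NumericMatrix phi(n_topics, vocab_size);
  for (int t = 0; t < n_topics; ++t) {
    for (int v = 0; v < vocab_size; ++v) {
      phi(t, v) = phi_sum[(size_t)t * vocab_size + v] / n_samples;
    }
  }
  IntegerMatrix ndt_out(D, n_topics);
  for (int d = 0; d < D; ++d) {
    for (int t = 0; t < n_topics; ++t) {
      ndt_out(d, t) = ndt[(size_t)d * n_topics + t];
    }
  }
  IntegerMatrix ntw_out(n_topics, vocab_size);
  for (int t = 0; t < n_topics; ++t) {
    for (int v = 0; v < vocab_size; ++v) {
      ntw_out(t, v) = ntw[(size_t)t * vocab_size + v];
    }
  }
  List out = List::create(
    _["phi"] = phi,
    _["n_dt"] = ndt_out,
    _["n_tw"] = ntw_out,
    _["n_t"] = IntegerVector(nt.begin(), nt.end()),
    _["n_samples"] = n_samples);
  if (track_assignments) {
    NumericMatrix zf(total_tokens, n_topics);
    for (long i = 0; i < total_tokens; ++i) {
      for (int t = 0; t < n_topics; ++t) {
        zf(i, t) = zfreq[(size_t)i * n_topics + t] / n_samples;
      }
    }
    out["assignment_freq"] = zf;
  }
  return out;
}

// Fold-in inference: phi is frozen; only the per-turn topic counts are
// resampled. theta-hat[d,t] is the average over retained sweeps of
// (n_dt + alpha) / (n_d + |allowed| alpha) on the allowed set, 0 elsewhere.
// Turns are independent given phi, so each is sampled separately.
// [[Rcpp::export]]
NumericMatrix gibbs_infer_cpp(List tokens_, List allowed_, NumericMatrix phi,
                              double alpha, int n_iter, int burn_in, int lag) {
  const int D = tokens_.size();
  const int n_topics = phi.nrow();
  NumericMatrix theta(D, n_topics);
  std::vector<double> p(n_topics);

  for (int d = 0; d < D; ++d) {
    std::vector<int> w = as<std::vector<int>>(tokens_[d]);
    std::vector<int> ad = as<std::vector<int>>(allowed_[d]);
    const int A = (int)ad.size();
    if (A == 0) stop("empty allowed-topic set at turn ", d + 1);
    const int nd = (int)w.size();
    if (nd == 0) {
      for (int j = 0; j < A; ++j) theta(d, ad[j]) = 1.0 / A;
      continue;
    }
    for (int i = 0; i < nd; ++i) {
      if (w[i] < 0 || w[i] >= phi.ncol()) stop("token id out of range");
    }
    std::vector<int> ndt(n_topics, 0);
    std::vector<int> z(nd);
    for (int i = 0; i < nd; ++i) {
      int j = (int)(unif_rand() * A);
      if (j >= A) j = A - 1;
      z[i] = ad[j];
      ndt[z[i]]++;
    }
    std::vector<double> theta_sum(n_topics, 0.0);
    int n_samples = 0;
    const double denom = nd + A * alpha;
    for (int iter = 0; iter < n_iter; ++iter) {
      for (int i = 0; i < nd; ++i) {
        const int word = w[i];
        ndt[z[i]]--;
        double total = 0.0;
        for (int j = 0; j < A; ++j) {
          const int t = ad[j];
          const double val = (ndt[t] + alpha) * phi(t, word);
          p[j] = val;
          total += val;
        }
        z[i] = ad[sample_index(p, A, total)];
        ndt[z[i]]++;
      }
      if (iter >= burn_in && (iter - burn_in) % lag == 0) {
        ++n_samples;
        for (int j = 0; j < A; ++j) {
          const int t = ad[j];
          theta_sum[t] += (ndt[t] + alpha) / denom;
        }
      }
    }
    if (n_samples == 0) stop("no retained samples: check n_iter/burn_in/lag");
    for (int j = 0; j < A; ++j) {
      const int t = ad[j];
      theta(d, t) = theta_sum[t] / n_samples;
    }
  }
  return theta;
}
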