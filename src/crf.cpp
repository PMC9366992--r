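// Linear-chain conditional random field over the three BIO tags, trained by
// stochastic gradient descent on the per-sentence negative log-likelihood
// (forward-backward gradients), decoded with Viterbi. Feature extraction and
// indexing happen on the R side; sentences arrive as lists of 0-based
// feature-id vectors per token.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int K = 3; // tags: 0 = B, 1 = I, 2 = O

struct Sentence {
  std::vector<std::vector<int>> feats; // per token
  std::vector<int> tags;               // may be empty at predict time
};

static std::vector<Sentence> convert(const List &sent_feats,
                                     const List &sent_tags) {
  int n = sent_feats.size();
  std::vector<Sentence> out(n);
  for (int s = 0; s < n; ++s) {
    List ft = sent_feats[s];
    Sentence &snt = out[s];
    snt.feats.resize(ft.size());
    for (int t = 0; t < ft.size(); ++t) {
      IntegerVector v = ft[t];
      snt.feats[t].assign(v.begin(), v.end());
    }
    if (sent_tags.size() > 0) {
      IntegerVector tg = sent_tags[s];
      snt.tags.assign(tg.begin(), tg.end());
    }
  }
  return out;
}

static inline double logsumexp3(const double *v) {
  double m = std::max(v[0], std::max(v[1], v[2]));
  return m + std::log(std::exp(v[0] - m) + std::exp(v[1] - m) +
                      std::exp(v[2] - m));
}

struct Model {
  std::vector<double> W;     // n_features x K, row-major by feature
  double trans[K][K];
  double start[K];
  int n_features;

  explicit Model(int nf) : W(static_cast<size_t>(nf) * K, 0.0),
                           n_features(nf) {
    for (int a = 0; a < K; ++a) {
      start[a] = 0.0;
      for (int b = 0; b < K; ++b) trans[a][b] = 0.0;
    }
  }

  inline double node(const std::vector<int> &f, int k) const {
    double s = 0.0;
    for (size_t j = 0; j < f.size(); ++j) s += W[f[j] * K + k];
    return s;
  }
};

// Accumulate the NLL gradient of one sentence into grad_* (observed minus
// expected feature counts, negated later by the update sign convention).
static void sentence_gradient(const Model &m, const Sentence &snt,
                              std::vector<double> &gW, double gT[K][K],
                              double gS[K]) {
  int T = snt.feats.size();
  if (T == 0) return;

  std::vector<double> node(T * K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) node[t * K + k] = m.node(snt.feats[t], k);

  // forward (log alpha)
  std::vector<double> alpha(T * K);
  for (int k = 0; k < K; ++k) alpha[k] = m.start[k] + node[k];
  double tmp[K];
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      for (int a = 0; a < K; ++a)
        tmp[a] = alpha[(t - 1) * K + a] + m.trans[a][k];
      alpha[t * K + k] = logsumexp3(tmp) + node[t * K + k];
    }
  }
  double logZ = logsumexp3(&alpha[(T - 1) * K]);

  // backward (log beta)
  std::vector<double> beta(T * K, 0.0);
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      for (int b = 0; b < K; ++b)
        tmp[b] = m.trans[k][b] + node[(t + 1) * K + b] + beta[(t + 1) * K + b];
      beta[t * K + k] = logsumexp3(tmp);
    }
  }

  // expected counts minus observed counts (gradient of NLL)
  for (int t = 0; t < T; ++t) {
    double p[K];
    for (int k = 0; k < K; ++k)
      p[k] = std::exp(alpha[t * K + k] + beta[t * K + k] - logZ);
    int gold = snt.tags[t];
    for (int k = 0; k < K; ++k) {
      double g = p[k] - (k == gold ? 1.0 : 0.0);
      if (g != 0.0)
        for (size_t j = 0; j < snt.feats[t].size(); ++j)
          gW[snt.feats[t][j] * K + k] += g;
      if (t == 0) gS[k] += g;
    }
    if (t > 0) {
      for (int a = 0; a < K; ++a) {
        double left = alpha[(t - 1) * K + a];
        for (int b = 0; b < K; ++b) {
          double pe = std::exp(left + m.trans[a][b] + node[t * K + b] +
                               beta[t * K + b] - logZ);
          gT[a][b] += pe;
        }
      }
      gT[snt.tags[t - 1]][snt.tags[t]] -= 1.0;
    }
  }
}

// Deterministic linear congruential shuffle (independent of R's RNG).
struct Lcg {
  uint64_t state;
  explicit Lcg(uint64_t seed) : state(seed * 6364136223846793005ULL + 1442695040888963407ULL) {}
  uint64_t next() {
    state = state * 6364136223846793005ULL + 1442695040888963407ULL;
    return state >> 33;
  }
};

static void shuffle_order(std::vector<int> &order, Lcg &rng) {
  for (int i = order.size() - 1; i > 0; --i) {
    int j = rng.next() % (i + 1);
    std::swap(order[i], order[j]);
  }
}

static List snapshot(const Model &m) {
  NumericMatrix W(m.n_features, K);
  for (int f = 0; f < m.n_features; ++f)
    for (int k = 0; k < K; ++k) W(f, k) = m.W[f * K + k];
  NumericMatrix Tr(K, K);
  NumericVector S(K);
  for (int a = 0; a < K; ++a) {
    S[a] = m.start[a];
    for (int b = 0; b < K; ++b) Tr(a, b) = m.trans[a][b];
  }
  return List::create(Named("W") = W, Named("trans") = Tr,
                      Named("start") = S);
}

// [[Rcpp::export(name = ".crf_train_path")]]
List crf_train_path(List sent_feats, List sent_tags, int n_features,
                    double learning_rate, IntegerVector checkpoints,
                    int batch_size, int seed) {
  std::vector<Sentence> data = convert(sent_feats, sent_tags);
  Model m(std::max(n_features, 1));
  // The transformer-style learning-rate grid (1e-5..5e-5) is mapped onto the
  // linear model's AdaGrad step by a fixed factor; grid ordering is
  // preserved. Per-parameter adaptive steps keep rare entity features
  // learnable next to the dominant O class.
  double step = learning_rate * 1e4;
  if (batch_size < 1) batch_size = 1;
  const double eps = 1e-8;
  std::vector<double> hW(m.W.size(), 0.0);
  double hT[K][K] = {{0}};
  double hS[K] = {0};

  std::vector<int> cps(checkpoints.begin(), checkpoints.end());
  std::sort(cps.begin(), cps.end());
  int max_epochs = cps.empty() ? 0 : cps.back();

  List out(cps.size());
  size_t next_cp = 0;
  Lcg rng(static_cast<uint64_t>(seed) + 0x9e3779b97f4a7c15ULL);
  std::vector<int> order(data.size());
  for (size_t i = 0; i < data.size(); ++i) order[i] = i;

  std::vector<double> gW(m.W.size(), 0.0);
  std::vector<int> touched;
  touched.reserve(4096);

  for (int ep = 1; ep <= max_epochs; ++ep) {
    shuffle_order(order, rng);
    size_t pos = 0;
    while (pos < order.size()) {
      size_t stop = std::min(pos + static_cast<size_t>(batch_size),
                             order.size());
      double gT[K][K] = {{0}};
      double gS[K] = {0};
      touched.clear();
      for (size_t i = pos; i < stop; ++i) {
        const Sentence &snt = data[order[i]];
        for (size_t t = 0; t < snt.feats.size(); ++t)
          for (size_t j = 0; j < snt.feats[t].size(); ++j)
            touched.push_back(snt.feats[t][j]);
        sentence_gradient(m, snt, gW, gT, gS);
      }
      for (size_t j = 0; j < touched.size(); ++j) {
        int f = touched[j];
        for (int k = 0; k < K; ++k) {
          double g = gW[f * K + k];
          if (g != 0.0) {
            hW[f * K + k] += g * g;
            m.W[f * K + k] -= step * g / (std::sqrt(hW[f * K + k]) + eps);
            gW[f * K + k] = 0.0;
          }
        }
      }
      for (int a = 0; a < K; ++a) {
        hS[a] += gS[a] * gS[a];
        m.start[a] -= step * gS[a] / (std::sqrt(hS[a]) + eps);
        for (int b = 0; b < K; ++b) {
          hT[a][b] += gT[a][b] * gT[a][b];
          m.trans[a][b] -= step * gT[a][b] / (std::sqrt(hT[a][b]) + eps);
        }
      }
      pos = stop;
    }
    while (next_cp < cps.size() && cps[next_cp] == ep) {
      out[next_cp] = snapshot(m);
      ++next_cp;
    }
  }
  // checkpoints beyond max_epochs cannot occur (max is the last checkpoint)
  if (max_epochs == 0 && !cps.empty()) {
    for (size_t c = 0; c < cps.size(); ++c) out[c] = snapshot(m);
  }
  return out;
}

// [[Rcpp::export(name = ".crf_viterbi")]]
List crf_viterbi(List sent_feats, NumericMatrix W, NumericMatrix trans,
                 NumericVector start) {
  int n_features = W.nrow();
  Model m(n_features);
  for (int f = 0; f < n_features; ++f)
    for (int k = 0; k < K; ++k) m.W[f * K + k] = W(f, k);
  for (int a = 0; a < K; ++a) {
    m.start[a] = start[a];
    for (int b = 0; b < K; ++b) m.trans[a][b] = trans(a, b);
  }

  List empty_tags;
  std::vector<Sentence> data = convert(sent_feats, empty_tags);
  List out(data.size());
  for (size_t s = 0; s < data.size(); ++s) {
    int T = data[s].feats.size();
    IntegerVector tags(T);
    if (T == 0) { out[s] = tags; continue; }
    std::vector<double> delta(T * K);
    std::vector<int> psi(T * K, 0);
    for (int k = 0; k < K; ++k)
      delta[k] = m.start[k] + m.node(data[s].feats[0], k);
    for (int t = 1; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = delta[(t - 1) * K] + m.trans[0][k];
        int arg = 0;
        for (int a = 1; a < K; ++a) {
          double v = delta[(t - 1) * K + a] + m.trans[a][k];
          if (v > best) { best = v; arg = a; }
        }
        delta[t * K + k] = best + m.node(data[s].feats[t], k);
        psi[t * K + k] = arg;
      }
    }
    int cur = 0;
    double best = delta[(T - 1) * K];
    for (int k = 1; k < K; ++k)
      if (delta[(T - 1) * K + k] > best) { best = delta[(T - 1) * K + k]; cur = k; }
    for (int t = T - 1; t >= 0; --t) {
      tags[t] = cur;
      cur = psi[t * K + cur];
    }
    out[s] = tags;
  }
  return out;
}
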