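// Elman recurrent network: forward pass, exact backpropagation through
// time, and the per-example SGD loop with a training-AUC stopping rule.
// Sequences are short clinical visit histories, so full (untruncated)
// unrolling is used throughout.
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Midrank (tie-aware) AUC: concordance probability of positives over
// negatives, equal to the trapezoidal area under the empirical ROC.
static double auc_midrank(const std::vector<double>& s, const std::vector<int>& lab) {
  const int n = s.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return s[a] < s[b]; });
  std::vector<double> rank(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && s[idx[j + 1]] == s[idx[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;  // midrank, 1-based
    for (int k = i; k <= j; ++k) rank[idx[k]] = r;
    i = j + 1;
  }
  double rpos = 0.0;
  long npos = 0;
  for (int k = 0; k < n; ++k) {
    if (lab[k] == 1) { rpos += rank[k]; ++npos; }
  }
  long nneg = n - npos;
  if (npos == 0 || nneg == 0) return NA_REAL;
  return (rpos - 0.5 * npos * (npos + 1)) / (double(npos) * double(nneg));
}

// Forward pass storing the hidden trajectory; returns final output.
static double forward_store(const mat& Wr, const mat& Wi, const vec& Wo,
                            const mat& X, mat& H) {
  const int T = X.n_rows;
  vec h(Wr.n_rows, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    h = arma::tanh(Wr * h + Wi * X.row(t).t());
    H.row(t) = h.t();
  }
  return sigmoid(arma::dot(Wo, h));
}

// Gradient of the final-step binary cross-entropy wrt (Wr, Wi, Wo).
static double bptt(const mat& Wr, const mat& Wi, const vec& Wo,
                   const mat& X, double label,
                   mat& gWr, mat& gWi, vec& gWo) {
  const int T = X.n_rows;
  const int n = Wr.n_rows;
  mat H(T, n);
  double y = forward_store(Wr, Wi, Wo, X, H);
  double dz = y - label;  // d(BCE)/d(Wo.h_T) for logistic output
  gWo = dz * H.row(T - 1).t();
  gWr.zeros();
  gWi.zeros();
  vec dh = dz * Wo;
  for (int t = T - 1; t >= 0; --t) {
    vec ht = H.row(t).t();
    vec da = dh % (1.0 - ht % ht);  // through tanh
    if (t > 0) gWr += da * H.row(t - 1);  // h_0 = 0 contributes nothing
    gWi += da * X.row(t);
    dh = Wr.t() * da;
  }
  return y;
}

// [[Rcpp::export]]
List rnn_forward_cpp(const arma::mat& Wr, const arma::mat& Wi,
                     const arma::vec& Wo, const arma::mat& X) {
  const int T = X.n_rows;
  mat H(T, Wr.n_rows);
  forward_store(Wr, Wi, Wo, X, H);
  vec y(T);
  for (int t = 0; t < T; ++t) y(t) = sigmoid(arma::dot(Wo, H.row(t).t()));
  return List::create(_["h"] = H, _["y"] = y, _["score"] = y(T - 1));
}

// [[Rcpp::export]]
List rnn_bptt_cpp(const arma::mat& Wr, const arma::mat& Wi,
                  const arma::vec& Wo, const arma::mat& X, double label) {
  mat gWr(Wr.n_rows, Wr.n_cols), gWi(Wi.n_rows, Wi.n_cols);
  vec gWo(Wo.n_elem);
  double y = bptt(Wr, Wi, Wo, X, label, gWr, gWi, gWo);
  return List::create(_["Wr"] = gWr, _["Wi"] = gWi, _["Wo"] = gWo,
                      _["score"] = y);
}

// [[Rcpp::export]]
NumericVector rnn_score_cpp(List seqs, const arma::mat& Wr,
                            const arma::mat& Wi, const arma::vec& Wo) {
  const int N = seqs.size();
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    mat X = as<mat>(seqs[i]);
    mat H(X.n_rows, Wr.n_rows);
    out[i] = forward_store(Wr, Wi, Wo, X, H);
  }
  return out;
}

// Per-example SGD over pre-shuffled epochs; `orders` holds one 1-based
// visiting order per epoch row so the caller owns all randomness.
// [[Rcpp::export]]
List rnn_sgd_cpp(List seqs, IntegerVector labels,
                 arma::mat Wr, arma::mat Wi, arma::vec Wo,
                 double lr, int max_epochs, double auc_stop,
                 IntegerMatrix orders) {
  const int N = seqs.size();
  std::vector<mat> X(N);
  for (int i = 0; i < N; ++i) X[i] = as<mat>(seqs[i]);
  std::vector<int> lab(labels.begin(), labels.end());

  const int n = Wr.n_rows, p = Wi.n_cols;
  mat gWr(n, n), gWi(n, p);
  vec gWo(n);
  std::vector<double> loss_hist, auc_hist;
  std::string reason = "max_epochs";

  for (int e = 0; e < max_epochs; ++e) {
    for (int k = 0; k < N; ++k) {
      const int i = orders(e, k) - 1;
      bptt(Wr, Wi, Wo, X[i], double(lab[i]), gWr, gWi, gWo);
      Wr -= lr * gWr;
      Wi -= lr * gWi;
      Wo -= lr * gWo;
    }
    // end-of-epoch training diagnostics on the whole pool
    std::vector<double> sc(N);
    double lsum = 0.0;
    for (int i = 0; i < N; ++i) {
      mat H(X[i].n_rows, n);
      double y = forward_store(Wr, Wi, Wo, X[i], H);
      sc[i] = y;
      double yc = std::min(std::max(y, 1e-12), 1.0 - 1e-12);
      lsum -= lab[i] == 1 ? std::log(yc) : std::log(1.0 - yc);
    }
    loss_hist.push_back(lsum / N);
    double a = auc_midrank(sc, lab);
    auc_hist.push_back(a);
    if (a > auc_stop) { reason = "early_stop"; break; }
  }
  return List::create(_["Wr"] = Wr, _["Wi"] = Wi, _["Wo"] = Wo,
                      _["loss"] = wrap(loss_hist), _["auc"] = wrap(auc_hist),
                      _["stop_reason"] = reason);
}
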