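#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Single-hidden-layer network trained with per-sample stochastic gradient
// descent on binary cross-entropy.  Hidden activation: sigmoid; output:
// linear, read through a logistic link inside the loss (logits-with-BCE).
// Deterministic given `seed` (init and per-epoch shuffles share one RNG).

static inline double sigmoidc(double z) {
  if (z >= 0) {
    double e = std::exp(-z);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(z);
  return e / (1.0 + e);
}

// [[Rcpp::export]]
List mlp_train_cpp(NumericMatrix X, NumericVector y, int hidden,
                   int max_epochs, double lr, double tol, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(-0.1, 0.1);

  std::vector<double> W1((size_t)hidden * p), b1(hidden), w2(hidden);
  double b2 = unif(rng);
  for (auto &v : W1) v = unif(rng);
  for (auto &v : b1) v = unif(rng);
  for (auto &v : w2) v = unif(rng);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> a(hidden), losses;
  losses.reserve(max_epochs);

  // column-major access into X: X(i, j) = x[i + j*n]
  const double *xp = X.begin();
  int epochs_run = 0;

  for (int ep = 0; ep < max_epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double loss_sum = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = idx[t];
      // forward
      double z2 = b2;
      for (int hdx = 0; hdx < hidden; ++hdx) {
        double z = b1[hdx];
        const double *wrow = &W1[(size_t)hdx * p];
        for (int j = 0; j < p; ++j) z += wrow[j] * xp[i + (size_t)j * n];
        a[hdx] = sigmoidc(z);
        z2 += w2[hdx] * a[hdx];
      }
      double prob = sigmoidc(z2);
      double yi = y[i];
      double pc = std::min(std::max(prob, 1e-12), 1.0 - 1e-12);
      loss_sum += -(yi * std::log(pc) + (1.0 - yi) * std::log(1.0 - pc));
      // backward
      double dz2 = prob - yi;
      for (int hdx = 0; hdx < hidden; ++hdx) {
        double dh = dz2 * w2[hdx] * a[hdx] * (1.0 - a[hdx]);
        w2[hdx] -= lr * dz2 * a[hdx];
        double *wrow = &W1[(size_t)hdx * p];
        for (int j = 0; j < p; ++j)
          wrow[j] -= lr * dh * xp[i + (size_t)j * n];
        b1[hdx] -= lr * dh;
      }
      b2 -= lr * dz2;
    }
    double mean_loss = loss_sum / n;
    if (!std::isfinite(mean_loss))
      stop("training diverged: non-finite epoch loss at epoch %d", ep + 1);
    losses.push_back(mean_loss);
    epochs_run = ep + 1;
    if (mean_loss < tol) break;
  }

  NumericMatrix W1r(hidden, p);
  for (int hdx = 0; hdx < hidden; ++hdx)
    for (int j = 0; j < p; ++j) W1r(hdx, j) = W1[(size_t)hdx * p + j];

  return List::create(_["w1"] = W1r,
                      _["b1"] = NumericVector(b1.begin(), b1.end()),
                      _["w2"] = NumericVector(w2.begin(), w2.end()),
                      _["b2"] = b2,
                      _["loss"] = NumericVector(losses.begin(), losses.end()),
                      _["epochs"] = epochs_run);
}
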