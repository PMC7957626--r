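#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Minibatch SGD on the softmax cross-entropy for the GAP+FC head.
// The loop is compiled because the stated learning rate (1e-6) needs on the
// order of 1e6 sample steps on unit-variance features before the weights
// leave the small-logit regime; an interpreted loop at that step count is
// impractical. Shuffling uses a private mt19937 stream (Fisher-Yates), so
// training is bit-reproducible for a fixed seed on every platform.
//
// Z: n x K standardized pooled features; y: 0-based class labels;
// tr_idx / val_idx: 0-based row indices. Returns the weights of the epoch
// with the best validation accuracy (earliest epoch wins ties) plus the
// validation history.
// optimizer: 0 = plain SGD, 1 = Adam (beta1 0.9, beta2 0.999, eps 1e-8).
// [[Rcpp::export(rng = false)]]
List sgd_softmax_train(NumericMatrix Z, IntegerVector y,
                       NumericMatrix w0, NumericVector b0,
                       double lr, int epochs, int batch_size,
                       IntegerVector tr_idx, IntegerVector val_idx,
                       int shuffle_seed, int optimizer) {
  const int K = w0.nrow(), C = w0.ncol();
  const int ntr = tr_idx.size(), nval = val_idx.size();
  std::vector<double> w(w0.begin(), w0.end());   // K x C, column-major
  std::vector<double> b(b0.begin(), b0.end());
  std::vector<double> wbest(w), bbest(b);
  std::vector<double> s(C), p(C);
  std::vector<int> order(tr_idx.begin(), tr_idx.end());
  std::mt19937 gen(static_cast<unsigned int>(shuffle_seed));
  NumericVector history(epochs);
  double best_loss = R_PosInf;
  int best_epoch = 0;

  auto logits = [&](const std::vector<double>& wv, const std::vector<double>& bv,
                    int row) {
    for (int c = 0; c < C; ++c) {
      double acc = bv[c];
      const double* wc = wv.data() + (size_t)c * K;
      for (int k = 0; k < K; ++k) acc += wc[k] * Z(row, k);
      s[c] = acc;
    }
  };
  // validation mean cross-entropy; the best epoch is the loss minimizer
  // (accuracy saturates early on separable data and would freeze a noisy
  // early-epoch head)
  auto val_loss = [&](const std::vector<double>& wv,
                      const std::vector<double>& bv) {
    if (nval == 0) return 0.0;
    double total = 0.0;
    for (int i = 0; i < nval; ++i) {
      int row = val_idx[i];
      logits(wv, bv, row);
      double mx = s[0];
      for (int c = 1; c < C; ++c) mx = std::max(mx, s[c]);
      double zsum = 0.0;
      for (int c = 0; c < C; ++c) zsum += std::exp(s[c] - mx);
      total += std::log(zsum) - (s[y[row]] - mx);
    }
    return total / nval;
  };

  std::vector<double> gw((size_t)K * C), gb(C);
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  std::vector<double> mw, vw, mb, vb;
  long tstep = 0;
  if (optimizer == 1) {
    mw.assign((size_t)K * C, 0.0); vw.assign((size_t)K * C, 0.0);
    mb.assign(C, 0.0); vb.assign(C, 0.0);
  }
  for (int epoch = 0; epoch < epochs; ++epoch) {
    // Fisher-Yates shuffle with our own stream (std::shuffle is
    // implementation-defined, this is not)
    for (int i = ntr - 1; i > 0; --i) {
      std::uniform_int_distribution<int> d(0, i);
      std::swap(order[i], order[d(gen)]);
    }
    for (int start = 0; start < ntr; start += batch_size) {
      int end = std::min(start + batch_size, ntr);
      int bs = end - start;
      std::fill(gw.begin(), gw.end(), 0.0);
      std::fill(gb.begin(), gb.end(), 0.0);
      for (int ii = start; ii < end; ++ii) {
        int row = order[ii];
        logits(w, b, row);
        double mx = s[0];
        for (int c = 1; c < C; ++c) mx = std::max(mx, s[c]);
        double zsum = 0.0;
        for (int c = 0; c < C; ++c) { p[c] = std::exp(s[c] - mx); zsum += p[c]; }
        for (int c = 0; c < C; ++c) {
          double g = p[c] / zsum - (y[row] == c ? 1.0 : 0.0);
          gb[c] += g;
          double* gwc = gw.data() + (size_t)c * K;
          for (int k = 0; k < K; ++k) gwc[k] += g * Z(row, k);
        }
      }
      if (optimizer == 1) {
        ++tstep;
        double bc1 = 1.0 - std::pow(beta1, (double)tstep);
        double bc2 = 1.0 - std::pow(beta2, (double)tstep);
        for (size_t j = 0; j < gw.size(); ++j) {
          double g = gw[j] / bs;
          mw[j] = beta1 * mw[j] + (1 - beta1) * g;
          vw[j] = beta2 * vw[j] + (1 - beta2) * g * g;
          w[j] -= lr * (mw[j] / bc1) / (std::sqrt(vw[j] / bc2) + eps);
        }
        for (int c = 0; c < C; ++c) {
          double g = gb[c] / bs;
          mb[c] = beta1 * mb[c] + (1 - beta1) * g;
          vb[c] = beta2 * vb[c] + (1 - beta2) * g * g;
          b[c] -= lr * (mb[c] / bc1) / (std::sqrt(vb[c] / bc2) + eps);
        }
      } else {
        double step = lr / bs;
        for (size_t j = 0; j < gw.size(); ++j) w[j] -= step * gw[j];
        for (int c = 0; c < C; ++c) b[c] -= step * gb[c];
      }
    }
    double loss = val_loss(w, b);
    history[epoch] = loss;
    if (loss < best_loss) {
      best_loss = loss;
      best_epoch = epoch + 1;
      wbest = w;
      bbest = b;
    }
  }

  NumericMatrix wout(K, C);
  std::copy(wbest.begin(), wbest.end(), wout.begin());
  return List::create(_["w"] = wout, _["b"] = NumericVector(bbest.begin(), bbest.end()),
                      _["best_epoch"] = best_epoch, _["history"] = history);
}
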