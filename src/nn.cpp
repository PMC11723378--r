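// Minimal single-precision training engine for the lab-of-origin
// classifiers: 1D convolutional networks with optional residual shortcuts
// (ResNet / plain CNN) and fully connected networks (MLP), trained with
// Adam on the softmax cross-entropy. Activations are laid out as
// (batch * length) x channels matrices so convolutions reduce to one BLAS
// GEMM per layer via im2col.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

using arma::fmat;
using arma::frowvec;

namespace {

// On separable data the loss collapses and gradients underflow to
// subnormals, which x86 handles orders of magnitude slower; flush them to
// zero while training and restore the FP environment afterwards.
struct FlushDenormals {
#ifdef __SSE2__
  unsigned int csr;
  FlushDenormals() : csr(_mm_getcsr()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() { _mm_setcsr(csr); }
#endif
};

struct Adam {
  fmat m, v;
  void init(const fmat &w) {
    m.zeros(w.n_rows, w.n_cols);
    v.zeros(w.n_rows, w.n_cols);
  }
  void step(fmat &w, const fmat &g, float lr, int t) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    m = b1 * m + (1.0f - b1) * g;
    v = b2 * v + (1.0f - b2) * (g % g);
    float c1 = 1.0f - std::pow(b1, (float)t);
    float c2 = 1.0f - std::pow(b2, (float)t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

struct ConvLayer {
  int c_in, c_out, k, pad_l;
  fmat W;        // (k * c_in) x c_out
  frowvec b;     // 1 x c_out
  Adam aW, ab;
  // per-batch caches
  fmat Xcol;     // (batch * L) x (k * c_in)
  fmat A_out;    // post-activation (or pre-relu sum cache for top layers)

  void init(int ci, int co, int kk, std::mt19937 &gen) {
    c_in = ci; c_out = co; k = kk; pad_l = (kk - 1) / 2;
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / (kk * ci)));
    W.set_size(kk * ci, co);
    for (auto &x : W) x = nd(gen);
    b.zeros(co);
    aW.init(W); ab.init(fmat(b));
  }

  void im2col(const fmat &A, int n, int L) {
    Xcol.zeros(n * L, k * c_in);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < k; ++j) {
        int lo = std::max(0, pad_l - j);
        int hi = std::min(L - 1, L - 1 + pad_l - j);
        if (lo > hi) continue;
        Xcol.submat(i * L + lo, j * c_in, i * L + hi, (j + 1) * c_in - 1) =
          A.rows(i * L + lo + j - pad_l, i * L + hi + j - pad_l);
      }
    }
  }

  // linear part only; caller applies relu / residual add
  fmat forward(const fmat &A, int n, int L) {
    im2col(A, n, L);
    fmat Z = Xcol * W;
    Z.each_row() += b;
    return Z;
  }

  // dZ: gradient wrt pre-activation; returns gradient wrt layer input
  fmat backward(const fmat &dZ, int n, int L, float lr, int t) {
    fmat dW = Xcol.t() * dZ;
    frowvec db = arma::sum(dZ, 0);
    fmat dXcol = dZ * W.t();
    fmat dA(n * L, c_in, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < k; ++j) {
        int lo = std::max(0, pad_l - j);
        int hi = std::min(L - 1, L - 1 + pad_l - j);
        if (lo > hi) continue;
        dA.rows(i * L + lo + j - pad_l, i * L + hi + j - pad_l) +=
          dXcol.submat(i * L + lo, j * c_in, i * L + hi, (j + 1) * c_in - 1);
      }
    }
    aW.step(W, dW, lr, t);
    fmat bb(b), gb(db);
    ab.step(bb, gb, lr, t);
    b = bb.row(0);
    return dA;
  }
};

struct DenseLayer {
  fmat W;
  frowvec b;
  Adam aW, ab;
  fmat X;  // cache

  void init(int d_in, int d_out, std::mt19937 &gen) {
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / d_in));
    W.set_size(d_in, d_out);
    for (auto &x : W) x = nd(gen);
    b.zeros(d_out);
    aW.init(W); ab.init(fmat(b));
  }
  fmat forward(const fmat &A) {
    X = A;
    fmat Z = A * W;
    Z.each_row() += b;
    return Z;
  }
  fmat backward(const fmat &dZ, float lr, int t) {
    fmat dW = X.t() * dZ;
    frowvec db = arma::sum(dZ, 0);
    fmat dX = dZ * W.t();
    aW.step(W, dW, lr, t);
    fmat bb(b), gb(db);
    ab.step(bb, gb, lr, t);
    b = bb.row(0);
    return dX;
  }
};

// softmax cross-entropy; returns mean loss, fills dZ (already / n)
float softmax_ce(const fmat &logits, const arma::ivec &y, fmat &dZ) {
  int n = logits.n_rows;
  fmat Z = logits;
  Z.each_col() -= arma::max(Z, 1);
  fmat E = arma::exp(Z);
  arma::fvec s = arma::sum(E, 1);
  fmat P = E.each_col() / s;
  float loss = 0.0f;
  for (int i = 0; i < n; ++i) loss -= std::log(std::max(P(i, y[i]), 1e-12f));
  dZ = P;
  for (int i = 0; i < n; ++i) dZ(i, y[i]) -= 1.0f;
  dZ /= (float)n;
  return loss / n;
}

struct ConvNet {
  int blocks, per_block, filters, kernel, L;
  bool residual;
  std::vector<ConvLayer> conv;   // blocks * per_block layers
  ConvLayer proj;                // 1x1 projection shortcut of block 1
  DenseLayer head;
  std::vector<fmat> acts;        // post-activation per layer (batch*L x C)
  std::vector<fmat> block_in;    // input of each block
  fmat gap;

  void init(int B, int P, int F, int K, int len, bool res, std::mt19937 &g) {
    blocks = B; per_block = P; filters = F; kernel = K; L = len;
    residual = res;
    conv.resize(B * P);
    for (int b = 0; b < B; ++b)
      for (int p = 0; p < P; ++p)
        conv[b * P + p].init((b == 0 && p == 0) ? 1 : F, F, K, g);
    if (residual) proj.init(1, F, 1, g);
    head.init(F, 2, g);
  }

  fmat forward(const fmat &X, int n) {
    // X: n x L -> column activation (n*L) x 1
    fmat A(n * L, 1);
    for (int i = 0; i < n; ++i)
      A.rows(i * L, i * L + L - 1) = X.row(i).t();
    acts.assign(conv.size(), fmat());
    block_in.assign(blocks, fmat());
    for (int b = 0; b < blocks; ++b) {
      block_in[b] = A;
      fmat sc;
      if (residual) sc = (b == 0) ? proj.forward(A, n, L) : A;
      for (int p = 0; p < per_block; ++p) {
        int li = b * per_block + p;
        fmat Z = conv[li].forward(A, n, L);
        if (residual && p == per_block - 1) Z += sc;
        A = Z % arma::conv_to<fmat>::from(Z > 0);
        acts[li] = A;
      }
    }
    // global average pooling over time
    gap.set_size(n, filters);
    for (int i = 0; i < n; ++i)
      gap.row(i) = arma::mean(A.rows(i * L, i * L + L - 1), 0);
    return head.forward(gap);
  }

  void backward(const fmat &dLogits, int n, float lr, int t) {
    fmat dGap = head.backward(dLogits, lr, t);
    fmat dA(n * L, filters);
    for (int i = 0; i < n; ++i)
      dA.rows(i * L, i * L + L - 1) =
        arma::repmat(dGap.row(i) / (float)L, L, 1);
    for (int b = blocks - 1; b >= 0; --b) {
      fmat dSc;
      for (int p = per_block - 1; p >= 0; --p) {
        int li = b * per_block + p;
        fmat dZ = dA % arma::conv_to<fmat>::from(acts[li] > 0);
        if (residual && p == per_block - 1) dSc = dZ;
        dA = conv[li].backward(dZ, n, L, lr, t);
      }
      if (residual) {
        if (b == 0) {
          dA += proj.backward(dSc, n, L, lr, t);
        } else {
          dA += dSc;
        }
      }
    }
  }
};

arma::uvec predict_conv(ConvNet &net, const fmat &X, int chunk = 256) {
  int n = X.n_rows;
  arma::uvec out(n);
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    fmat logits = net.forward(X.rows(s, e - 1), e - s);
    out.subvec(s, e - 1) = arma::index_max(logits, 1);
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_train_convnet(const arma::mat &Xtr, const arma::ivec &ytr,
                             const arma::mat &Xte, const arma::ivec &yte,
                             int blocks, int per_block, int filters,
                             int kernel, bool residual, int epochs,
                             int batch, double lr, int seed) {
  FlushDenormals ftz;
  std::mt19937 gen(seed);
  int n = Xtr.n_rows, L = Xtr.n_cols;
  fmat Xtrf = arma::conv_to<fmat>::from(Xtr);
  fmat Xtef = arma::conv_to<fmat>::from(Xte);
  ConvNet net;
  net.init(blocks, per_block, filters, kernel, L, residual, gen);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int t = 0;
  float last_loss = 0.0f;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), gen);
    for (int s = 0; s < n; s += batch) {
      int eend = std::min(n, s + batch);
      int bs = eend - s;
      if (bs < 2) continue;  // degenerate tail batch
      fmat Xb(bs, L);
      arma::ivec yb(bs);
      for (int i = 0; i < bs; ++i) {
        Xb.row(i) = Xtrf.row(idx[s + i]);
        yb[i] = ytr[idx[s + i]];
      }
      fmat logits = net.forward(Xb, bs);
      fmat dZ;
      last_loss = softmax_ce(logits, yb, dZ);
      ++t;
      net.backward(dZ, bs, (float)lr, t);
    }
    Rcpp::checkUserInterrupt();
  }
  arma::uvec pred = predict_conv(net, Xtef);
  double acc = 0.0;
  for (arma::uword i = 0; i < pred.n_elem; ++i)
    if ((int)pred[i] == yte[i]) acc += 1.0;
  acc /= pred.n_elem;
  return Rcpp::List::create(Rcpp::Named("accuracy") = acc,
                            Rcpp::Named("train_loss") = (double)last_loss);
}

// [[Rcpp::export]]
Rcpp::List cpp_train_mlp(const arma::mat &Xtr, const arma::ivec &ytr,
                         const arma::mat &Xte, const arma::ivec &yte,
                         const arma::ivec &hidden, int epochs, int batch,
                         double lr, int seed) {
  FlushDenormals ftz;
  std::mt19937 gen(seed);
  int n = Xtr.n_rows, L = Xtr.n_cols;
  fmat Xtrf = arma::conv_to<fmat>::from(Xtr);
  fmat Xtef = arma::conv_to<fmat>::from(Xte);
  std::vector<DenseLayer> layers(hidden.n_elem + 1);
  int d = L;
  for (arma::uword h = 0; h < hidden.n_elem; ++h) {
    layers[h].init(d, hidden[h], gen);
    d = hidden[h];
  }
  layers.back().init(d, 2, gen);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int t = 0;
  float last_loss = 0.0f;
  std::vector<fmat> acts(layers.size());
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), gen);
    for (int s = 0; s < n; s += batch) {
      int eend = std::min(n, s + batch);
      int bs = eend - s;
      if (bs < 2) continue;
      fmat A(bs, L);
      arma::ivec yb(bs);
      for (int i = 0; i < bs; ++i) {
        A.row(i) = Xtrf.row(idx[s + i]);
        yb[i] = ytr[idx[s + i]];
      }
      for (size_t li = 0; li + 1 < layers.size(); ++li) {
        { fmat Z = layers[li].forward(A); A = Z % arma::conv_to<fmat>::from(Z > 0); }
        acts[li] = A;
      }
      fmat logits = layers.back().forward(A);
      fmat dZ;
      last_loss = softmax_ce(logits, yb, dZ);
      ++t;
      fmat dA = layers.back().backward(dZ, (float)lr, t);
      for (int li = (int)layers.size() - 2; li >= 0; --li) {
        dA = dA % arma::conv_to<fmat>::from(acts[li] > 0);
        dA = layers[li].backward(dA, (float)lr, t);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  fmat A = Xtef;
  for (size_t li = 0; li + 1 < layers.size(); ++li)
    { fmat Z = layers[li].forward(A); A = Z % arma::conv_to<fmat>::from(Z > 0); }
  arma::uvec pred = arma::index_max(layers.back().forward(A), 1);
  double acc = 0.0;
  for (arma::uword i = 0; i < pred.n_elem; ++i)
    if ((int)pred[i] == yte[i]) acc += 1.0;
  acc /= pred.n_elem;
  return Rcpp::List::create(Rcpp::Named("accuracy") = acc,
                            Rcpp::Named("train_loss") = (double)last_loss);
}
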