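// Small patch-classification ConvNets: conv (5x5, zero-padded) + L2-norm
// pooling stages, one fully connected ReLU layer, 2-unit softmax output,
// trained by plain SGD with a per-update learning-rate decay
// rate_t = lr / (1 + decay * t). Single precision throughout; the heavy
// lifting is im2col + sgemm.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <algorithm>
#include <random>
#if defined(__SSE3__) || defined(__x86_64__)
#include <pmmintrin.h>
#include <xmmintrin.h>
#endif
#if defined(__GLIBC__)
#include <malloc.h>
#endif

// Denormalized intermediates (tiny ReLU/softmax tails) can slow x86 float
// arithmetic by an order of magnitude; flush them to zero — for the numeric
// scale of this workload they are indistinguishable from zero. Also keep
// glibc from returning the large per-batch gradient buffers to the kernel
// between mini-batches (mmap churn re-zeroes hundreds of MB per epoch).
static inline void flush_denormals() {
#if defined(__SSE3__) || defined(__x86_64__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
#if defined(__GLIBC__)
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Arch {
  int H, W, C;
  std::vector<int> maps;   // feature maps per conv+pool stage
  int fc_units;
  int kernel, pad, pool;
  int n_class;
};

struct StageDims {
  int Hin, Win, Cin;   // input geometry
  int Ho, Wo;          // conv output (zero padding keeps Ho = Hin when pad = (k-1)/2)
  int Hp, Wp;          // pooled output (floor division; trailing row/col dropped)
};

std::vector<StageDims> stage_dims(const Arch& a) {
  std::vector<StageDims> out;
  int h = a.H, w = a.W, c = a.C;
  for (size_t s = 0; s < a.maps.size(); ++s) {
    StageDims d;
    d.Hin = h; d.Win = w; d.Cin = c;
    d.Ho = h + 2 * a.pad - a.kernel + 1;
    d.Wo = w + 2 * a.pad - a.kernel + 1;
    if (d.Ho < 1 || d.Wo < 1) Rcpp::stop("conv stage output collapsed to zero size");
    d.Hp = d.Ho / a.pool; d.Wp = d.Wo / a.pool;
    if (d.Hp < 1 || d.Wp < 1) Rcpp::stop("pool stage output collapsed to zero size");
    out.push_back(d);
    h = d.Hp; w = d.Wp; c = a.maps[s];
  }
  return out;
}

int flat_dim(const Arch& a) {
  auto dims = stage_dims(a);
  const StageDims& last = dims.back();
  return last.Hp * last.Wp * a.maps.back();
}

// Activation layout: value (i, j, c) of sample b sits at row i + j*H + c*H*W,
// column b. im2col column order: b*Ho*Wo + j*Ho + i; row order kc*k*k + kj*k + ki.
// Cell-major loops: each im2col column (one output pixel) is K contiguous
// floats, so the inner loops stream through memory.
void im2col(const fmat& A, const StageDims& d, int kernel, int pad, fmat& col) {
  const int K = d.Cin * kernel * kernel;
  const int B = A.n_cols;
  col.zeros(K, (size_t)d.Ho * d.Wo * B);
  for (int b = 0; b < B; ++b) {
    const float* src = A.colptr(b);
    for (int j = 0; j < d.Wo; ++j) {
      for (int i = 0; i < d.Ho; ++i) {
        float* dst = col.colptr((size_t)b * d.Ho * d.Wo + (size_t)j * d.Ho + i);
        for (int c = 0; c < d.Cin; ++c) {
          const float* plane = src + (size_t)c * d.Hin * d.Win;
          for (int kj = 0; kj < kernel; ++kj) {
            const int sj = j + kj - pad;
            float* out = dst + (c * kernel + kj) * kernel;
            if (sj < 0 || sj >= d.Win) continue;
            const float* scol = plane + (size_t)sj * d.Hin;
            for (int ki = 0; ki < kernel; ++ki) {
              const int si = i + ki - pad;
              if (si >= 0 && si < d.Hin) out[ki] = scol[si];
            }
          }
        }
      }
    }
  }
}

void col2im(const fmat& dcol, const StageDims& d, int kernel, int pad, fmat& dA) {
  const int B = dA.n_cols;
  dA.zeros();
  for (int b = 0; b < B; ++b) {
    float* dst = dA.colptr(b);
    for (int j = 0; j < d.Wo; ++j) {
      for (int i = 0; i < d.Ho; ++i) {
        const float* src = dcol.colptr((size_t)b * d.Ho * d.Wo +
                                       (size_t)j * d.Ho + i);
        for (int c = 0; c < d.Cin; ++c) {
          float* plane = dst + (size_t)c * d.Hin * d.Win;
          for (int kj = 0; kj < kernel; ++kj) {
            const int sj = j + kj - pad;
            const float* in = src + (c * kernel + kj) * kernel;
            if (sj < 0 || sj >= d.Win) continue;
            float* scol = plane + (size_t)sj * d.Hin;
            for (int ki = 0; ki < kernel; ++ki) {
              const int si = i + ki - pad;
              if (si >= 0 && si < d.Hin) scol[si] += in[ki];
            }
          }
        }
      }
    }
  }
}

// L2-norm pooling over pool x pool windows of the (already ReLU'd) conv
// output Y (M x Ho*Wo*B, conv layout) into the next activation layout
// (M*Hp*Wp x B). Stores the pooled norms for the backward pass.
void l2pool_forward(const fmat& Y, const StageDims& d, int M, int pool, int B,
                    fmat& P) {
  P.set_size((size_t)M * d.Hp * d.Wp, B);
  std::vector<float> acc(M);
  for (int b = 0; b < B; ++b) {
    float* dst = P.colptr(b);
    for (int j = 0; j < d.Wp; ++j) {
      for (int i = 0; i < d.Hp; ++i) {
        std::fill(acc.begin(), acc.end(), 0.0f);
        for (int pj = 0; pj < pool; ++pj) {
          for (int pi = 0; pi < pool; ++pi) {
            const float* yc = Y.colptr((size_t)b * d.Ho * d.Wo +
                                       (size_t)(j * pool + pj) * d.Ho +
                                       (i * pool + pi));
            for (int m = 0; m < M; ++m) acc[m] += yc[m] * yc[m];
          }
        }
        float* out = dst + (size_t)i + (size_t)j * d.Hp;
        for (int m = 0; m < M; ++m)
          out[(size_t)m * d.Hp * d.Wp] = std::sqrt(acc[m]);
      }
    }
  }
}

// dP (M*Hp*Wp x B) -> dY (M x Ho*Wo*B): d sqrt(sum y^2) / dy = y / norm.
void l2pool_backward(const fmat& dP, const fmat& P, const fmat& Y,
                     const StageDims& d, int M, int pool, int B, fmat& dY) {
  dY.zeros(Y.n_rows, Y.n_cols);
  const float eps = 1e-8f;
  std::vector<float> g(M);
  for (int b = 0; b < B; ++b) {
    const float* dp = dP.colptr(b);
    const float* pp = P.colptr(b);
    for (int j = 0; j < d.Wp; ++j) {
      for (int i = 0; i < d.Hp; ++i) {
        const size_t base = (size_t)i + (size_t)j * d.Hp;
        for (int m = 0; m < M; ++m) {
          const size_t pidx = base + (size_t)m * d.Hp * d.Wp;
          g[m] = dp[pidx] / std::max(pp[pidx], eps);
        }
        for (int pj = 0; pj < pool; ++pj) {
          for (int pi = 0; pi < pool; ++pi) {
            const size_t cidx = (size_t)b * d.Ho * d.Wo +
              (size_t)(j * pool + pj) * d.Ho + (i * pool + pi);
            const float* yc = Y.colptr(cidx);
            float* dyc = dY.colptr(cidx);
            for (int m = 0; m < M; ++m) dyc[m] += g[m] * yc[m];
          }
        }
      }
    }
  }
}

struct Params {
  std::vector<fmat> Wc;   // conv weights, maps x (Cin*k*k)
  std::vector<fvec> bc;
  fmat W1; fvec b1;       // fully connected hidden
  fmat W2; fvec b2;       // softmax output
};

Params init_params(const Arch& a, std::mt19937& rng) {
  Params p;
  auto dims = stage_dims(a);
  auto draw = [&](fmat& m, int fan_in) {
    const float lim = std::sqrt(6.0f / (float)fan_in);
    std::uniform_real_distribution<float> u(-lim, lim);
    for (uword i = 0; i < m.n_elem; ++i) m(i) = u(rng);
  };
  for (size_t s = 0; s < a.maps.size(); ++s) {
    const int K = dims[s].Cin * a.kernel * a.kernel;
    fmat w(a.maps[s], K);
    draw(w, K);
    p.Wc.push_back(w);
    p.bc.push_back(fvec(a.maps[s], fill::zeros));
  }
  const int D = flat_dim(a);
  p.W1.set_size(a.fc_units, D); draw(p.W1, D);
  p.b1.zeros(a.fc_units);
  p.W2.set_size(a.n_class, a.fc_units); draw(p.W2, a.fc_units);
  p.b2.zeros(a.n_class);
  return p;
}

struct ForwardCache {
  std::vector<fmat> cols;   // im2col matrices per stage
  std::vector<fmat> Y;      // post-ReLU conv outputs per stage
  std::vector<fmat> P;      // pooled activations per stage (next-layer input)
  fmat a_flat;              // input to FC block (== P.back() or input)
  fmat h;                   // FC hidden post-ReLU
  fmat probs;               // n_class x B
};

void forward(const fmat& Xb, const Arch& a, const Params& p,
             const std::vector<StageDims>& dims, ForwardCache& fc,
             bool keep_cache) {
  const int B = Xb.n_cols;
  fc.cols.clear(); fc.Y.clear(); fc.P.clear();
  fmat A = Xb;
  for (size_t s = 0; s < a.maps.size(); ++s) {
    const StageDims& d = dims[s];
    fmat col;
    im2col(A, d, a.kernel, a.pad, col);
    fmat Y = p.Wc[s] * col;
    Y.each_col() += p.bc[s];
    Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });  // ReLU
    fmat P;
    l2pool_forward(Y, d, a.maps[s], a.pool, B, P);
    if (keep_cache) {
      fc.cols.push_back(std::move(col));
      fc.Y.push_back(std::move(Y));
      fc.P.push_back(P);
    }
    A = std::move(P);
  }
  fc.a_flat = A;
  fc.h = p.W1 * fc.a_flat;
  fc.h.each_col() += p.b1;
  fc.h.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fmat logits = p.W2 * fc.h;
  logits.each_col() += p.b2;
  logits.each_row() -= max(logits, 0);
  fmat e = exp(logits);
  frowvec denom = sum(e, 0);
  e.each_row() /= denom;
  fc.probs = std::move(e);
}

void backward_and_update(const fmat& Xb, const uvec& yb, const Arch& a,
                         Params& p, const std::vector<StageDims>& dims,
                         ForwardCache& fc, float lr_t) {
  const int B = Xb.n_cols;
  fmat dlogits = fc.probs;                       // p - onehot, averaged
  for (int b = 0; b < B; ++b) dlogits(yb(b), b) -= 1.0f;
  dlogits /= (float)B;

  fmat dW2 = dlogits * fc.h.t();
  fvec db2 = sum(dlogits, 1);
  fmat dh = p.W2.t() * dlogits;
  for (uword t = 0; t < dh.n_elem; ++t) if (fc.h[t] <= 0.0f) dh[t] = 0.0f;
  fmat dW1 = dh * fc.a_flat.t();
  fvec db1 = sum(dh, 1);
  fmat dA = p.W1.t() * dh;

  const int n_stage = (int)a.maps.size();
  std::vector<fmat> dWc(n_stage);
  std::vector<fvec> dbc(n_stage);
  for (int s = n_stage - 1; s >= 0; --s) {
    const StageDims& d = dims[s];
    fmat dY;
    l2pool_backward(dA, fc.P[s], fc.Y[s], d, a.maps[s], a.pool, B, dY);
    const fmat& Ys = fc.Y[s];                   // ReLU gate
    for (uword t = 0; t < dY.n_elem; ++t) if (Ys[t] <= 0.0f) dY[t] = 0.0f;
    dWc[s] = dY * fc.cols[s].t();
    dbc[s] = sum(dY, 1);
    if (s > 0) {
      fmat dcol = p.Wc[s].t() * dY;
      dA.set_size((size_t)d.Cin * d.Hin * d.Win, B);
      col2im(dcol, d, a.kernel, a.pad, dA);
    }
  }

  for (int s = 0; s < n_stage; ++s) {
    p.Wc[s] -= lr_t * dWc[s];
    p.bc[s] -= lr_t * dbc[s];
  }
  p.W1 -= lr_t * dW1; p.b1 -= lr_t * db1;
  p.W2 -= lr_t * dW2; p.b2 -= lr_t * db2;
}

Arch make_arch(int H, int W, int C, const Rcpp::IntegerVector& maps,
               int fc_units, int kernel, int pad, int pool) {
  Arch a;
  a.H = H; a.W = W; a.C = C;
  a.maps = std::vector<int>(maps.begin(), maps.end());
  a.fc_units = fc_units; a.kernel = kernel; a.pad = pad; a.pool = pool;
  a.n_class = 2;
  return a;
}

Params params_from_list(const Rcpp::List& w, const Arch& a) {
  Params p;
  Rcpp::List conv = w["conv"];
  for (int s = 0; s < (int)a.maps.size(); ++s) {
    Rcpp::List st = conv[s];
    p.Wc.push_back(conv_to<fmat>::from(Rcpp::as<mat>(st["W"])));
    p.bc.push_back(conv_to<fvec>::from(Rcpp::as<vec>(st["b"])));
  }
  p.W1 = conv_to<fmat>::from(Rcpp::as<mat>(w["fc_W"]));
  p.b1 = conv_to<fvec>::from(Rcpp::as<vec>(w["fc_b"]));
  p.W2 = conv_to<fmat>::from(Rcpp::as<mat>(w["out_W"]));
  p.b2 = conv_to<fvec>::from(Rcpp::as<vec>(w["out_b"]));
  return p;
}

Rcpp::List params_to_list(const Params& p) {
  Rcpp::List conv(p.Wc.size());
  for (size_t s = 0; s < p.Wc.size(); ++s) {
    conv[s] = Rcpp::List::create(
      Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(p.Wc[s])),
      Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(p.bc[s])));
  }
  return Rcpp::List::create(
    Rcpp::Named("conv") = conv,
    Rcpp::Named("fc_W") = Rcpp::wrap(conv_to<mat>::from(p.W1)),
    Rcpp::Named("fc_b") = Rcpp::wrap(conv_to<vec>::from(p.b1)),
    Rcpp::Named("out_W") = Rcpp::wrap(conv_to<mat>::from(p.W2)),
    Rcpp::Named("out_b") = Rcpp::wrap(conv_to<vec>::from(p.b2)));
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::mat& X, const arma::ivec& y,
                         int H, int W, int C,
                         Rcpp::IntegerVector maps, int fc_units,
                         int kernel, int pad, int pool,
                         int epochs, int batch_size,
                         double lr, double lr_decay, int seed) {
  flush_denormals();
  Arch a = make_arch(H, W, C, maps, fc_units, kernel, pad, pool);
  auto dims = stage_dims(a);
  const int n = X.n_cols;
  if ((int)X.n_rows != H * W * C) Rcpp::stop("patch dimension mismatch");
  if (n != (int)y.n_elem) Rcpp::stop("label count mismatch");

  fmat Xf = conv_to<fmat>::from(X);
  uvec yv(n);
  for (int i = 0; i < n; ++i) {
    if (y(i) != 0 && y(i) != 1) Rcpp::stop("labels must be 0/1");
    yv(i) = (uword)y(i);
  }

  std::mt19937 rng((unsigned)seed);
  Params p = init_params(a, rng);

  std::vector<uword> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Rcpp::NumericVector ep_loss(epochs), ep_acc(epochs);
  long t = 0;  // global update counter
  ForwardCache fc;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    long correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int B = std::min(batch_size, n - start);
      uvec idx(B);
      for (int i = 0; i < B; ++i) idx(i) = order[start + i];
      fmat Xb = Xf.cols(idx);
      uvec yb = yv.elem(idx);
      forward(Xb, a, p, dims, fc, true);
      for (int b = 0; b < B; ++b) {
        const float pr = std::max(fc.probs(yb(b), b), 1e-12f);
        loss_sum += -std::log((double)pr);
        const uword pred = fc.probs(1, b) >= fc.probs(0, b) ? 1 : 0;
        if (pred == yb(b)) ++correct;
      }
      const float lr_t = (float)(lr / (1.0 + lr_decay * (double)t));
      if (lr_t > 0.0f) backward_and_update(Xb, yb, a, p, dims, fc, lr_t);
      ++t;
      Rcpp::checkUserInterrupt();
    }
    ep_loss[ep] = loss_sum / n;
    ep_acc[ep] = (double)correct / n;
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = params_to_list(p),
    Rcpp::Named("history") = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = Rcpp::seq(1, epochs),
      Rcpp::Named("loss") = ep_loss,
      Rcpp::Named("accuracy") = ep_acc));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cnn_predict_cpp(const arma::mat& X, Rcpp::List weights,
                                    int H, int W, int C,
                                    Rcpp::IntegerVector maps, int fc_units,
                                    int kernel, int pad, int pool,
                                    int batch_size = 64) {
  flush_denormals();
  Arch a = make_arch(H, W, C, maps, fc_units, kernel, pad, pool);
  auto dims = stage_dims(a);
  if ((int)X.n_rows != H * W * C) Rcpp::stop("patch dimension mismatch");
  const int n = X.n_cols;
  fmat Xf = conv_to<fmat>::from(X);
  Params p = params_from_list(weights, a);
  Rcpp::NumericMatrix out(n, 2);
  ForwardCache fc;
  for (int start = 0; start < n; start += batch_size) {
    const int B = std::min(batch_size, n - start);
    fmat Xb = Xf.cols(start, start + B - 1);
    forward(Xb, a, p, dims, fc, false);
    for (int b = 0; b < B; ++b) {
      out(start + b, 0) = fc.probs(0, b);
      out(start + b, 1) = fc.probs(1, b);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
int cnn_flat_dim_cpp(int H, int W, int C, Rcpp::IntegerVector maps,
                     int kernel, int pad, int pool) {
  Arch a = make_arch(H, W, C, maps, 1, kernel, pad, pool);
  return flat_dim(a);
}
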