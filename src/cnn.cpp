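// 1-D convolutional network for spectral classification.
//
// Fixed topology: conv(K) -> ReLU -> maxpool -> batchnorm ->
//                 conv(K) -> ReLU -> maxpool -> batchnorm ->
//                 flatten -> dense -> ReLU -> dense -> ReLU -> dense -> softmax
// with channel counts, kernel/pool sizes and dense widths taken from the
// config. Trained with plain SGD (optional momentum) on softmax
// cross-entropy. Single precision throughout; convolutions are im2col GEMMs.
// All randomness (init, shuffling) flows from one std::mt19937 seed, so a
// run is reproducible bit-for-bit on a given platform.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
#include <cstring>

using namespace arma;

namespace {

struct Shapes {
  int nb, K, pool, c1, c2, d1, d2, ncls;
  int P1, Q1, P2, Q2, flat;
};

Shapes make_shapes(int nb, int K, int pool, int c1, int c2, int d1, int d2,
                   int ncls) {
  Shapes s;
  s.nb = nb; s.K = K; s.pool = pool; s.c1 = c1; s.c2 = c2;
  s.d1 = d1; s.d2 = d2; s.ncls = ncls;
  s.P1 = nb - K + 1;
  s.Q1 = s.P1 / pool;
  s.P2 = s.Q1 - K + 1;
  s.Q2 = s.P2 / pool;
  if (s.P1 < 1 || s.Q1 < 1 || s.P2 < 1 || s.Q2 < 1)
    Rcpp::stop("input too short for the conv/pool stack: %d bands", nb);
  s.flat = s.Q2 * c2;
  return s;
}

struct Params {
  fmat W1, W2, W3, W4, W5;
  frowvec b1, b2, b3, b4, b5;
  frowvec g1, be1, rm1, rv1;
  frowvec g2, be2, rm2, rv2;
};

void he_init(fmat &W, int fan_in, std::mt19937 &rng) {
  std::normal_distribution<float> N(0.0f, std::sqrt(2.0f / fan_in));
  for (uword j = 0; j < W.n_cols; ++j)
    for (uword i = 0; i < W.n_rows; ++i) W(i, j) = N(rng);
}

Params init_params(const Shapes &s, std::mt19937 &rng) {
  Params p;
  p.W1.set_size(s.K, s.c1);            he_init(p.W1, s.K, rng);
  p.W2.set_size(s.K * s.c1, s.c2);     he_init(p.W2, s.K * s.c1, rng);
  p.W3.set_size(s.flat, s.d1);         he_init(p.W3, s.flat, rng);
  p.W4.set_size(s.d1, s.d2);           he_init(p.W4, s.d1, rng);
  p.W5.set_size(s.d2, s.ncls);         he_init(p.W5, s.d2, rng);
  p.b1.zeros(s.c1); p.b2.zeros(s.c2); p.b3.zeros(s.d1);
  p.b4.zeros(s.d2); p.b5.zeros(s.ncls);
  p.g1.ones(s.c1);  p.be1.zeros(s.c1); p.rm1.zeros(s.c1); p.rv1.ones(s.c1);
  p.g2.ones(s.c2);  p.be2.zeros(s.c2); p.rm2.zeros(s.c2); p.rv2.ones(s.c2);
  return p;
}

// im2col for 1-D conv over blocks of P_out positions within blocks of P_in
// rows per sample. In: A ((B*P_in) x C). Out: ((B*P_out) x (K*C)), column
// block k holds A shifted by k. Raw-pointer copies: the generic submatrix
// path is the hot spot otherwise.
fmat im2col(const fmat &A, int B, int P_in, int P_out, int K) {
  const int C = A.n_cols;
  fmat out(B * P_out, K * C);
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c) {
      const float *src = A.colptr(c);
      float *dst = out.colptr(k * C + c);
      for (int b = 0; b < B; ++b)
        std::memcpy(dst + b * P_out, src + b * P_in + k,
                    P_out * sizeof(float));
    }
  return out;
}

// reverse of im2col: accumulate gradient blocks back onto dA ((B*P_in) x C).
void col2im_add(fmat &dA, const fmat &dCol, int B, int P_in, int P_out,
                int K) {
  const int C = dA.n_cols;
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c) {
      float *dst = dA.colptr(c);
      const float *src = dCol.colptr(k * C + c);
      for (int b = 0; b < B; ++b) {
        float *d = dst + b * P_in + k;
        const float *sc = src + b * P_out;
        for (int p = 0; p < P_out; ++p) d[p] += sc[p];
      }
    }
}

// max pool over non-overlapping windows of `pool` positions within blocks
// of P rows per sample; records the source row of each maximum.
fmat maxpool(const fmat &A, int B, int P, int Q, int pool, umat &amax) {
  const int C = A.n_cols;
  const int nr_in = A.n_rows;
  fmat out(B * Q, C);
  amax.set_size(B * Q, C);
  for (int c = 0; c < C; ++c) {
    const float *ac = A.colptr(c);
    float *oc = out.colptr(c);
    uword *mc = amax.colptr(c);
    (void)nr_in;
    for (int b = 0; b < B; ++b)
      for (int q = 0; q < Q; ++q) {
        const int base = b * P + q * pool;
        float best = ac[base];
        int besti = base;
        for (int j = 1; j < pool; ++j)
          if (ac[base + j] > best) { best = ac[base + j]; besti = base + j; }
        oc[b * Q + q] = best;
        mc[b * Q + q] = besti;
      }
  }
  return out;
}

void unpool_add(fmat &dA, const fmat &dOut, const umat &amax) {
  for (uword c = 0; c < dOut.n_cols; ++c) {
    float *dc = dA.colptr(c);
    const float *oc = dOut.colptr(c);
    const uword *mc = amax.colptr(c);
    for (uword r = 0; r < dOut.n_rows; ++r) dc[mc[r]] += oc[r];
  }
}

struct BNCache { fmat xhat; frowvec invstd; };

// batchnorm over rows, per column. In training mode uses batch statistics
// and updates the running ones; in eval mode uses the running statistics.
fmat bn_forward(const fmat &X, frowvec &gamma, frowvec &beta, frowvec &rmean,
                frowvec &rvar, float eps, float momentum, bool training,
                BNCache *cache) {
  frowvec mu, var;
  if (training) {
    mu = mean(X, 0);
    var = mean(square(X.each_row() - mu), 0);  // biased, as used for norm
    rmean = (1.0f - momentum) * rmean + momentum * mu;
    rvar = (1.0f - momentum) * rvar + momentum * var;
  } else {
    mu = rmean;
    var = rvar;
  }
  frowvec invstd = 1.0f / sqrt(var + eps);
  fmat out(X.n_rows, X.n_cols);
  if (cache) {
    cache->xhat.set_size(X.n_rows, X.n_cols);
    cache->invstd = invstd;
  }
  const uword nr = X.n_rows;
  for (uword c = 0; c < X.n_cols; ++c) {
    const float m = mu(c), is = invstd(c), ga = gamma(c), be = beta(c);
    const float *x = X.colptr(c);
    float *o = out.colptr(c);
    if (cache) {
      float *xh = cache->xhat.colptr(c);
      for (uword r = 0; r < nr; ++r) {
        const float h = (x[r] - m) * is;
        xh[r] = h;
        o[r] = ga * h + be;
      }
    } else {
      const float a = ga * is, b0 = be - ga * m * is;
      for (uword r = 0; r < nr; ++r) o[r] = a * x[r] + b0;
    }
  }
  return out;
}

// transforms d (the gradient w.r.t. the BN output) into the gradient
// w.r.t. the BN input, in place and allocation-free
void bn_backward_inplace(fmat &d, const BNCache &cache, const frowvec &gamma,
                         frowvec &dgamma, frowvec &dbeta) {
  const uword nr = d.n_rows;
  const float N = nr;
  dgamma.set_size(d.n_cols);
  dbeta.set_size(d.n_cols);
  for (uword c = 0; c < d.n_cols; ++c) {
    float *dc = d.colptr(c);
    const float *xh = cache.xhat.colptr(c);
    const float ga = gamma(c);
    double s0 = 0.0, s1 = 0.0, s2 = 0.0;
    for (uword r = 0; r < nr; ++r) {
      s0 += dc[r];
      s1 += dc[r] * ga;
      s2 += dc[r] * ga * xh[r];
    }
    double sg = 0.0;
    for (uword r = 0; r < nr; ++r) sg += dc[r] * xh[r];
    dgamma(c) = (float)sg;
    dbeta(c) = (float)s0;
    const float m1 = (float)(s1 / N), m2 = (float)(s2 / N);
    const float is = cache.invstd(c);
    for (uword r = 0; r < nr; ++r)
      dc[r] = (dc[r] * ga - m1 - xh[r] * m2) * is;
  }
}

struct Cache {
  fmat C1, A1, M1, B1, C2, A2, M2, B2, Ft, H1, H2, P;
  umat idx1, idx2;
  BNCache bn1, bn2;
};

// Forward pass; Xt is the transposed batch (nb x B). Returns class
// probabilities (B x ncls).
fmat forward(const fmat &Xt, Params &p, const Shapes &s, float eps,
             float momentum, bool training, Cache *cc) {
  const int B = Xt.n_cols;
  Cache local;
  Cache &c = cc ? *cc : local;
  // conv1 via im2col on the raw spectra
  c.C1.set_size(B * s.P1, s.K);
  for (int k = 0; k < s.K; ++k)
    c.C1.col(k) = vectorise(Xt.rows(k, k + s.P1 - 1));
  c.A1 = c.C1 * p.W1;
  c.A1.each_row() += p.b1;
  c.A1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  c.M1 = maxpool(c.A1, B, s.P1, s.Q1, s.pool, c.idx1);
  c.B1 = bn_forward(c.M1, p.g1, p.be1, p.rm1, p.rv1, eps, momentum, training,
                    training ? &c.bn1 : nullptr);
  // conv2
  c.C2 = im2col(c.B1, B, s.Q1, s.P2, s.K);
  c.A2 = c.C2 * p.W2;
  c.A2.each_row() += p.b2;
  c.A2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  c.M2 = maxpool(c.A2, B, s.P2, s.Q2, s.pool, c.idx2);
  c.B2 = bn_forward(c.M2, p.g2, p.be2, p.rm2, p.rv2, eps, momentum, training,
                    training ? &c.bn2 : nullptr);
  // flatten, stored transposed (flat x B) so the dense head is plain GEMM;
  // within a sample the order is channel-major (c * Q2 + q)
  c.Ft.set_size(s.flat, B);
  for (int c2i = 0; c2i < s.c2; ++c2i) {
    const float *src = c.B2.colptr(c2i);
    for (int b = 0; b < B; ++b)
      std::memcpy(c.Ft.colptr(b) + c2i * s.Q2, src + b * s.Q2,
                  s.Q2 * sizeof(float));
  }
  c.H1 = c.Ft.t() * p.W3;
  c.H1.each_row() += p.b3;
  c.H1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  c.H2 = c.H1 * p.W4;
  c.H2.each_row() += p.b4;
  c.H2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fmat Z = c.H2 * p.W5;
  Z.each_row() += p.b5;
  Z.each_col() -= max(Z, 1);
  fmat E = exp(Z);
  c.P = E.each_col() / sum(E, 1);
  return c.P;
}

// zero gradient entries where the forward activation was clipped
void relu_mask(fmat &dX, const fmat &A) {
  float *d = dX.memptr();
  const float *a = A.memptr();
  const uword n = dX.n_elem;
  for (uword i = 0; i < n; ++i)
    if (a[i] <= 0.0f) d[i] = 0.0f;
}

struct Grads {
  fmat W1, W2, W3, W4, W5;
  frowvec b1, b2, b3, b4, b5, g1, be1, g2, be2;
};

// large reusable backward temporaries (avoid fresh page allocation per batch)
struct Workspace {
  fmat dZ, dH2, dH1, dFt, dB2, dA2, dC2, dB1, dA1;
};

float backward(const uvec &y, Params &p, const Shapes &s,
               Cache &c, Grads &g, Workspace &w, int &ncorrect) {
  const int B = y.n_elem;
  float loss = 0.0f;
  w.dZ = c.P;
  ncorrect = 0;
  for (int b = 0; b < B; ++b) {
    loss -= std::log(std::max(c.P(b, y(b)), 1e-30f));
    w.dZ(b, y(b)) -= 1.0f;
    if (c.P.row(b).index_max() == y(b)) ++ncorrect;
  }
  loss /= B;
  w.dZ /= (float)B;
  g.W5 = c.H2.t() * w.dZ;      g.b5 = sum(w.dZ, 0);
  w.dH2 = w.dZ * p.W5.t();
  relu_mask(w.dH2, c.H2);
  g.W4 = c.H1.t() * w.dH2;     g.b4 = sum(w.dH2, 0);
  w.dH1 = w.dH2 * p.W4.t();
  relu_mask(w.dH1, c.H1);
  g.W3 = c.Ft * w.dH1;         g.b3 = sum(w.dH1, 0);
  w.dFt = p.W3 * w.dH1.t();    // flat x B
  // unflatten (inverse of the channel-major transposed flatten)
  w.dB2.set_size(B * s.Q2, s.c2);
  for (int c2i = 0; c2i < s.c2; ++c2i) {
    float *dst = w.dB2.colptr(c2i);
    for (int b = 0; b < B; ++b)
      std::memcpy(dst + b * s.Q2, w.dFt.colptr(b) + c2i * s.Q2,
                  s.Q2 * sizeof(float));
  }
  bn_backward_inplace(w.dB2, c.bn2, p.g2, g.g2, g.be2);
  w.dA2.zeros(B * s.P2, s.c2);
  unpool_add(w.dA2, w.dB2, c.idx2);
  relu_mask(w.dA2, c.A2);
  g.W2 = c.C2.t() * w.dA2;     g.b2 = sum(w.dA2, 0);
  w.dC2 = w.dA2 * p.W2.t();
  w.dB1.zeros(B * s.Q1, s.c1);
  col2im_add(w.dB1, w.dC2, B, s.Q1, s.P2, s.K);
  bn_backward_inplace(w.dB1, c.bn1, p.g1, g.g1, g.be1);
  w.dA1.zeros(B * s.P1, s.c1);
  unpool_add(w.dA1, w.dB1, c.idx1);
  relu_mask(w.dA1, c.A1);
  g.W1 = c.C1.t() * w.dA1;     g.b1 = sum(w.dA1, 0);
  return loss;
}

template <typename M>
void sgd_step(M &param, M &vel, const M &grad, float lr, float mom) {
  if (mom > 0.0f) {
    vel = mom * vel - lr * grad;
    param += vel;
  } else {
    param -= lr * grad;
  }
}

fmat as_fmat(const Rcpp::NumericMatrix &X) {
  fmat out(X.nrow(), X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i) out(i, j) = (float)X(i, j);
  return out;
}

Params params_from_list(const Rcpp::List &w) {
  Params p;
  p.W1 = as_fmat(w["W1"]); p.W2 = as_fmat(w["W2"]); p.W3 = as_fmat(w["W3"]);
  p.W4 = as_fmat(w["W4"]); p.W5 = as_fmat(w["W5"]);
  auto rv = [&](const char *nm) {
    Rcpp::NumericVector v = w[nm];
    frowvec out(v.size());
    for (int i = 0; i < v.size(); ++i) out(i) = (float)v[i];
    return out;
  };
  p.b1 = rv("b1"); p.b2 = rv("b2"); p.b3 = rv("b3"); p.b4 = rv("b4");
  p.b5 = rv("b5");
  p.g1 = rv("g1"); p.be1 = rv("be1"); p.rm1 = rv("rm1"); p.rv1 = rv("rv1");
  p.g2 = rv("g2"); p.be2 = rv("be2"); p.rm2 = rv("rm2"); p.rv2 = rv("rv2");
  return p;
}

Rcpp::List params_to_list(const Params &p) {
  auto m = [](const fmat &x) { return Rcpp::wrap(conv_to<mat>::from(x)); };
  auto v = [](const frowvec &x) {
    return Rcpp::wrap(conv_to<rowvec>::from(x));
  };
  return Rcpp::List::create(
      Rcpp::Named("W1") = m(p.W1), Rcpp::Named("b1") = v(p.b1),
      Rcpp::Named("g1") = v(p.g1), Rcpp::Named("be1") = v(p.be1),
      Rcpp::Named("rm1") = v(p.rm1), Rcpp::Named("rv1") = v(p.rv1),
      Rcpp::Named("W2") = m(p.W2), Rcpp::Named("b2") = v(p.b2),
      Rcpp::Named("g2") = v(p.g2), Rcpp::Named("be2") = v(p.be2),
      Rcpp::Named("rm2") = v(p.rm2), Rcpp::Named("rv2") = v(p.rv2),
      Rcpp::Named("W3") = m(p.W3), Rcpp::Named("b3") = v(p.b3),
      Rcpp::Named("W4") = m(p.W4), Rcpp::Named("b4") = v(p.b4),
      Rcpp::Named("W5") = m(p.W5), Rcpp::Named("b5") = v(p.b5));
}

Shapes shapes_from_cfg(const Rcpp::List &cfg, int nb) {
  return make_shapes(nb, Rcpp::as<int>(cfg["kernel_size"]),
                     Rcpp::as<int>(cfg["pool_size"]),
                     Rcpp::as<int>(cfg["conv1"]), Rcpp::as<int>(cfg["conv2"]),
                     Rcpp::as<int>(cfg["dense1"]),
                     Rcpp::as<int>(cfg["dense2"]),
                     Rcpp::as<int>(cfg["n_classes"]));
}

fmat predict_eval(const fmat &Xt, Params &p, const Shapes &s, float eps,
                  int chunk = 1024) {
  fmat out(Xt.n_cols, s.ncls);
  for (uword lo = 0; lo < Xt.n_cols; lo += chunk) {
    uword hi = std::min<uword>(lo + chunk, Xt.n_cols) - 1;
    out.rows(lo, hi) =
        forward(Xt.cols(lo, hi), p, s, eps, 0.0f, false, nullptr);
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::NumericMatrix X, Rcpp::IntegerVector y,
                         SEXP Xval, SEXP yval, Rcpp::List cfg) {
  const fmat Xft = as_fmat(X).t();  // nb x n, contiguous per spectrum
  const int n = Xft.n_cols;
  uvec yv(n);
  for (int i = 0; i < n; ++i) yv(i) = y[i];  // 0-based classes
  Shapes s = shapes_from_cfg(cfg, Xft.n_rows);
  const float lr = Rcpp::as<float>(cfg["lr"]);
  const float mom = Rcpp::as<float>(cfg["momentum"]);
  const float eps = Rcpp::as<float>(cfg["bn_eps"]);
  const float bn_mom = Rcpp::as<float>(cfg["bn_momentum"]);
  const int epochs = Rcpp::as<int>(cfg["epochs"]);
  const int batch = Rcpp::as<int>(cfg["batch_size"]);
  const unsigned seed = Rcpp::as<unsigned>(cfg["seed"]);

  bool has_val = !Rf_isNull(Xval);
  fmat Xv;
  uvec yvv;
  if (has_val) {
    Xv = as_fmat(Rcpp::as<Rcpp::NumericMatrix>(Xval)).t();
    Rcpp::IntegerVector yvr(yval);
    yvv.set_size(yvr.size());
    for (int i = 0; i < yvr.size(); ++i) yvv(i) = yvr[i];
  }

  std::mt19937 rng(seed);
  Params p = init_params(s, rng);
  Grads vel;  // momentum buffers, zero-initialized lazily via Grads of zeros
  vel.W1.zeros(size(p.W1)); vel.W2.zeros(size(p.W2));
  vel.W3.zeros(size(p.W3)); vel.W4.zeros(size(p.W4));
  vel.W5.zeros(size(p.W5));
  vel.b1.zeros(s.c1); vel.b2.zeros(s.c2); vel.b3.zeros(s.d1);
  vel.b4.zeros(s.d2); vel.b5.zeros(s.ncls);
  vel.g1.zeros(s.c1); vel.be1.zeros(s.c1);
  vel.g2.zeros(s.c2); vel.be2.zeros(s.c2);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Rcpp::NumericVector h_loss(epochs), h_tracc(epochs), h_valacc(epochs);
  Cache cache;
  Grads g;
  Workspace ws;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    int ep_correct = 0, ep_seen = 0;
    for (int lo = 0; lo < n; lo += batch) {
      int hi = std::min(lo + batch, n);
      int B = hi - lo;
      if (B < 2 && n >= 2) continue;  // batchnorm needs >= 2 rows
      fmat Xbt(s.nb, B);
      uvec yb(B);
      for (int i = 0; i < B; ++i) {
        Xbt.col(i) = Xft.col(order[lo + i]);
        yb(i) = yv(order[lo + i]);
      }
      forward(Xbt, p, s, eps, bn_mom, true, &cache);
      int ncorrect = 0;
      float loss = backward(yb, p, s, cache, g, ws, ncorrect);
      ep_loss += (double)loss * B;
      ep_correct += ncorrect;
      ep_seen += B;
      sgd_step(p.W1, vel.W1, g.W1, lr, mom);
      sgd_step(p.b1, vel.b1, g.b1, lr, mom);
      sgd_step(p.g1, vel.g1, g.g1, lr, mom);
      sgd_step(p.be1, vel.be1, g.be1, lr, mom);
      sgd_step(p.W2, vel.W2, g.W2, lr, mom);
      sgd_step(p.b2, vel.b2, g.b2, lr, mom);
      sgd_step(p.g2, vel.g2, g.g2, lr, mom);
      sgd_step(p.be2, vel.be2, g.be2, lr, mom);
      sgd_step(p.W3, vel.W3, g.W3, lr, mom);
      sgd_step(p.b3, vel.b3, g.b3, lr, mom);
      sgd_step(p.W4, vel.W4, g.W4, lr, mom);
      sgd_step(p.b4, vel.b4, g.b4, lr, mom);
      sgd_step(p.W5, vel.W5, g.W5, lr, mom);
      sgd_step(p.b5, vel.b5, g.b5, lr, mom);
    }
    h_loss[ep] = ep_seen ? ep_loss / ep_seen : NA_REAL;
    h_tracc[ep] = ep_seen ? (double)ep_correct / ep_seen : NA_REAL;
    if (has_val) {
      fmat Pv = predict_eval(Xv, p, s, eps);
      int ok = 0;
      for (uword i = 0; i < Pv.n_rows; ++i)
        if (Pv.row(i).index_max() == yvv(i)) ++ok;
      h_valacc[ep] = (double)ok / Pv.n_rows;
    } else {
      h_valacc[ep] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = params_to_list(p),
      Rcpp::Named("history") = Rcpp::DataFrame::create(
          Rcpp::Named("epoch") = Rcpp::seq_len(epochs),
          Rcpp::Named("train_loss") = h_loss,
          Rcpp::Named("train_acc") = h_tracc,
          Rcpp::Named("val_acc") = h_valacc),
      Rcpp::Named("flat_width") = s.flat,
      Rcpp::Named("feature_lengths") =
          Rcpp::IntegerVector::create(s.P1, s.Q1, s.P2, s.Q2));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cnn_predict_cpp(Rcpp::List weights, Rcpp::NumericMatrix X,
                                    Rcpp::List cfg) {
  fmat Xft = as_fmat(X).t();
  Shapes s = shapes_from_cfg(cfg, Xft.n_rows);
  Params p = params_from_list(weights);
  const float eps = Rcpp::as<float>(cfg["bn_eps"]);
  fmat P = predict_eval(Xft, p, s, eps);
  return Rcpp::wrap(conv_to<mat>::from(P));
}

// [[Rcpp::export]]
Rcpp::IntegerVector cnn_shape_trace_cpp(int n_bands, int kernel, int pool,
                                        int conv2_channels) {
  // trace the feature lengths the conv/pool stack actually produces
  Shapes s = make_shapes(n_bands, kernel, pool, 1, conv2_channels, 1, 1, 2);
  return Rcpp::IntegerVector::create(s.P1, s.Q1, s.P2, s.Q2, s.flat);
}
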