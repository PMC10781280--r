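// Convolutional network core: im2col-based forward/backward passes, Adam
// optimisation and binary cross-entropy, in single precision over BLAS GEMM.
// Layout conventions (fixed, internal):
//   * images are column-major cubes (rows H, cols W, slices = channels);
//   * an im2col matrix has one row per output position p = oi + oj*oh and
//     one column per tap q = c*k*k + kj*k + ki, i.e. input pixel
//     (oi+ki, oj+kj, c);
//   * a conv output stored as (oh*ow) x F matrix shares memory layout with
//     the cube (oh, ow, F), so no transposition is ever needed.
// All randomness (init, shuffling, dropout) comes from one std::mt19937
// seeded from R, so runs are bit-reproducible on a given BLAS.

#include <RcppArmadillo.h>
#include <random>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvDims {
  int h_in, w_in, c_in;   // input to the conv
  int h_cv, w_cv;         // after valid k x k conv
  int h_pl, w_pl;         // after 2x2 max pool (floor)
  int f;                  // filters
};

// Shape chain for a stack of (conv k x k valid -> ReLU -> 2x2 max pool) blocks.
std::vector<ConvDims> chain_dims(int h, int w, int c,
                                 const std::vector<int>& filters, int k) {
  std::vector<ConvDims> out;
  for (size_t b = 0; b < filters.size(); ++b) {
    ConvDims d;
    d.h_in = h; d.w_in = w; d.c_in = c; d.f = filters[b];
    d.h_cv = h - k + 1; d.w_cv = w - k + 1;
    if (d.h_cv <= 0 || d.w_cv <= 0)
      stop("convolution block %d would produce a non-positive side", (int)b + 1);
    d.h_pl = d.h_cv / 2; d.w_pl = d.w_cv / 2;
    if (d.h_pl <= 0 || d.w_pl <= 0)
      stop("pooling block %d would produce a non-positive side", (int)b + 1);
    out.push_back(d);
    h = d.h_pl; w = d.w_pl; c = d.f;
  }
  return out;
}

void im2col(const arma::fcube& x, int k, arma::fmat& col) {
  const int oh = (int)x.n_rows - k + 1, ow = (int)x.n_cols - k + 1;
  const int c_in = (int)x.n_slices;
  col.set_size(oh * (arma::uword)ow, (arma::uword)(k * k * c_in));
  for (int c = 0; c < c_in; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int q = c * k * k + kj * k + ki;
        float* dst = col.colptr(q);
        for (int oj = 0; oj < ow; ++oj) {
          const float* src = x.slice(c).colptr(oj + kj) + ki;
          std::memcpy(dst + (size_t)oj * oh, src, sizeof(float) * oh);
        }
      }
}

// Scatter-add of an im2col-shaped gradient back onto the input grid.
void col2im(const arma::fmat& dcol, int k, arma::fcube& dx) {
  const int h = (int)dx.n_rows, w = (int)dx.n_cols, c_in = (int)dx.n_slices;
  const int oh = h - k + 1, ow = w - k + 1;
  dx.zeros();
  for (int c = 0; c < c_in; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int q = c * k * k + kj * k + ki;
        const float* src = dcol.colptr(q);
        for (int oj = 0; oj < ow; ++oj) {
          float* dst = dx.slice(c).colptr(oj + kj) + ki;
          const float* s = src + (size_t)oj * oh;
          for (int oi = 0; oi < oh; ++oi) dst[oi] += s[oi];
        }
      }
}

// 2x2 stride-2 max pool; argmax stored as di + 2*dj in [0,4).
void maxpool(const arma::fcube& x, arma::fcube& y, arma::Cube<unsigned char>& idx) {
  const int oh = (int)x.n_rows / 2, ow = (int)x.n_cols / 2, f = (int)x.n_slices;
  y.set_size(oh, ow, f); idx.set_size(oh, ow, f);
  for (int c = 0; c < f; ++c) {
    const arma::fmat& xs = x.slice(c);
    for (int oj = 0; oj < ow; ++oj) {
      const float* in0 = xs.colptr(2 * oj);
      const float* in1 = xs.colptr(2 * oj + 1);
      float* out = y.slice_colptr(c, oj);
      unsigned char* oid = idx.slice_colptr(c, oj);
      for (int oi = 0; oi < oh; ++oi) {
        const float a = in0[2 * oi], b = in0[2 * oi + 1];
        const float e = in1[2 * oi], d = in1[2 * oi + 1];
        float best = a; unsigned char bi = 0;
        if (b > best) { best = b; bi = 1; }
        if (e > best) { best = e; bi = 2; }
        if (d > best) { best = d; bi = 3; }
        out[oi] = best; oid[oi] = bi;
      }
    }
  }
}

void maxpool_bwd(const arma::fcube& dy, const arma::Cube<unsigned char>& idx,
                 int h, int w, arma::fcube& dx) {
  const int oh = (int)dy.n_rows, ow = (int)dy.n_cols, f = (int)dy.n_slices;
  dx.set_size(h, w, f); dx.zeros();
  for (int c = 0; c < f; ++c) {
    arma::fmat& xs = dx.slice(c);
    for (int oj = 0; oj < ow; ++oj) {
      float* out0 = xs.colptr(2 * oj);
      float* out1 = xs.colptr(2 * oj + 1);
      const float* g = dy.slice_colptr(c, oj);
      const unsigned char* b = idx.slice_colptr(c, oj);
      for (int oi = 0; oi < oh; ++oi) {
        float* dst = (b[oi] & 2) ? out1 : out0;
        dst[2 * oi + (b[oi] & 1)] += g[oi];
      }
    }
  }
}

struct Params {
  std::vector<arma::fmat> Wc; std::vector<arma::frowvec> bc;  // conv
  arma::fmat W1; arma::frowvec b1;                            // dense hidden
  arma::fmat W2; arma::frowvec b2;                            // dense output
};

struct Arch {
  int h, w, c, k, dense;
  std::vector<int> filters;
  std::vector<ConvDims> dims;
  int flat;
};

Arch make_arch(int h, int w, int c, const IntegerVector& filters, int k, int dense) {
  Arch a; a.h = h; a.w = w; a.c = c; a.k = k; a.dense = dense;
  a.filters = as<std::vector<int>>(filters);
  a.dims = chain_dims(h, w, c, a.filters, k);
  const ConvDims& last = a.dims.back();
  a.flat = last.h_pl * last.w_pl * last.f;
  return a;
}

float glorot_limit(int fan_in, int fan_out) {
  return std::sqrt(6.0f / (float)(fan_in + fan_out));
}

Params init_params(const Arch& a, std::mt19937& rng) {
  Params p;
  auto fill = [&](arma::fmat& m, float lim) {
    std::uniform_real_distribution<float> u(-lim, lim);
    for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = u(rng);
  };
  for (const ConvDims& d : a.dims) {
    arma::fmat W(a.k * a.k * d.c_in, d.f);
    fill(W, glorot_limit(a.k * a.k * d.c_in, a.k * a.k * d.f));
    p.Wc.push_back(W);
    p.bc.push_back(arma::frowvec(d.f, arma::fill::zeros));
  }
  p.W1.set_size(a.flat, a.dense);
  fill(p.W1, glorot_limit(a.flat, a.dense));
  p.b1 = arma::frowvec(a.dense, arma::fill::zeros);
  p.W2.set_size(a.dense, 1);
  fill(p.W2, glorot_limit(a.dense, 1));
  p.b2 = arma::frowvec(1, arma::fill::zeros);
  return p;
}

// Convert image n of an integer (H,W,C,N) array in [0,255] to a float cube in [0,1].
arma::fcube load_image(const int* x, const Arch& a, size_t n) {
  arma::fcube out(a.h, a.w, a.c);
  const size_t npx = (size_t)a.h * a.w * a.c;
  const int* src = x + n * npx;
  float* dst = out.memptr();
  for (size_t i = 0; i < npx; ++i) dst[i] = (float)src[i] / 255.0f;
  return out;
}

// Forward through the conv stack; caches are optional (training mode).
// The im2col matrices themselves are cached so backward never regathers.
// All cache buffers are preallocated once and reused across batches and
// epochs: re-mapping ~30 MB of fresh pages per image each batch costs more
// than the GEMMs themselves.
struct ConvCache {
  std::vector<arma::fmat> cols;                    // im2col of each block input
  std::vector<arma::Cube<unsigned char>> relu;     // relu mask of conv output
  std::vector<arma::Cube<unsigned char>> poolidx;  // argmax of each pool
  std::vector<arma::fmat> z;                       // conv outputs (pre-pool)
  std::vector<arma::fcube> pooled;                 // pool outputs
  std::vector<arma::fcube> dz;                     // backward scratch
  std::vector<arma::fmat> dcol;                    // backward scratch
  void init(size_t nb) {
    cols.resize(nb); relu.resize(nb); poolidx.resize(nb);
    z.resize(nb); pooled.resize(nb); dz.resize(nb); dcol.resize(nb);
  }
};

arma::fvec conv_forward(const arma::fcube& x0, const Arch& a, const Params& p,
                        ConvCache& cache) {
  for (size_t b = 0; b < a.dims.size(); ++b) {
    const ConvDims& d = a.dims[b];
    im2col(b == 0 ? x0 : cache.pooled[b - 1], a.k, cache.cols[b]);
    arma::fmat& z = cache.z[b];
    z = cache.cols[b] * p.Wc[b];
    z.each_row() += p.bc[b];
    arma::Cube<unsigned char>& m = cache.relu[b];
    m.set_size(d.h_cv, d.w_cv, d.f);
    unsigned char* mm = m.memptr();
    float* zz = z.memptr();
    for (arma::uword i = 0; i < z.n_elem; ++i) {
      mm[i] = zz[i] > 0.0f; if (!mm[i]) zz[i] = 0.0f;
    }
    // view z as cube (h_cv, w_cv, f): identical memory layout, no copy
    arma::fcube zc(z.memptr(), d.h_cv, d.w_cv, d.f, false, true);
    maxpool(zc, cache.pooled[b], cache.poolidx[b]);
  }
  const arma::fcube& last = cache.pooled[a.dims.size() - 1];
  return arma::fvec(last.memptr(), a.flat);  // copy of flattened features
}

// Backward through the conv stack for one image; accumulates into gWc/gbc.
// The gradient flowing between blocks reuses the cache's dz buffers (block
// b's input gradient is written into dz[b-1]'s backing store via col2im).
void conv_backward(const arma::fvec& dflat, const Arch& a, const Params& p,
                   ConvCache& cache,
                   std::vector<arma::fmat>& gWc, std::vector<arma::frowvec>& gbc) {
  const int nb = (int)a.dims.size();
  const ConvDims& dl = a.dims[nb - 1];
  arma::fcube dcur(dl.h_pl, dl.w_pl, dl.f);
  std::memcpy(dcur.memptr(), dflat.memptr(), sizeof(float) * a.flat);
  for (int b = nb - 1; b >= 0; --b) {
    const ConvDims& d = a.dims[b];
    arma::fcube& dz = cache.dz[b];
    if (b == nb - 1) maxpool_bwd(dcur, cache.poolidx[b], d.h_cv, d.w_cv, dz);
    const unsigned char* mm = cache.relu[b].memptr();
    float* dd = dz.memptr();
    for (arma::uword i = 0; i < dz.n_elem; ++i) if (!mm[i]) dd[i] = 0.0f;
    arma::fmat dzm(dz.memptr(), (arma::uword)d.h_cv * d.w_cv, d.f, false, true);
    gWc[b] += cache.cols[b].t() * dzm;
    gbc[b] += arma::sum(dzm, 0);
    if (b > 0) {
      const ConvDims& dp = a.dims[b - 1];
      arma::fmat& dcol = cache.dcol[b];
      dcol = dzm * p.Wc[b].t();
      arma::fcube dx(dp.h_pl, dp.w_pl, dp.f);   // pooled-output gradient
      col2im(dcol, a.k, dx);
      maxpool_bwd(dx, cache.poolidx[b - 1], dp.h_cv, dp.w_cv, cache.dz[b - 1]);
    }
  }
}

// opt: 0 = Adam, 1 = plain SGD, 2 = RMSprop (decay beta2, no momentum).
// Fused single-pass loops: the dense weight block is large (flat x dense),
// so expression-template temporaries would double its memory traffic.
void opt_step(arma::fmat& w, const arma::fmat& g, arma::fmat& m, arma::fmat& v,
              float lr, float b1, float b2, float eps, int t, int opt) {
  const arma::uword n = w.n_elem;
  float* wp = w.memptr(); const float* gp = g.memptr();
  float* mp = m.memptr(); float* vp = v.memptr();
  if (opt == 1) {
    for (arma::uword i = 0; i < n; ++i) wp[i] -= lr * gp[i];
    return;
  }
  if (opt == 2) {
    for (arma::uword i = 0; i < n; ++i) {
      vp[i] = b2 * vp[i] + (1.0f - b2) * gp[i] * gp[i];
      wp[i] -= lr * gp[i] / (std::sqrt(vp[i]) + eps);
    }
    return;
  }
  const float c1 = 1.0f - std::pow(b1, (float)t);
  const float c2 = 1.0f - std::pow(b2, (float)t);
  for (arma::uword i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1.0f - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1.0f - b2) * gp[i] * gp[i];
    wp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
}

List params_to_list(const Params& p) {
  List conv_w(p.Wc.size()), conv_b(p.bc.size());
  for (size_t i = 0; i < p.Wc.size(); ++i) {
    conv_w[i] = wrap(arma::conv_to<arma::mat>::from(p.Wc[i]));
    conv_b[i] = wrap(arma::conv_to<arma::rowvec>::from(p.bc[i]));
  }
  return List::create(_["conv_w"] = conv_w, _["conv_b"] = conv_b,
                      _["dense_w"] = wrap(arma::conv_to<arma::mat>::from(p.W1)),
                      _["dense_b"] = wrap(arma::conv_to<arma::rowvec>::from(p.b1)),
                      _["out_w"] = wrap(arma::conv_to<arma::mat>::from(p.W2)),
                      _["out_b"] = wrap(arma::conv_to<arma::rowvec>::from(p.b2)));
}

Params params_from_list(const List& w) {
  Params p;
  List conv_w = w["conv_w"], conv_b = w["conv_b"];
  for (int i = 0; i < conv_w.size(); ++i) {
    p.Wc.push_back(arma::conv_to<arma::fmat>::from(as<arma::mat>(conv_w[i])));
    p.bc.push_back(arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(conv_b[i])));
  }
  p.W1 = arma::conv_to<arma::fmat>::from(as<arma::mat>(w["dense_w"]));
  p.b1 = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(w["dense_b"]));
  p.W2 = arma::conv_to<arma::fmat>::from(as<arma::mat>(w["out_w"]));
  p.b2 = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(w["out_b"]));
  return p;
}

double bce(const arma::fvec& prob, const arma::fvec& y) {
  double s = 0.0;
  for (arma::uword i = 0; i < prob.n_elem; ++i) {
    const double pc = std::min(std::max((double)prob(i), 1e-7), 1.0 - 1e-7);
    s += -(y(i) * std::log(pc) + (1.0 - y(i)) * std::log(1.0 - pc));
  }
  return s / prob.n_elem;
}

// Batched evaluation-mode prediction: conv per image, dense per chunk so
// the (flat x dense) weight matrix streams once per chunk, not per image.
arma::fvec predict_probs(const int* x, size_t n, const Arch& a, const Params& p) {
  arma::fvec out(n);
  const size_t chunk = 32;
  ConvCache scratch; scratch.init(a.dims.size());
  for (size_t start = 0; start < n; start += chunk) {
    const size_t bs = std::min(chunk, n - start);
    arma::fmat A(bs, a.flat);
    for (size_t i = 0; i < bs; ++i)
      A.row(i) = conv_forward(load_image(x, a, start + i), a, p, scratch).t();
    arma::fmat H1 = A * p.W1;
    H1.each_row() += p.b1;
    H1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    arma::fvec z = H1 * p.W2 + p.b2(0);
    for (size_t i = 0; i < bs; ++i)
      out(start + i) = 1.0f / (1.0f + std::exp(-z(i)));
  }
  return out;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_cnn_layer_dims")]]
IntegerMatrix cpp_cnn_layer_dims(int h, int w, int c, IntegerVector filters,
                                 int kernel, int dense) {
  Arch a = make_arch(h, w, c, filters, kernel, dense);
  // Rows: conv, pool per block (actual matrix dims), then flatten/dense/dropout/out.
  const int nb = (int)a.dims.size();
  IntegerMatrix out(2 * nb + 4, 3);
  int r = 0;
  for (const ConvDims& d : a.dims) {
    out(r, 0) = d.h_cv; out(r, 1) = d.w_cv; out(r, 2) = d.f; ++r;
    out(r, 0) = d.h_pl; out(r, 1) = d.w_pl; out(r, 2) = d.f; ++r;
  }
  out(r, 0) = a.flat;  out(r, 1) = 1; out(r, 2) = 1; ++r;
  out(r, 0) = a.dense; out(r, 1) = 1; out(r, 2) = 1; ++r;
  out(r, 0) = a.dense; out(r, 1) = 1; out(r, 2) = 1; ++r;
  out(r, 0) = 1;       out(r, 1) = 1; out(r, 2) = 1;
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_cnn_init")]]
List cpp_cnn_init(int h, int w, int c, IntegerVector filters, int kernel,
                  int dense, int seed) {
  Arch a = make_arch(h, w, c, filters, kernel, dense);
  std::mt19937 rng((unsigned)seed);
  return params_to_list(init_params(a, rng));
}

//' @noRd
// [[Rcpp::export(name = ".cpp_cnn_predict")]]
NumericVector cpp_cnn_predict(IntegerVector x, IntegerVector dim, List weights,
                              IntegerVector filters, int kernel, int dense) {
  Arch a = make_arch(dim[0], dim[1], dim[2], filters, kernel, dense);
  Params p = params_from_list(weights);
  const size_t n = (size_t)dim[3];
  arma::fvec probs = predict_probs(INTEGER(x), n, a, p);
  return wrap(arma::conv_to<arma::vec>::from(probs));
}

//' @noRd
// [[Rcpp::export(name = ".cpp_cnn_train")]]
List cpp_cnn_train(IntegerVector x, IntegerVector dim, NumericVector y,
                   IntegerVector filters, int kernel, int dense,
                   double dropout_rate, int epochs, int batch_size,
                   double lr, double beta1, double beta2, double adam_eps,
                   int optimizer, int seed,
                   Nullable<IntegerVector> val_x, Nullable<IntegerVector> val_dim,
                   Nullable<NumericVector> val_y) {
  Arch a = make_arch(dim[0], dim[1], dim[2], filters, kernel, dense);
  const int n = dim[3];
  if ((int)y.size() != n) stop("label count does not match image count");
#ifdef __GLIBC__
  // Keep the multi-MB transient buffers of each step inside the malloc
  // arena instead of round-tripping pages through mmap every mini-batch.
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
  std::mt19937 rng((unsigned)seed);
  Params p = init_params(a, rng);

  // Adam state
  Params m = p, v = p;
  auto zero_all = [](Params& q) {
    for (auto& w : q.Wc) w.zeros();
    for (auto& b : q.bc) b.zeros();
    q.W1.zeros(); q.b1.zeros(); q.W2.zeros(); q.b2.zeros();
  };
  zero_all(m); zero_all(v);

  const bool has_val = val_x.isNotNull();
  IntegerVector vx; NumericVector vy; int nval = 0;
  if (has_val) {
    vx = val_x.get(); vy = val_y.get();
    IntegerVector vd = val_dim.get();
    nval = vd[3];
  }

  const int* xp = INTEGER(x);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector h_loss(epochs, NA_REAL), h_acc(epochs, NA_REAL);
  NumericVector h_vloss(epochs, NA_REAL), h_vacc(epochs, NA_REAL);
  const float keep = 1.0f - (float)dropout_rate;
  bool diverged = false;
  int adam_t = 0, epochs_run = 0;

  std::vector<arma::fmat> gWc; std::vector<arma::frowvec> gbc;
  for (const ConvDims& d : a.dims) {
    gWc.push_back(arma::fmat(a.k * a.k * d.c_in, d.f));
    gbc.push_back(arma::frowvec(d.f));
  }
  std::vector<ConvCache> caches(batch_size);
  for (auto& c : caches) c.init(a.dims.size());
  arma::fmat gW1(a.flat, a.dense), gW2(a.dense, 1);
  arma::frowvec gb1(a.dense), gb2(1);

  for (int ep = 0; ep < epochs && !diverged; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0; int ep_correct = 0, nbatch = 0;
    for (int start = 0; start < n && !diverged; start += batch_size) {
      const int bs = std::min(batch_size, n - start);
      // conv forward, per image, caching what backward needs
      arma::fmat A(bs, a.flat);
      arma::fvec yb(bs);
      for (int i = 0; i < bs; ++i) {
        const int id = order[start + i];
        arma::fcube img = load_image(xp, a, (size_t)id);
        A.row(i) = conv_forward(img, a, p, caches[i]).t();
        yb(i) = (float)y[id];
      }
      // dense forward (batched)
      arma::fmat Z1 = A * p.W1;
      Z1.each_row() += p.b1;
      arma::Mat<unsigned char> relu1(bs, a.dense);
      for (arma::uword i = 0; i < Z1.n_elem; ++i) {
        relu1(i) = Z1(i) > 0.0f; if (!relu1(i)) Z1(i) = 0.0f;
      }
      arma::fmat drop(bs, a.dense, arma::fill::ones);
      if (dropout_rate > 0) {
        std::uniform_real_distribution<float> u(0.0f, 1.0f);
        for (arma::uword i = 0; i < drop.n_elem; ++i)
          drop(i) = u(rng) < dropout_rate ? 0.0f : 1.0f / keep;
      }
      arma::fmat D = Z1 % drop;
      arma::fvec z2 = D * p.W2 + p.b2(0);
      arma::fvec prob = 1.0f / (1.0f + arma::exp(-z2));
      const double loss = bce(prob, yb);
      if (!std::isfinite(loss)) { diverged = true; break; }
      ep_loss += loss; ++nbatch;
      for (int i = 0; i < bs; ++i)
        if ((prob(i) >= 0.5f) == (yb(i) >= 0.5f)) ++ep_correct;

      // backward
      arma::fvec dz2 = (prob - yb) / (float)bs;
      gW2 = D.t() * dz2; gb2(0) = arma::accu(dz2);
      arma::fmat dD = dz2 * p.W2.t();
      arma::fmat dZ1 = (dD % drop);
      for (arma::uword i = 0; i < dZ1.n_elem; ++i) if (!relu1(i)) dZ1(i) = 0.0f;
      gW1 = A.t() * dZ1;
      gb1 = arma::sum(dZ1, 0);
      arma::fmat dA = dZ1 * p.W1.t();
      for (auto& g : gWc) g.zeros();
      for (auto& g : gbc) g.zeros();
      for (int i = 0; i < bs; ++i)
        conv_backward(dA.row(i).t(), a, p, caches[i], gWc, gbc);

      ++adam_t;
      const float flr = (float)lr, fb1 = (float)beta1, fb2 = (float)beta2,
                  fe = (float)adam_eps;
      auto step = [&](arma::fmat& w, const arma::fmat& g, arma::fmat& mm,
                      arma::fmat& vv) {
        opt_step(w, g, mm, vv, flr, fb1, fb2, fe, adam_t, optimizer);
      };
      auto step_row = [&](arma::frowvec& w, arma::frowvec& g, arma::frowvec& mm,
                          arma::frowvec& vv) {
        arma::fmat wm(w.memptr(), 1, w.n_elem, false, true);
        arma::fmat gm(g.memptr(), 1, g.n_elem, false, true);
        arma::fmat mmat(mm.memptr(), 1, mm.n_elem, false, true);
        arma::fmat vmat(vv.memptr(), 1, vv.n_elem, false, true);
        opt_step(wm, gm, mmat, vmat, flr, fb1, fb2, fe, adam_t, optimizer);
      };
      for (size_t b = 0; b < gWc.size(); ++b) {
        step(p.Wc[b], gWc[b], m.Wc[b], v.Wc[b]);
        step_row(p.bc[b], gbc[b], m.bc[b], v.bc[b]);
      }
      step(p.W1, gW1, m.W1, v.W1);
      step(p.W2, gW2, m.W2, v.W2);
      step_row(p.b1, gb1, m.b1, v.b1);
      step_row(p.b2, gb2, m.b2, v.b2);
    }
    if (diverged) break;
    epochs_run = ep + 1;
    h_loss[ep] = ep_loss / std::max(nbatch, 1);
    h_acc[ep] = (double)ep_correct / n;
    if (has_val) {
      arma::fvec vp = predict_probs(INTEGER(vx), (size_t)nval, a, p);
      arma::fvec vyv(nval);
      for (int i = 0; i < nval; ++i) vyv(i) = (float)vy[i];
      h_vloss[ep] = bce(vp, vyv);
      int ok = 0;
      for (int i = 0; i < nval; ++i)
        if ((vp(i) >= 0.5f) == (vyv(i) >= 0.5f)) ++ok;
      h_vacc[ep] = (double)ok / nval;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["weights"] = params_to_list(p),
      _["train_loss"] = h_loss, _["train_acc"] = h_acc,
      _["val_loss"] = h_vloss, _["val_acc"] = h_vacc,
      _["diverged"] = diverged, _["epochs_run"] = epochs_run);
}
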