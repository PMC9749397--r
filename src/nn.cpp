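// Minimal float32 conv-net engine for the sketcher-refiner model.
//
// Tensors are (channels x voxels) matrices; voxel n = d + D*(h + H*w) for a
// (D,H,W) grid. 3x3x3 convolutions are evaluated as 27 shifted GEMMs, which
// keeps all heavy lifting inside BLAS. Gradients are accumulated per layer
// until an Adam step; the step rescales (for batch averaging) and zeroes them.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
#include <vector>

#ifdef __GLIBC__
#include <malloc.h>
// Large tensor temporaries would otherwise be mmap'd and returned to the OS
// on every free, costing a page fault per touched page per training step;
// keeping them on the heap lets the allocator recycle the buffers.
struct MallocTuner {
  MallocTuner() {
    mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
  }
};
static MallocTuner malloc_tuner_;
#endif

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Dims {
  int d, h, w;
  int n() const { return d * h * w; }
  Dims half() const { return Dims{d / 2, h / 2, w / 2}; }
  bool even() const { return d % 2 == 0 && h % 2 == 0 && w % 2 == 0; }
};

// im2col for a 3^3 neighbourhood: column n of B stacks, over the 27 offsets
// k, the cin input channels at voxel n + offset_k (zero outside the grid).
// Offset order matches the weight layout: dz fastest, then dy, then dx.
static void im2col3(const fmat &X, fmat &B, const Dims &dm) {
  const int D = dm.d, H = dm.h, W = dm.w;
  const int C = X.n_rows;
  const float *x0 = X.memptr();
  float *pd = B.memptr();  // filled strictly sequentially, column by column
  const float *xs[9];
  for (int w = 0; w < W; w++)
    for (int h = 0; h < H; h++) {
      bool allhw = true;
      for (int i = 0, dx = -1; dx <= 1; dx++)
        for (int dy = -1; dy <= 1; dy++, i++) {
          const int ww = w + dx, hh = h + dy;
          const bool ok = ww >= 0 && ww < W && hh >= 0 && hh < H;
          xs[i] = ok ? x0 + (size_t)C * (D * (hh + (size_t)H * ww)) : nullptr;
          allhw = allhw && ok;
        }
      for (int d = 0; d < D; d++) {
        if (allhw && d >= 1 && d < D - 1) {
          // interior fast path: each (dx,dy) line contributes 3*C
          // contiguous floats (dz = -1, 0, +1)
          for (int i = 0; i < 9; i++) {
            const float *ps = xs[i] + (size_t)C * (d - 1);
            for (int c = 0; c < 3 * C; c++) *pd++ = ps[c];
          }
        } else {
          for (int i = 0; i < 9; i++) {
            const float *line = xs[i];
            for (int dz = -1; dz <= 1; dz++) {
              const int dd = d + dz;
              if (line && dd >= 0 && dd < D) {
                const float *ps = line + (size_t)C * dd;
                for (int c = 0; c < C; c++) *pd++ = ps[c];
              } else {
                for (int c = 0; c < C; c++) *pd++ = 0.0f;
              }
            }
          }
        }
      }
    }
}

// scatter-add counterpart: dX[:, n + offset_k] += T[k-block, n]; T is read
// sequentially, dX is small enough to stay cached.
static void col2im3_add(const fmat &T, fmat &dX, const Dims &dm) {
  const int D = dm.d, H = dm.h, W = dm.w;
  const int C = dX.n_rows;
  float *x0 = dX.memptr();
  const float *ps = T.memptr();
  float *xs[9];
  for (int w = 0; w < W; w++)
    for (int h = 0; h < H; h++) {
      bool allhw = true;
      for (int i = 0, dx = -1; dx <= 1; dx++)
        for (int dy = -1; dy <= 1; dy++, i++) {
          const int ww = w + dx, hh = h + dy;
          const bool ok = ww >= 0 && ww < W && hh >= 0 && hh < H;
          xs[i] = ok ? x0 + (size_t)C * (D * (hh + (size_t)H * ww)) : nullptr;
          allhw = allhw && ok;
        }
      for (int d = 0; d < D; d++) {
        if (allhw && d >= 1 && d < D - 1) {
          for (int i = 0; i < 9; i++) {
            float *pd2 = xs[i] + (size_t)C * (d - 1);
            for (int c = 0; c < 3 * C; c++) pd2[c] += ps[c];
            ps += 3 * C;
          }
        } else {
          for (int i = 0; i < 9; i++) {
            float *line = xs[i];
            for (int dz = -1; dz <= 1; dz++) {
              const int dd = d + dz;
              if (line && dd >= 0 && dd < D) {
                float *pd2 = line + (size_t)C * dd;
                for (int c = 0; c < C; c++) pd2[c] += ps[c];
              }
              ps += C;
            }
          }
        }
      }
    }
}

struct AdamState {
  fmat mW, vW;
  fvec mb, vb;
};

struct ConvBase {
  int cin = 0, cout = 0;
  fmat W, gW;
  fvec b, gb;
  AdamState ad;
  fmat Xc;    // cached input / im2col matrix (reused across calls)
  fmat Tc;    // scratch for the input-gradient GEMM
  Dims dmc{0, 0, 0};

  void init_adam() {
    gW.zeros(W.n_rows, W.n_cols);
    gb.zeros(b.n_elem);
    ad.mW.zeros(W.n_rows, W.n_cols);
    ad.vW.zeros(W.n_rows, W.n_cols);
    ad.mb.zeros(b.n_elem);
    ad.vb.zeros(b.n_elem);
  }
  void adam(double lr, double scale, long t) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    fmat g = gW * (float)scale;
    ad.mW = b1 * ad.mW + (1 - b1) * g;
    ad.vW = b2 * ad.vW + (1 - b2) * (g % g);
    W -= (float)lr * (ad.mW / c1) / (arma::sqrt(ad.vW / c2) + eps);
    fvec gbv = gb * (float)scale;
    ad.mb = b1 * ad.mb + (1 - b1) * gbv;
    ad.vb = b2 * ad.vb + (1 - b2) * (gbv % gbv);
    b -= (float)lr * (ad.mb / c1) / (arma::sqrt(ad.vb / c2) + eps);
    gW.zeros();
    gb.zeros();
  }
  long n_par() const { return (long)W.n_elem + (long)b.n_elem; }
};

// 3x3x3 convolution, zero padding, stride 1.
struct Conv3 : ConvBase {
  void init(int ci, int co, std::mt19937 &rng) {
    cin = ci;
    cout = co;
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / (ci * 27.0f)));
    W.set_size(co, ci * 27);
    for (arma::uword i = 0; i < W.n_elem; i++) W[i] = nd(rng);
    b.zeros(co);
    init_adam();
  }
  fmat fw(const fmat &X, const Dims &dm, bool train) {
    const arma::uword N = dm.n();
    if (Xc.n_rows != (arma::uword)(27 * cin) || Xc.n_cols != N)
      Xc.set_size(27 * cin, N);   // persistent buffer: no per-call paging
    im2col3(X, Xc, dm);
    fmat Y = W * Xc;
    Y.each_col() += b;
    dmc = dm;  // the cached im2col stays valid until the next fw call
    return Y;
  }
  fmat bw(const fmat &dY, bool want_dx, bool accum) {
    if (accum) {
      gb += arma::sum(dY, 1);
      gW += dY * Xc.t();
    }
    if (!want_dx) return fmat();
    if (Tc.n_rows != Xc.n_rows || Tc.n_cols != Xc.n_cols)
      Tc.set_size(Xc.n_rows, Xc.n_cols);
    Tc = W.t() * dY;  // (27*cin) x N
    fmat dX(cin, dmc.n(), arma::fill::zeros);
    col2im3_add(Tc, dX, dmc);
    return dX;
  }
};

// 1x1x1 convolution (channel mixing).
struct Conv1 : ConvBase {
  void init(int ci, int co, std::mt19937 &rng) {
    cin = ci;
    cout = co;
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / (float)ci));
    W.set_size(co, ci);
    for (arma::uword i = 0; i < W.n_elem; i++) W[i] = nd(rng);
    b.zeros(co);
    init_adam();
  }
  fmat fw(const fmat &X, bool train) {
    fmat Y = W * X;
    Y.each_col() += b;
    if (train) Xc = X;
    return Y;
  }
  fmat bw(const fmat &dY, bool want_dx, bool accum) {
    if (accum) {
      gW += dY * Xc.t();
      gb += arma::sum(dY, 1);
    }
    if (want_dx) return W.t() * dY;
    return fmat();
  }
};

static fmat lrelu(fmat Y, float slope = 0.2f) {
  for (arma::uword i = 0; i < Y.n_elem; i++)
    if (Y[i] < 0) Y[i] *= slope;
  return Y;
}
// derivative from the stored post-activation output (slope > 0 so sign kept)
static void lrelu_bw(fmat &dY, const fmat &act, float slope = 0.2f) {
  for (arma::uword i = 0; i < dY.n_elem; i++)
    if (act[i] < 0) dY[i] *= slope;
}

static fmat avgpool2(const fmat &X, const Dims &dm) {
  const Dims o = dm.half();
  fmat Y(X.n_rows, o.n(), arma::fill::zeros);
  const int C = X.n_rows;
  for (int w = 0; w < o.w; w++)
    for (int h = 0; h < o.h; h++)
      for (int d = 0; d < o.d; d++) {
        float *py = Y.colptr(d + o.d * (h + o.h * w));
        for (int dz = 0; dz < 2; dz++)
          for (int dy = 0; dy < 2; dy++)
            for (int dx = 0; dx < 2; dx++) {
              const float *px = X.colptr((2 * d + dz) +
                                         dm.d * ((2 * h + dy) +
                                                 dm.h * (2 * w + dx)));
              for (int c = 0; c < C; c++) py[c] += px[c];
            }
        for (int c = 0; c < C; c++) py[c] *= 0.125f;
      }
  return Y;
}

static fmat avgpool2_bw(const fmat &dY, const Dims &dm_in) {
  const Dims o = dm_in.half();
  fmat dX(dY.n_rows, dm_in.n(), arma::fill::zeros);
  const int C = dY.n_rows;
  for (int w = 0; w < o.w; w++)
    for (int h = 0; h < o.h; h++)
      for (int d = 0; d < o.d; d++) {
        const float *py = dY.colptr(d + o.d * (h + o.h * w));
        for (int dz = 0; dz < 2; dz++)
          for (int dy = 0; dy < 2; dy++)
            for (int dx = 0; dx < 2; dx++) {
              float *px = dX.colptr((2 * d + dz) +
                                    dm_in.d * ((2 * h + dy) +
                                               dm_in.h * (2 * w + dx)));
              for (int c = 0; c < C; c++) px[c] += 0.125f * py[c];
            }
      }
  return dX;
}

static fmat upsample2(const fmat &X, const Dims &dm_in) {
  const Dims o{dm_in.d * 2, dm_in.h * 2, dm_in.w * 2};
  fmat Y(X.n_rows, o.n());
  const int C = X.n_rows;
  for (int w = 0; w < o.w; w++)
    for (int h = 0; h < o.h; h++)
      for (int d = 0; d < o.d; d++)
        std::memcpy(Y.colptr(d + o.d * (h + o.h * w)),
                    X.colptr((d / 2) + dm_in.d * ((h / 2) +
                                                  dm_in.h * (w / 2))),
                    sizeof(float) * C);
  return Y;
}

static fmat upsample2_bw(const fmat &dY, const Dims &dm_in) {
  // dm_in = coarse dims of the upsample input
  const Dims o{dm_in.d * 2, dm_in.h * 2, dm_in.w * 2};
  fmat dX(dY.n_rows, dm_in.n(), arma::fill::zeros);
  const int C = dY.n_rows;
  for (int w = 0; w < o.w; w++)
    for (int h = 0; h < o.h; h++)
      for (int d = 0; d < o.d; d++) {
        const float *py = dY.colptr(d + o.d * (h + o.h * w));
        float *px = dX.colptr((d / 2) +
                              dm_in.d * ((h / 2) + dm_in.h * (w / 2)));
        for (int c = 0; c < C; c++) px[c] += py[c];
      }
  return dX;
}

// ----------------------------------------------------------------------------
// U-Net generator: per level one 3x3x3 conv; average-pool between levels;
// nearest-neighbour upsampling with skip concatenation; the decoder first
// reduces the concatenation with a 1x1x1 conv, then applies a 3x3x3 conv.
struct UNet {
  int cin;
  std::vector<int> ch;  // channels per level, level 0 = full resolution
  std::vector<Conv3> enc, dec;
  std::vector<Conv1> red;
  Conv1 out;
  long t = 0;
  // caches
  std::vector<fmat> A, actR, actD;
  std::vector<Dims> dims;

  void build(int ci, const std::vector<int> &channels, unsigned seed) {
    cin = ci;
    ch = channels;
    const int L = (int)ch.size();
    std::mt19937 rng(seed);
    enc.resize(L);
    enc[0].init(cin, ch[0], rng);
    for (int l = 1; l < L; l++) enc[l].init(ch[l - 1], ch[l], rng);
    red.resize(L - 1);
    dec.resize(L - 1);
    for (int i = 0; i < L - 1; i++) {
      red[i].init(ch[i + 1] + ch[i], ch[i], rng);
      dec[i].init(ch[i], ch[i], rng);
    }
    out.init(ch[0], 1, rng);
    A.resize(L);
    actR.resize(L - 1);
    actD.resize(L - 1);
    dims.resize(L);
  }

  fmat fw(const fmat &x, const Dims &dm, bool train) {
    const int L = (int)ch.size();
    dims[0] = dm;
    A[0] = lrelu(enc[0].fw(x, dm, train));
    for (int l = 1; l < L; l++) {
      if (!dims[l - 1].even())
        stop("patch dims must be divisible by 2 at every level");
      dims[l] = dims[l - 1].half();
      A[l] = lrelu(enc[l].fw(avgpool2(A[l - 1], dims[l - 1]), dims[l],
                             train));
    }
    fmat U = A[L - 1];
    for (int i = L - 2; i >= 0; i--) {
      fmat C = arma::join_cols(upsample2(U, dims[i + 1]), A[i]);
      actR[i] = lrelu(red[i].fw(C, train));
      actD[i] = lrelu(dec[i].fw(actR[i], dims[i], train));
      U = actD[i];
    }
    return out.fw(U, train);
  }

  void bw(const fmat &dy) {
    const int L = (int)ch.size();
    fmat dU = out.bw(dy, true, true);
    std::vector<fmat> dSkip(L - 1);
    for (int i = 0; i <= L - 2; i++) {
      lrelu_bw(dU, actD[i]);
      fmat dR = dec[i].bw(dU, true, true);
      lrelu_bw(dR, actR[i]);
      fmat dC = red[i].bw(dR, true, true);
      dSkip[i] = dC.rows(ch[i + 1], dC.n_rows - 1);
      dU = upsample2_bw(dC.rows(0, ch[i + 1] - 1), dims[i + 1]);
    }
    fmat g = dU;  // grad w.r.t. A[L-1]
    for (int l = L - 1; l >= 1; l--) {
      lrelu_bw(g, A[l]);
      fmat gP = enc[l].bw(g, true, true);
      g = avgpool2_bw(gP, dims[l - 1]);
      g += dSkip[l - 1];
    }
    lrelu_bw(g, A[0]);
    enc[0].bw(g, false, true);
  }

  void step(double lr, double scale) {
    t++;
    for (auto &c : enc) c.adam(lr, scale, t);
    for (auto &c : red) c.adam(lr, scale, t);
    for (auto &c : dec) c.adam(lr, scale, t);
    out.adam(lr, scale, t);
  }

  std::vector<ConvBase *> layers() {
    std::vector<ConvBase *> v;
    for (auto &c : enc) v.push_back(&c);
    for (auto &c : red) v.push_back(&c);
    for (auto &c : dec) v.push_back(&c);
    v.push_back(&out);
    return v;
  }
};

// PatchGAN discriminator: optional pre-pooling, then conv+pool stages and a
// 1x1x1 head with sigmoid output over the remaining patch grid.
struct Disc {
  int cin, npre;
  std::vector<int> ch;
  std::vector<Conv3> convs;
  Conv1 out;
  long t = 0;
  std::vector<fmat> acts;
  std::vector<Dims> dims;  // dims at conv j input (post pre-pool chain)
  fmat sig;
  Dims dm_in{0, 0, 0}, dm_out{0, 0, 0};

  void build(int ci, const std::vector<int> &channels, int prepool,
             unsigned seed) {
    cin = ci;
    npre = prepool;
    ch = channels;
    std::mt19937 rng(seed + 77);
    const int K = (int)ch.size();
    convs.resize(K);
    convs[0].init(cin, ch[0], rng);
    for (int j = 1; j < K; j++) convs[j].init(ch[j - 1], ch[j], rng);
    out.init(ch[K - 1], 1, rng);
    acts.resize(K);
    dims.resize(K + 1);
  }

  fmat fw(const fmat &x, const Dims &dm, bool train) {
    dm_in = dm;
    fmat cur = x;
    Dims cd = dm;
    for (int p = 0; p < npre; p++) {
      if (!cd.even()) stop("discriminator input dims not divisible");
      cur = avgpool2(cur, cd);
      cd = cd.half();
    }
    const int K = (int)ch.size();
    for (int j = 0; j < K; j++) {
      dims[j] = cd;
      cur = lrelu(convs[j].fw(cur, cd, train));
      acts[j] = cur;
      if (!cd.even()) stop("discriminator dims not divisible");
      cur = avgpool2(cur, cd);
      cd = cd.half();
    }
    dims[K] = cd;
    dm_out = cd;
    fmat y = out.fw(cur, train);
    sig = 1.0f / (1.0f + arma::exp(-y));
    return sig;
  }

  // dy is the gradient w.r.t. the sigmoid output
  fmat bw(const fmat &dy, bool want_dx, bool accum) {
    const int K = (int)ch.size();
    fmat d = dy % sig % (1.0f - sig);
    fmat dU = out.bw(d, true, accum);
    for (int j = K - 1; j >= 0; j--) {
      dU = avgpool2_bw(dU, dims[j]);
      lrelu_bw(dU, acts[j]);
      const bool need = want_dx || j > 0;
      dU = convs[j].bw(dU, need, accum);
    }
    if (!want_dx) return fmat();
    Dims cd = dm_in;
    std::vector<Dims> pre(npre);
    for (int p = 0; p < npre; p++) {
      pre[p] = cd;
      cd = cd.half();
    }
    for (int p = npre - 1; p >= 0; p--) dU = avgpool2_bw(dU, pre[p]);
    return dU;
  }

  void step(double lr, double scale) {
    t++;
    for (auto &c : convs) c.adam(lr, scale, t);
    out.adam(lr, scale, t);
  }

  std::vector<ConvBase *> layers() {
    std::vector<ConvBase *> v;
    for (auto &c : convs) v.push_back(&c);
    v.push_back(&out);
    return v;
  }
};

// ---------------------------------------------------------------------------
// R interface

static fmat to_fmat(const NumericVector &x, int c, int n) {
  if ((int)x.size() != c * n) stop("tensor size mismatch");
  fmat X(c, n);
  for (int i = 0; i < c * n; i++) X[i] = (float)x[i];
  return X;
}
static NumericVector to_num(const fmat &X) {
  NumericVector y(X.n_elem);
  for (arma::uword i = 0; i < X.n_elem; i++) y[i] = X[i];
  return y;
}

// [[Rcpp::export(name = ".nn_unet_create")]]
SEXP nn_unet_create(int cin, IntegerVector channels, int seed) {
  UNet *net = new UNet();
  net->build(cin, std::vector<int>(channels.begin(), channels.end()),
             (unsigned)seed);
  XPtr<UNet> p(net, true);
  return p;
}

// [[Rcpp::export(name = ".nn_unet_forward")]]
NumericVector nn_unet_forward(SEXP ptr, NumericVector x, IntegerVector dims,
                              bool train) {
  XPtr<UNet> p(ptr);
  Dims dm{dims[0], dims[1], dims[2]};
  return to_num(p->fw(to_fmat(x, p->cin, dm.n()), dm, train));
}

// [[Rcpp::export(name = ".nn_unet_backward")]]
void nn_unet_backward(SEXP ptr, NumericVector dy) {
  XPtr<UNet> p(ptr);
  const int n = p->dims[0].n();
  p->bw(to_fmat(dy, 1, n));
}

// [[Rcpp::export(name = ".nn_unet_step")]]
void nn_unet_step(SEXP ptr, double lr, double scale) {
  XPtr<UNet> p(ptr);
  p->step(lr, scale);
}

// [[Rcpp::export(name = ".nn_disc_create")]]
SEXP nn_disc_create(int cin, IntegerVector channels, int prepool, int seed) {
  Disc *net = new Disc();
  net->build(cin, std::vector<int>(channels.begin(), channels.end()),
             prepool, (unsigned)seed);
  XPtr<Disc> p(net, true);
  return p;
}

// [[Rcpp::export(name = ".nn_disc_forward")]]
NumericVector nn_disc_forward(SEXP ptr, NumericVector x, IntegerVector dims,
                              bool train) {
  XPtr<Disc> p(ptr);
  Dims dm{dims[0], dims[1], dims[2]};
  NumericVector y = to_num(p->fw(to_fmat(x, p->cin, dm.n()), dm, train));
  y.attr("outdims") =
      IntegerVector::create(p->dm_out.d, p->dm_out.h, p->dm_out.w);
  return y;
}

// [[Rcpp::export(name = ".nn_disc_backward")]]
NumericVector nn_disc_backward(SEXP ptr, NumericVector dy, bool want_dx,
                               bool accum) {
  XPtr<Disc> p(ptr);
  fmat dx = p->bw(to_fmat(dy, 1, p->dm_out.n()), want_dx, accum);
  if (!want_dx) return NumericVector(0);
  return to_num(dx);
}

// [[Rcpp::export(name = ".nn_disc_step")]]
void nn_disc_step(SEXP ptr, double lr, double scale) {
  XPtr<Disc> p(ptr);
  p->step(lr, scale);
}

template <class NET>
static List get_weights_impl(NET *p) {
  std::vector<ConvBase *> ls = p->layers();
  List res(2 * ls.size());
  for (size_t i = 0; i < ls.size(); i++) {
    res[2 * i] = to_num(ls[i]->W);
    res[2 * i + 1] = to_num(fmat(ls[i]->b));
  }
  return res;
}

template <class NET>
static void set_weights_impl(NET *p, List w) {
  std::vector<ConvBase *> ls = p->layers();
  if ((size_t)w.size() != 2 * ls.size()) stop("weight list length mismatch");
  for (size_t i = 0; i < ls.size(); i++) {
    NumericVector Wv = w[2 * i], bv = w[2 * i + 1];
    if ((arma::uword)Wv.size() != ls[i]->W.n_elem ||
        (arma::uword)bv.size() != ls[i]->b.n_elem)
      stop("weight element count mismatch at layer %d", (int)i);
    for (arma::uword j = 0; j < ls[i]->W.n_elem; j++)
      ls[i]->W[j] = (float)Wv[j];
    for (arma::uword j = 0; j < ls[i]->b.n_elem; j++)
      ls[i]->b[j] = (float)bv[j];
  }
}

template <class NET>
static List get_grads_impl(NET *p) {
  std::vector<ConvBase *> ls = p->layers();
  List res(2 * ls.size());
  for (size_t i = 0; i < ls.size(); i++) {
    res[2 * i] = to_num(ls[i]->gW);
    res[2 * i + 1] = to_num(fmat(ls[i]->gb));
  }
  return res;
}

template <class NET>
static double n_params_impl(NET *p) {
  double s = 0;
  for (ConvBase *c : p->layers()) s += (double)c->n_par();
  return s;
}

// [[Rcpp::export(name = ".nn_unet_get_weights")]]
List nn_unet_get_weights(SEXP ptr) { return get_weights_impl(XPtr<UNet>(ptr).get()); }
// [[Rcpp::export(name = ".nn_unet_set_weights")]]
void nn_unet_set_weights(SEXP ptr, List w) { set_weights_impl(XPtr<UNet>(ptr).get(), w); }
// [[Rcpp::export(name = ".nn_unet_nparams")]]
double nn_unet_nparams(SEXP ptr) { return n_params_impl(XPtr<UNet>(ptr).get()); }
// [[Rcpp::export(name = ".nn_disc_get_weights")]]
List nn_disc_get_weights(SEXP ptr) { return get_weights_impl(XPtr<Disc>(ptr).get()); }
// [[Rcpp::export(name = ".nn_disc_set_weights")]]
void nn_disc_set_weights(SEXP ptr, List w) { set_weights_impl(XPtr<Disc>(ptr).get(), w); }
// [[Rcpp::export(name = ".nn_disc_nparams")]]
double nn_disc_nparams(SEXP ptr) { return n_params_impl(XPtr<Disc>(ptr).get()); }
// [[Rcpp::export(name = ".nn_unet_get_grads")]]
List nn_unet_get_grads(SEXP ptr) { return get_grads_impl(XPtr<UNet>(ptr).get()); }
// [[Rcpp::export(name = ".nn_disc_get_grads")]]
List nn_disc_get_grads(SEXP ptr) { return get_grads_impl(XPtr<Disc>(ptr).get()); }
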