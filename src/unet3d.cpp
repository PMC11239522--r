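// 3D encoder-decoder segmentation network (BasicUNet-style).
//
// Activations are stored channel-major: arma::fmat A(C, N) where column v is
// the voxel with linear index v = z + Z*y + Z*Y*x (z fastest), matching an R
// array of dim c(Z, Y, X). Convolutions are 3x3x3 (zero-padded, stride 1),
// realised as im2col + single-precision BLAS GEMM, chunked along x so the
// column buffer stays cache-friendly. Backprop is hand-derived and verified
// against finite differences in the test suite.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

struct Conv {
  int Cin, Cout, k;            // k = 3 or 1
  fmat W;                      // Cout x (Cin * k^3)
  fvec b;
  fmat gW; fvec gb;            // gradient accumulators
  fmat mW, vW; fvec mb, vb;    // Adam state
  void init_adam() {
    mW.zeros(W.n_rows, W.n_cols); vW.zeros(W.n_rows, W.n_cols);
    mb.zeros(b.n_elem); vb.zeros(b.n_elem);
  }
  void zero_grad() { gW.zeros(W.n_rows, W.n_cols); gb.zeros(b.n_elem); }
};

// branchless polynomial exp (rel. err < 1e-6), written so the activation
// loops auto-vectorize; clamped to the float-safe range
inline float fast_expf(float x) {
  x = x < -40.0f ? -40.0f : (x > 40.0f ? 40.0f : x);
  float y = x * 1.44269504f;
  float n = std::floor(y);
  float f = y - n;
  float p = 1.0f + f * (0.693147182f + f * (0.240226507f +
            f * (0.0555041086f + f * (0.00961812911f +
            f * 0.00133335581f))));
  union { uint32_t u; float fl; } v;
  v.u = (uint32_t)((int)n + 127) << 23;
  return p * v.fl;
}

// Mish via the closed form tanh(softplus(x)) = (t^2 + 2t) / (t^2 + 2t + 2)
// with t = exp(x): one (cheap) exponential per element instead of three
// transcendentals.
inline float mish_f(float x) {
  float t = fast_expf(x);
  float u = t * (t + 2.0f);
  return x * u / (u + 2.0f);  // for x >= 40, u/(u+2) == 1 in float
}
inline float mish_grad_f(float x) {
  float t = fast_expf(x);
  float u = t * (t + 2.0f);
  float du = 2.0f * t * (t + 1.0f);
  float inv = 1.0f / (u + 2.0f);
  return u * inv + 2.0f * x * du * inv * inv;
}

// im2col for a contiguous x-slab [x0, x1) of the output volume.
// col is K x (Z*Y*(x1-x0)), rows ordered r = c + Cin*o with
// o = (dz+1) + 3*(dy+1) + 9*(dx+1). Because voxel columns of X are
// contiguous (Cin floats apart) and z is the fastest axis, the three dz
// neighbours of a voxel occupy one contiguous 3*Cin block in X, and the
// corresponding rows of the output column are contiguous too: each column
// is assembled from 9 contiguous block copies (one per (dy, dx) pair).
void im2col_slab(const fmat& X, int Z, int Y, int Xd, int x0, int x1,
                 fmat& col) {
  const int Cin = X.n_rows;
  const long ZY = (long)Z * Y;
  const long K = col.n_rows;
  for (int x = x0; x < x1; ++x) {
    for (int y = 0; y < Y; ++y) {
      long jc0 = (long)Z * y + ZY * (x - x0);  // column of voxel (0, y, x)
      for (int p = 0; p < 9; ++p) {
        int dy = p % 3 - 1, dx = p / 3 - 1;
        int ys = y + dy, xs = x + dx;
        float* dstbase = col.colptr(jc0) + (long)Cin * 3 * p;
        if (ys < 0 || ys >= Y || xs < 0 || xs >= Xd) {
          for (int z = 0; z < Z; ++z) {
            float* dst = dstbase + (long)K * z;
            for (int c = 0; c < 3 * Cin; ++c) dst[c] = 0.0f;
          }
          continue;
        }
        const float* srcbase = X.colptr((long)Z * ys + ZY * xs);
        // interior z: rows (dz=-1,0,+1) <- X columns (z-1, z, z+1)
        for (int z = 1; z < Z - 1; ++z) {
          float* dst = dstbase + (long)K * z;
          const float* src = srcbase + (long)Cin * (z - 1);
          for (int c = 0; c < 3 * Cin; ++c) dst[c] = src[c];
        }
        {  // z = 0: dz=-1 is out of bounds
          float* dst = dstbase;
          for (int c = 0; c < Cin; ++c) dst[c] = 0.0f;
          for (int c = 0; c < 2 * Cin; ++c) dst[Cin + c] = srcbase[c];
        }
        if (Z > 1) {  // z = Z-1: dz=+1 is out of bounds
          float* dst = dstbase + (long)K * (Z - 1);
          const float* src = srcbase + (long)Cin * (Z - 2);
          for (int c = 0; c < 2 * Cin; ++c) dst[c] = src[c];
          for (int c = 0; c < Cin; ++c) dst[2 * Cin + c] = 0.0f;
        }
      }
    }
  }
}

// scatter-add transpose of im2col_slab: gX(:, v + off) += colG rows
void col2im_slab(const fmat& colG, int Z, int Y, int Xd, int x0, int x1,
                 fmat& gX) {
  const int Cin = gX.n_rows;
  const long ZY = (long)Z * Y;
  const long K = colG.n_rows;
  for (int x = x0; x < x1; ++x) {
    for (int y = 0; y < Y; ++y) {
      long jc0 = (long)Z * y + ZY * (x - x0);
      for (int p = 0; p < 9; ++p) {
        int dy = p % 3 - 1, dx = p / 3 - 1;
        int ys = y + dy, xs = x + dx;
        if (ys < 0 || ys >= Y || xs < 0 || xs >= Xd) continue;
        const float* srcbase = colG.colptr(jc0) + (long)Cin * 3 * p;
        float* dstbase = gX.colptr((long)Z * ys + ZY * xs);
        for (int z = 1; z < Z - 1; ++z) {
          const float* src = srcbase + (long)K * z;
          float* dst = dstbase + (long)Cin * (z - 1);
          for (int c = 0; c < 3 * Cin; ++c) dst[c] += src[c];
        }
        {
          const float* src = srcbase;
          for (int c = 0; c < 2 * Cin; ++c) dstbase[c] += src[Cin + c];
        }
        if (Z > 1) {
          const float* src = srcbase + (long)K * (Z - 1);
          float* dst = dstbase + (long)Cin * (Z - 2);
          for (int c = 0; c < 2 * Cin; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// pick the x-slab width so the im2col buffer stays cache-resident (~3 MB)
inline int slab_width(int Cin, int Z, int Y) {
  long per_x = (long)Cin * 27 * Z * Y * sizeof(float);
  int w = (int)std::max(1L, (1L << 20) / std::max(1L, per_x));
  return w;
}

void conv_forward(Conv& L, const fmat& X, int Z, int Y, int Xd, fmat& out) {
  const long N = (long)Z * Y * Xd;
  out.set_size(L.Cout, N);
  if (L.k == 1) {
    out = L.W * X;
    out.each_col() += L.b;
    return;
  }
  const int w = slab_width(L.Cin, Z, Y);
  fmat col(L.Cin * 27, (long)Z * Y * std::min(w, Xd));
  for (int x0 = 0; x0 < Xd; x0 += w) {
    int x1 = std::min(Xd, x0 + w);
    long j0 = (long)Z * Y * x0, nc = (long)Z * Y * (x1 - x0);
    if ((long)col.n_cols != nc) col.set_size(L.Cin * 27, nc);
    im2col_slab(X, Z, Y, Xd, x0, x1, col);
    out.cols(j0, j0 + nc - 1) = L.W * col;
  }
  out.each_col() += L.b;
}

// Accumulates gW, gb; writes grad wrt input into gX unless skip_input.
void conv_backward(Conv& L, const fmat& X, const fmat& G, int Z, int Y,
                   int Xd, fmat& gX, bool skip_input) {
  L.gb += arma::sum(G, 1);
  if (L.k == 1) {
    L.gW += G * X.t();
    if (!skip_input) gX = L.W.t() * G;
    return;
  }
  if (!skip_input) gX.zeros(L.Cin, X.n_cols);
  const int w = slab_width(L.Cin, Z, Y);
  fmat col(L.Cin * 27, (long)Z * Y * std::min(w, Xd));
  fmat colG;
  for (int x0 = 0; x0 < Xd; x0 += w) {
    int x1 = std::min(Xd, x0 + w);
    long j0 = (long)Z * Y * x0, nc = (long)Z * Y * (x1 - x0);
    if ((long)col.n_cols != nc) col.set_size(L.Cin * 27, nc);
    im2col_slab(X, Z, Y, Xd, x0, x1, col);
    const fmat Gs = G.cols(j0, j0 + nc - 1);
    L.gW += Gs * col.t();
    if (!skip_input) {
      colG = L.W.t() * Gs;
      col2im_slab(colG, Z, Y, Xd, x0, x1, gX);
    }
  }
}

void maxpool_forward(const fmat& X, int Z, int Y, int Xd, fmat& out,
                     arma::umat& idx) {
  const int C = X.n_rows, Zo = Z / 2, Yo = Y / 2, Xo = Xd / 2;
  const long No = (long)Zo * Yo * Xo;
  out.set_size(C, No);
  idx.set_size(C, No);
  for (int x = 0; x < Xo; ++x)
    for (int y = 0; y < Yo; ++y)
      for (int z = 0; z < Zo; ++z) {
        long vo = (long)z + (long)Zo * y + (long)Zo * Yo * x;
        float* po = out.colptr(vo);
        arma::uword* pi = idx.colptr(vo);
        bool first = true;
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy)
            for (int dz = 0; dz < 2; ++dz) {
              long vs = (long)(2 * z + dz) + (long)Z * (2 * y + dy) +
                        (long)Z * Y * (2 * x + dx);
              const float* ps = X.colptr(vs);
              if (first) {
                for (int c = 0; c < C; ++c) { po[c] = ps[c]; pi[c] = vs; }
                first = false;
              } else {
                for (int c = 0; c < C; ++c)
                  if (ps[c] > po[c]) { po[c] = ps[c]; pi[c] = vs; }
              }
            }
      }
}

void maxpool_backward(const fmat& G, const arma::umat& idx, long Nin,
                      fmat& gX) {
  const int C = G.n_rows;
  gX.zeros(C, Nin);
  for (long v = 0; v < (long)G.n_cols; ++v) {
    const float* pg = G.colptr(v);
    const arma::uword* pi = idx.colptr(v);
    for (int c = 0; c < C; ++c) gX(c, pi[c]) += pg[c];
  }
}

void upsample_forward(const fmat& X, int Z, int Y, int Xd, fmat& out) {
  const int C = X.n_rows, Zo = Z * 2, Yo = Y * 2, Xo = Xd * 2;
  out.set_size(C, (long)Zo * Yo * Xo);
  for (int x = 0; x < Xo; ++x)
    for (int y = 0; y < Yo; ++y)
      for (int z = 0; z < Zo; ++z) {
        long vo = (long)z + (long)Zo * y + (long)Zo * Yo * x;
        long vs = (long)(z / 2) + (long)Z * (y / 2) + (long)Z * Y * (x / 2);
        std::memcpy(out.colptr(vo), X.colptr(vs), C * sizeof(float));
      }
}

void upsample_backward(const fmat& G, int Zo, int Yo, int Xo, fmat& gX) {
  const int C = G.n_rows, Z = Zo / 2, Y = Yo / 2, Xd = Xo / 2;
  gX.zeros(C, (long)Z * Y * Xd);
  for (int x = 0; x < Xo; ++x)
    for (int y = 0; y < Yo; ++y)
      for (int z = 0; z < Zo; ++z) {
        long vo = (long)z + (long)Zo * y + (long)Zo * Yo * x;
        long vs = (long)(z / 2) + (long)Z * (y / 2) + (long)Z * Y * (x / 2);
        const float* pg = G.colptr(vo);
        float* px = gX.colptr(vs);
        for (int c = 0; c < C; ++c) px[c] += pg[c];
      }
}

struct UNet {
  int depth, base;
  long adam_t = 0;
  std::vector<Conv> convs;  // encA0,encB0,...,decA_{D-2},decB_{D-2},...,final

  int feat(int l) const { return base << l; }
  int enc_idx(int l, int which) const { return 2 * l + which; }
  int dec_idx(int l, int which) const {
    return 2 * depth + 2 * (depth - 2 - l) + which;
  }
  int fin_idx() const { return 4 * depth - 2; }

  void build() {
    convs.clear();
    for (int l = 0; l < depth; ++l) {
      int cin = (l == 0) ? 1 : feat(l - 1);
      convs.push_back(Conv{cin, feat(l), 3});
      convs.push_back(Conv{feat(l), feat(l), 3});
    }
    for (int l = depth - 2; l >= 0; --l) {
      convs.push_back(Conv{feat(l) + feat(l + 1), feat(l), 3});
      convs.push_back(Conv{feat(l), feat(l), 3});
    }
    convs.push_back(Conv{feat(0), 1, 1});
    for (auto& c : convs) {
      c.W.set_size(c.Cout, c.Cin * c.k * c.k * c.k);
      c.b.zeros(c.Cout);
      c.init_adam();
      c.zero_grad();
    }
  }

  void init_weights() {
    // He-normal via R's RNG so set.seed() governs initialisation
    for (auto& c : convs) {
      double sd = std::sqrt(2.0 / (double)(c.Cin * c.k * c.k * c.k));
      for (arma::uword i = 0; i < c.W.n_elem; ++i)
        c.W(i) = (float)(norm_rand() * sd);
      c.b.zeros();
    }
    // logit-head bias starts at the sparse-foreground prior (~2% positives)
    // so early optimisation does not stall at the all-background solution
    convs.back().b.fill(-4.0f);
  }

  long n_params() const {
    long n = 0;
    for (auto& c : convs) n += (long)c.W.n_elem + c.b.n_elem;
    return n;
  }
};

struct Cache {
  std::vector<fmat> in;    // input of each conv
  std::vector<fmat> pre;   // pre-activation output of each conv
  std::vector<arma::umat> pool_idx;
  std::vector<std::array<int, 3>> dims_at;  // dims per level
};

// forward pass; if cache != nullptr store what backward needs
fmat unet_forward_pass(UNet& net, const fmat& x0, int Z, int Y, int Xd,
                       Cache* cache) {
  const int D = net.depth;
  std::vector<fmat> skip(D);
  std::vector<std::array<int, 3>> dims(D);
  if (cache) {
    cache->in.resize(net.convs.size());
    cache->pre.resize(net.convs.size());
    cache->pool_idx.resize(D);
  }
  fmat cur = x0;
  int z = Z, y = Y, x = Xd;
  for (int l = 0; l < D; ++l) {
    if (l > 0) {
      fmat pooled; arma::umat idx;
      maxpool_forward(cur, z, y, x, pooled, idx);
      z /= 2; y /= 2; x /= 2;
      cur = std::move(pooled);
      if (cache) cache->pool_idx[l] = std::move(idx);
    }
    dims[l] = {z, y, x};
    for (int which = 0; which < 2; ++which) {
      Conv& c = net.convs[net.enc_idx(l, which)];
      fmat pre;
      conv_forward(c, cur, z, y, x, pre);
      if (cache) {
        cache->in[net.enc_idx(l, which)] = cur;
        cache->pre[net.enc_idx(l, which)] = pre;
      }
      cur.set_size(pre.n_rows, pre.n_cols);
      for (arma::uword i = 0; i < pre.n_elem; ++i) cur(i) = mish_f(pre(i));
    }
    skip[l] = cur;
  }
  for (int l = D - 2; l >= 0; --l) {
    fmat up;
    upsample_forward(cur, dims[l + 1][0], dims[l + 1][1], dims[l + 1][2], up);
    z = dims[l][0]; y = dims[l][1]; x = dims[l][2];
    fmat cat(skip[l].n_rows + up.n_rows, up.n_cols);
    cat.rows(0, skip[l].n_rows - 1) = skip[l];
    cat.rows(skip[l].n_rows, cat.n_rows - 1) = up;
    for (int which = 0; which < 2; ++which) {
      Conv& c = net.convs[net.dec_idx(l, which)];
      fmat& src = (which == 0) ? cat : cur;
      fmat pre;
      conv_forward(c, src, z, y, x, pre);
      if (cache) {
        cache->in[net.dec_idx(l, which)] = src;
        cache->pre[net.dec_idx(l, which)] = pre;
      }
      cur.set_size(pre.n_rows, pre.n_cols);
      for (arma::uword i = 0; i < pre.n_elem; ++i) cur(i) = mish_f(pre(i));
    }
  }
  Conv& fc = net.convs[net.fin_idx()];
  fmat logits;
  conv_forward(fc, cur, z, y, x, logits);
  if (cache) {
    cache->in[net.fin_idx()] = cur;
    cache->pre[net.fin_idx()] = logits;
    cache->dims_at.assign(dims.begin(), dims.end());
  }
  return logits;
}

// backward from dLoss/dlogits; accumulates parameter grads
void unet_backward_pass(UNet& net, Cache& cache, const fmat& dlogits) {
  const int D = net.depth;
  std::vector<fmat> gskip(D);
  fmat g, gin;
  Conv& fc = net.convs[net.fin_idx()];
  conv_backward(fc, cache.in[net.fin_idx()], dlogits, 0, 0, 0, gin, false);
  fmat g_cur = std::move(gin);  // grad wrt output of decoder level 0 (or skip[D-1])
  for (int l = 0; l <= D - 2; ++l) {
    int z = cache.dims_at[l][0], y = cache.dims_at[l][1],
        x = cache.dims_at[l][2];
    // decB_l
    {
      Conv& c = net.convs[net.dec_idx(l, 1)];
      const fmat& pre = cache.pre[net.dec_idx(l, 1)];
      g.set_size(g_cur.n_rows, g_cur.n_cols);
      for (arma::uword i = 0; i < g.n_elem; ++i)
        g(i) = g_cur(i) * mish_grad_f(pre(i));
      conv_backward(c, cache.in[net.dec_idx(l, 1)], g, z, y, x, gin, false);
    }
    // decA_l
    fmat gcat;
    {
      Conv& c = net.convs[net.dec_idx(l, 0)];
      const fmat& pre = cache.pre[net.dec_idx(l, 0)];
      g.set_size(gin.n_rows, gin.n_cols);
      for (arma::uword i = 0; i < g.n_elem; ++i)
        g(i) = gin(i) * mish_grad_f(pre(i));
      conv_backward(c, cache.in[net.dec_idx(l, 0)], g, z, y, x, gcat, false);
    }
    int fl = net.feat(l);
    gskip[l] = gcat.rows(0, fl - 1);
    fmat gup = gcat.rows(fl, gcat.n_rows - 1);
    upsample_backward(gup, z, y, x, g_cur);  // -> grad at level l+1 output
  }
  gskip[D - 1] = std::move(g_cur);
  for (int l = D - 1; l >= 0; --l) {
    int z = cache.dims_at[l][0], y = cache.dims_at[l][1],
        x = cache.dims_at[l][2];
    fmat gl = std::move(gskip[l]);
    for (int which = 1; which >= 0; --which) {
      Conv& c = net.convs[net.enc_idx(l, which)];
      const fmat& pre = cache.pre[net.enc_idx(l, which)];
      g.set_size(gl.n_rows, gl.n_cols);
      for (arma::uword i = 0; i < g.n_elem; ++i)
        g(i) = gl(i) * mish_grad_f(pre(i));
      bool skip_in = (l == 0 && which == 0);
      conv_backward(c, cache.in[net.enc_idx(l, which)], g, z, y, x, gin,
                    skip_in);
      if (!skip_in) gl = std::move(gin);
    }
    if (l > 0) {
      fmat gprev;
      long Nin = (long)cache.dims_at[l - 1][0] * cache.dims_at[l - 1][1] *
                 cache.dims_at[l - 1][2];
      maxpool_backward(gl, cache.pool_idx[l], Nin, gprev);
      gskip[l - 1] += gprev;
    }
  }
}

void adam_step(UNet& net, double lr, double beta1, double beta2, double eps) {
  net.adam_t += 1;
  double bc1 = 1.0 - std::pow(beta1, (double)net.adam_t);
  double bc2 = 1.0 - std::pow(beta2, (double)net.adam_t);
  for (auto& c : net.convs) {
    c.mW = (float)beta1 * c.mW + (float)(1 - beta1) * c.gW;
    c.vW = (float)beta2 * c.vW + (float)(1 - beta2) * (c.gW % c.gW);
    c.W -= (float)(lr / bc1) * (c.mW / (arma::sqrt(c.vW / (float)bc2) +
                                        (float)eps));
    c.mb = (float)beta1 * c.mb + (float)(1 - beta1) * c.gb;
    c.vb = (float)beta2 * c.vb + (float)(1 - beta2) * (c.gb % c.gb);
    c.b -= (float)(lr / bc1) * (c.mb / (arma::sqrt(c.vb / (float)bc2) +
                                        (float)eps));
  }
}

fmat as_channel_matrix(const NumericVector& arr) {
  fmat x(1, arr.size());
  for (long i = 0; i < (long)arr.size(); ++i) x(0, i) = (float)arr[i];
  return x;
}

void check_dims(const UNet& net, const IntegerVector& dim) {
  if (dim.size() != 3) stop("expected a 3D array");
  int f = 1 << (net.depth - 1);
  for (int a = 0; a < 3; ++a) {
    if (dim[a] <= 0) stop("non-positive dimension");
    if (dim[a] % f != 0)
      stop("input dims must be divisible by 2^(depth-1) = %d", f);
  }
}

}  // namespace

// [[Rcpp::export]]
SEXP unet_create(int depth, int base_features, int seed) {
  if (depth < 2) stop("depth must be >= 2");
  if (base_features < 1) stop("base_features must be >= 1");
  UNet* net = new UNet();
  net->depth = depth;
  net->base = base_features;
  net->build();
  {
    // scoped RNG so the given seed fully determines the weights
    Function set_seed("set.seed");
    set_seed(seed);
    GetRNGstate();
    net->init_weights();
    PutRNGstate();
  }
  XPtr<UNet> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
double unet_n_params(SEXP handle) {
  XPtr<UNet> net(handle);
  return (double)net->n_params();
}

// [[Rcpp::export]]
List unet_get_weights(SEXP handle) {
  XPtr<UNet> net(handle);
  List out(net->convs.size());
  for (size_t i = 0; i < net->convs.size(); ++i) {
    Conv& c = net->convs[i];
    NumericMatrix W(c.W.n_rows, c.W.n_cols);
    for (arma::uword j = 0; j < c.W.n_elem; ++j) W[j] = c.W(j);
    NumericVector b(c.b.n_elem);
    for (arma::uword j = 0; j < c.b.n_elem; ++j) b[j] = c.b(j);
    out[i] = List::create(_["W"] = W, _["b"] = b);
  }
  return out;
}

// [[Rcpp::export]]
void unet_set_weights(SEXP handle, List weights) {
  XPtr<UNet> net(handle);
  if ((size_t)weights.size() != net->convs.size())
    stop("weight list length does not match architecture");
  for (size_t i = 0; i < net->convs.size(); ++i) {
    List li = weights[i];
    NumericMatrix W = li["W"];
    NumericVector b = li["b"];
    Conv& c = net->convs[i];
    if ((int)W.nrow() != (int)c.W.n_rows || (int)W.ncol() != (int)c.W.n_cols)
      stop("weight matrix %d has wrong shape", (int)i + 1);
    for (arma::uword j = 0; j < c.W.n_elem; ++j) c.W(j) = (float)W[j];
    for (arma::uword j = 0; j < c.b.n_elem; ++j) c.b(j) = (float)b[j];
  }
}

// [[Rcpp::export]]
NumericVector unet_forward(SEXP handle, NumericVector arr, bool sigmoid) {
  XPtr<UNet> net(handle);
  IntegerVector dim = arr.attr("dim");
  check_dims(*net, dim);
  fmat x = as_channel_matrix(arr);
  fmat logits = unet_forward_pass(*net, x, dim[0], dim[1], dim[2], nullptr);
  NumericVector out(arr.size());
  if (sigmoid) {
    for (long i = 0; i < (long)out.size(); ++i)
      out[i] = 1.0 / (1.0 + std::exp(-(double)logits(0, i)));
  } else {
    for (long i = 0; i < (long)out.size(); ++i) out[i] = logits(0, i);
  }
  out.attr("dim") = dim;
  return out;
}

// One optimisation step on a batch; returns mean BCE-with-logits loss.
// [[Rcpp::export]]
double unet_train_batch(SEXP handle, List xs, List ys, double lr,
                        double beta1, double beta2, double eps) {
  XPtr<UNet> net(handle);
  int B = xs.size();
  if (B < 1 || ys.size() != B) stop("batch lists must be non-empty and paired");
  for (auto& c : net->convs) c.zero_grad();
  double total_loss = 0;
  long total_vox = 0;
  for (int b = 0; b < B; ++b) {
    NumericVector xa = xs[b], ya = ys[b];
    IntegerVector dim = xa.attr("dim");
    check_dims(*net, dim);
    if (ya.size() != xa.size()) stop("label shape mismatch in batch");
    total_vox += (long)xa.size();
  }
  for (int b = 0; b < B; ++b) {
    NumericVector xa = xs[b], ya = ys[b];
    IntegerVector dim = xa.attr("dim");
    fmat x = as_channel_matrix(xa);
    Cache cache;
    fmat logits = unet_forward_pass(*net, x, dim[0], dim[1], dim[2], &cache);
    long N = logits.n_cols;
    fmat dlog(1, N);
    for (long i = 0; i < N; ++i) {
      double z = logits(0, i), y = ya[i];
      double p = 1.0 / (1.0 + std::exp(-z));
      // numerically stable BCE with logits
      double l = std::max(z, 0.0) - z * y + std::log1p(std::exp(-std::fabs(z)));
      total_loss += l;
      dlog(0, i) = (float)((p - y) / (double)total_vox);
    }
    unet_backward_pass(*net, cache, dlog);
  }
  adam_step(*net, lr, beta1, beta2, eps);
  return total_loss / (double)total_vox;
}

// Mean BCE-with-logits loss without updating (for logging/eval).
// [[Rcpp::export]]
double unet_loss(SEXP handle, List xs, List ys) {
  XPtr<UNet> net(handle);
  int B = xs.size();
  double total_loss = 0;
  long total_vox = 0;
  for (int b = 0; b < B; ++b) {
    NumericVector xa = xs[b], ya = ys[b];
    IntegerVector dim = xa.attr("dim");
    check_dims(*net, dim);
    fmat x = as_channel_matrix(xa);
    fmat logits = unet_forward_pass(*net, x, dim[0], dim[1], dim[2], nullptr);
    for (long i = 0; i < (long)logits.n_cols; ++i) {
      double z = logits(0, i), y = ya[i];
      total_loss += std::max(z, 0.0) - z * y +
                    std::log1p(std::exp(-std::fabs(z)));
    }
    total_vox += (long)xa.size();
  }
  return total_loss / (double)total_vox;
}

// Analytic parameter gradients for a single example (finite-difference tests)
// [[Rcpp::export]]
List unet_param_grads(SEXP handle, NumericVector xa, NumericVector ya) {
  XPtr<UNet> net(handle);
  IntegerVector dim = xa.attr("dim");
  check_dims(*net, dim);
  for (auto& c : net->convs) c.zero_grad();
  fmat x = as_channel_matrix(xa);
  Cache cache;
  fmat logits = unet_forward_pass(*net, x, dim[0], dim[1], dim[2], &cache);
  long N = logits.n_cols;
  fmat dlog(1, N);
  for (long i = 0; i < N; ++i) {
    double z = logits(0, i), y = ya[i];
    double p = 1.0 / (1.0 + std::exp(-z));
    dlog(0, i) = (float)((p - y) / (double)N);
  }
  unet_backward_pass(*net, cache, dlog);
  List out(net->convs.size());
  for (size_t i = 0; i < net->convs.size(); ++i) {
    Conv& c = net->convs[i];
    NumericMatrix gW(c.gW.n_rows, c.gW.n_cols);
    for (arma::uword j = 0; j < c.gW.n_elem; ++j) gW[j] = c.gW(j);
    NumericVector gb(c.gb.n_elem);
    for (arma::uword j = 0; j < c.gb.n_elem; ++j) gb[j] = c.gb(j);
    out[i] = List::create(_["W"] = gW, _["b"] = gb);
  }
  return out;
}
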