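// Dual-stream convolutional network for self-supervised phase retrieval.
//
// All tensors are single precision. An activation holding N patches of
// C channels at H x W is stored pixel-major as an arma::fmat with C
// columns; rows enumerate pixels in a guard-padded layout: each patch
// occupies an (H+1) x (W+1) block (column-major, matching R) whose last
// row and last column are kept at zero, and the whole buffer carries
// zero pad strips at both ends. With this layout a zero-padded "same"
// 3x3 convolution is exactly nine row-shifted SGEMM accumulations on
// contiguous views - no im2col materialisation. Convolution weights are
// (9*Cin) x Cout with row index (dx+1)*3*Cin + (dy+1)*Cin + c, so the
// per-offset weight block is a (Cin x Cout) submatrix at leading
// dimension 9*Cin.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
#include <vector>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

using arma::fmat;
using arma::fvec;
using arma::uword;

extern "C" {
void sgemm_(const char* transa, const char* transb, const int* m,
            const int* n, const int* k, const float* alpha, const float* a,
            const int* lda, const float* b, const int* ldb, const float* beta,
            float* c, const int* ldc);
}

namespace {

void gemm(char ta, char tb, int m, int n, int k, float alpha, const float* a,
          int lda, const float* b, int ldb, float beta, float* c, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

struct Geom {
  int C, H, W, N;
  int Hp() const { return H + 1; }
  int Wp() const { return W + 1; }
  long patch() const { return (long)Hp() * Wp(); }
  long lead() const { return (long)Hp() + 2; }
  long rows() const { return lead() + N * patch() + lead(); }
  long px(long n, long x, long y) const {
    return lead() + n * patch() + x * Hp() + y;
  }
};

// zero every non-valid row: pad strips, per-patch guard row and column
void zero_guards(fmat& A, const Geom& g) {
  const long lead = g.lead(), patch = g.patch();
  const int Hp = g.Hp();
  for (uword c = 0; c < A.n_cols; ++c) {
    float* a = A.colptr(c);
    std::memset(a, 0, lead * sizeof(float));
    std::memset(a + lead + g.N * patch, 0, lead * sizeof(float));
    for (long n = 0; n < g.N; ++n) {
      float* pb = a + lead + n * patch;
      std::memset(pb + (long)g.W * Hp, 0, Hp * sizeof(float));     // x = W
      for (int x = 0; x < g.W; ++x) pb[(long)x * Hp + g.H] = 0.0f;  // y = H
    }
  }
}

// resize if needed, zero-filling so guards start clean; the valid region
// is always overwritten by the caller
void ensure(fmat& A, long rows, int cols) {
  if ((long)A.n_rows != rows || (int)A.n_cols != cols) A.zeros(rows, cols);
}

struct ConvLayer {
  fmat W;  // 9*Cin x Cout
  fvec b;
  bool relu;
  bool need_dx;
  fmat y;                        // post-activation output, padded layout
  const fmat* fwd_in = nullptr;  // forward input, set before forward()
  fmat dW, mW, vW;
  fvec db, mb, vb;

  int cin() const { return (int)W.n_rows / 9; }
  int cout() const { return (int)W.n_cols; }

  void init(int in_ch, int out_ch, bool relu_, bool need_dx_) {
    W.zeros(9 * in_ch, out_ch);
    b.zeros(out_ch);
    relu = relu_;
    need_dx = need_dx_;
    mW.zeros(arma::size(W));
    vW.zeros(arma::size(W));
    mb.zeros(out_ch);
    vb.zeros(out_ch);
  }

  // padded-row offset of kernel tap j; taps are ordered dx-major
  static long tap(const Geom& g, int j) {
    const int dx = j / 3 - 1, dy = j % 3 - 1;
    return dy + (long)g.Hp() * dx;
  }

  void forward(const fmat& A, const Geom& gin) {
    const long R = gin.rows();
    const int Ci = cin(), Co = cout();
    fwd_in = &A;
    ensure(y, R, Co);
    for (int j = 0; j < 9; ++j) {
      const long off = tap(gin, j);
      const long r0 = std::max(0L, -off);
      const int M = (int)(R - std::labs(off));
      gemm('N', 'N', M, Co, Ci, 1.0f, A.memptr() + r0 + off, (int)R,
           W.memptr() + (long)j * Ci, (int)W.n_rows, j == 0 ? 0.0f : 1.0f,
           y.memptr() + r0, (int)R);
    }
    for (int c = 0; c < Co; ++c) {
      float* p = y.colptr(c);
      const float bc = b(c);
      if (relu)
        for (long i = 0; i < R; ++i) {
          const float v = p[i] + bc;
          p[i] = v > 0.0f ? v : 0.0f;
        }
      else
        for (long i = 0; i < R; ++i) p[i] += bc;
    }
    Geom gout = gin;
    gout.C = Co;
    zero_guards(y, gout);
  }

  // consumes dY (padded layout, zero on guards); writes the gradient with
  // respect to the layer input into dX when need_dx
  void backward(fmat& dY, const Geom& gin, fmat& dX) {
    const long R = gin.rows();
    const int Ci = cin(), Co = cout();
    const fmat& A = *fwd_in;
    if (relu) {
      for (int c = 0; c < Co; ++c) {
        float* d = dY.colptr(c);
        const float* yy = y.colptr(c);
        for (long i = 0; i < R; ++i)
          if (yy[i] <= 0.0f) d[i] = 0.0f;
      }
    }
    if ((long)dW.n_rows != (long)W.n_rows) dW.set_size(arma::size(W));
    for (int j = 0; j < 9; ++j) {
      // dW_j = A(shifted)^T dY ; exact because dY vanishes on guards
      const long off = tap(gin, j);
      const long r0 = std::max(0L, -off);
      const int K = (int)(R - std::labs(off));
      gemm('T', 'N', Ci, Co, K, 1.0f, A.memptr() + r0 + off, (int)R,
           dY.memptr() + r0, (int)R, 0.0f, dW.memptr() + (long)j * Ci,
           (int)dW.n_rows);
    }
    db = arma::sum(dY, 0).t();
    if (!need_dx) return;
    ensure(dX, R, Ci);
    for (int j = 0; j < 9; ++j) {
      // dX[q] += dY[q - off_j] W_j^T (transposed convolution)
      const long off = tap(gin, j);
      const long s0 = std::max(0L, off);
      const int M = (int)(R - std::labs(off));
      gemm('N', 'T', M, Ci, Co, 1.0f, dY.memptr() + s0 - off, (int)R,
           W.memptr() + (long)j * Ci, (int)W.n_rows, j == 0 ? 0.0f : 1.0f,
           dX.memptr() + s0, (int)R);
    }
    zero_guards(dX, gin);
  }
};

void maxpool_fwd(const fmat& A, const Geom& g, fmat& out, arma::umat& idx) {
  Geom gl = g;
  gl.H = g.H / 2;
  gl.W = g.W / 2;
  ensure(out, gl.rows(), g.C);
  if ((long)idx.n_rows != gl.rows() || (int)idx.n_cols != g.C)
    idx.zeros(gl.rows(), g.C);
  for (int c = 0; c < g.C; ++c) {
    const float* a = A.colptr(c);
    float* o = out.colptr(c);
    uword* ix = idx.colptr(c);
    for (long n = 0; n < g.N; ++n)
      for (int x = 0; x < gl.W; ++x)
        for (int y = 0; y < gl.H; ++y) {
          const long p = g.px(n, 2 * x, 2 * y);
          const long cand[4] = {p, p + 1, p + g.Hp(), p + g.Hp() + 1};
          long bi = cand[0];
          float bv = a[cand[0]];
          for (int t = 1; t < 4; ++t)
            if (a[cand[t]] > bv) { bv = a[cand[t]]; bi = cand[t]; }
          const long q = gl.px(n, x, y);
          o[q] = bv;
          ix[q] = (uword)bi;
        }
  }
}

void maxpool_bwd(const fmat& dOut, const arma::umat& idx, const Geom& g,
                 fmat& dA) {
  Geom gl = g;
  gl.H = g.H / 2;
  gl.W = g.W / 2;
  dA.zeros(g.rows(), g.C);
  for (int c = 0; c < g.C; ++c) {
    float* d = dA.colptr(c);
    const float* o = dOut.colptr(c);
    const uword* ix = idx.colptr(c);
    for (long n = 0; n < g.N; ++n)
      for (int x = 0; x < gl.W; ++x)
        for (int y = 0; y < gl.H; ++y) {
          const long q = gl.px(n, x, y);
          d[ix[q]] += o[q];
        }
  }
}

// nearest-neighbour x2 upsampling; gl is the low-resolution geometry
void upsample_fwd(const fmat& A, const Geom& gl, fmat& out) {
  Geom g = gl;
  g.H = 2 * gl.H;
  g.W = 2 * gl.W;
  ensure(out, g.rows(), gl.C);
  for (int c = 0; c < gl.C; ++c) {
    const float* a = A.colptr(c);
    float* o = out.colptr(c);
    for (long n = 0; n < g.N; ++n)
      for (int x = 0; x < g.W; ++x) {
        const float* src = a + gl.px(n, x / 2, 0);
        float* dst = o + g.px(n, x, 0);
        for (int y = 0; y < g.H; ++y) dst[y] = src[y / 2];
      }
  }
}

void upsample_bwd(const fmat& dOut, const Geom& gl, fmat& dA) {
  Geom g = gl;
  g.H = 2 * gl.H;
  g.W = 2 * gl.W;
  dA.zeros(gl.rows(), gl.C);
  for (int c = 0; c < gl.C; ++c) {
    float* d = dA.colptr(c);
    const float* o = dOut.colptr(c);
    for (long n = 0; n < g.N; ++n)
      for (int x = 0; x < g.W; ++x) {
        float* dst = d + gl.px(n, x / 2, 0);
        const float* src = o + g.px(n, x, 0);
        for (int y = 0; y < g.H; ++y) dst[y / 2] += src[y];
      }
  }
}

// first-order x-derivative with replicate boundary (first column zero),
// acting on a single-channel padded column; matches the R-level operator
void grad_x(const fmat& f, const Geom& g, fmat& out) {
  out.zeros(g.rows(), 1);
  const float* a = f.memptr();
  float* o = out.memptr();
  for (long n = 0; n < g.N; ++n)
    for (int x = 1; x < g.W; ++x) {
      const long p = g.px(n, x, 0);
      for (int y = 0; y < g.H; ++y) o[p + y] = a[p + y] - a[p + y - g.Hp()];
    }
}

void grad_x_adj(const fmat& q, const Geom& g, fmat& out) {
  out.zeros(g.rows(), 1);
  const float* a = q.memptr();
  float* o = out.memptr();
  for (long n = 0; n < g.N; ++n)
    for (int x = 1; x < g.W; ++x) {
      const long p = g.px(n, x, 0);
      for (int y = 0; y < g.H; ++y) {
        o[p + y] += a[p + y];
        o[p + y - g.Hp()] -= a[p + y];
      }
    }
}

void grad_y(const fmat& f, const Geom& g, fmat& out) {
  out.zeros(g.rows(), 1);
  const float* a = f.memptr();
  float* o = out.memptr();
  for (long n = 0; n < g.N; ++n)
    for (int x = 0; x < g.W; ++x) {
      const long p = g.px(n, x, 0);
      for (int y = 1; y < g.H; ++y) o[p + y] = a[p + y] - a[p + y - 1];
    }
}

void grad_y_adj(const fmat& q, const Geom& g, fmat& out) {
  out.zeros(g.rows(), 1);
  const float* a = q.memptr();
  float* o = out.memptr();
  for (long n = 0; n < g.N; ++n)
    for (int x = 0; x < g.W; ++x) {
      const long p = g.px(n, x, 0);
      for (int y = 1; y < g.H; ++y) {
        o[p + y] += a[p + y];
        o[p + y - 1] -= a[p + y];
      }
    }
}

struct Stream {
  std::vector<ConvLayer> enc;
  std::vector<ConvLayer> dec;
  std::vector<fmat> pooled;
  std::vector<arma::umat> pidx;
  std::vector<fmat> skipsum;  // decoder outputs after each skip addition
  bool is_base;
  const fmat& out() const {
    return skipsum.empty() ? enc.back().y : skipsum.back();
  }
};

class Net {
 public:
  int depth, base_feat, fusion_blocks, cin_base, cin_detail;
  Stream base, detail;
  std::vector<ConvLayer> fus;  // fusion_blocks-1 blocks of base_feat, then
  ConvLayer outL;              // the final 1-channel convolution
  long adam_t;
  fmat S_, f_;
  fmat Xb_, Xd_;  // inputs kept alive for the first-layer weight gradients

  Net(int depth_, int base_feat_, int fusion_blocks_, int cb, int cd)
      : depth(depth_), base_feat(base_feat_), fusion_blocks(fusion_blocks_),
        cin_base(cb), cin_detail(cd), adam_t(0) {
    base.is_base = true;
    detail.is_base = false;
    init_stream(base, cb);
    init_stream(detail, cd);
    fus.resize(fusion_blocks - 1);
    for (int i = 0; i < fusion_blocks - 1; ++i)
      fus[i].init(base_feat, base_feat, true, true);
    outL.init(base_feat, 1, false, true);
  }

  int feat(int level) const { return base_feat << level; }

  void init_stream(Stream& s, int cin) {
    s.enc.resize(depth);
    s.dec.resize(depth - 1);
    s.enc[0].init(cin, feat(0), true, false);
    for (int l = 1; l < depth; ++l)
      s.enc[l].init(feat(l - 1), feat(l), true, true);
    for (int i = 0; i < depth - 1; ++i) {
      const int l = depth - 1 - i;
      s.dec[i].init(feat(l), feat(l - 1), true, true);
    }
  }

  std::vector<ConvLayer*> layers() {
    std::vector<ConvLayer*> v;
    for (auto& L : base.enc) v.push_back(&L);
    for (auto& L : base.dec) v.push_back(&L);
    for (auto& L : detail.enc) v.push_back(&L);
    for (auto& L : detail.dec) v.push_back(&L);
    for (auto& L : fus) v.push_back(&L);
    v.push_back(&outL);
    return v;
  }

  Geom glev(int level, int H, int W, int N) const {
    Geom g;
    g.C = feat(level);
    g.H = H >> level;
    g.W = W >> level;
    g.N = N;
    return g;
  }

  void stream_fwd(Stream& s, const fmat& X, int H, int W, int N) {
    Geom gin = glev(0, H, W, N);
    gin.C = s.is_base ? cin_base : cin_detail;
    s.enc[0].forward(X, gin);
    if ((int)s.pooled.size() != depth) {
      s.pooled.resize(depth);
      s.pidx.resize(depth);
    }
    for (int l = 1; l < depth; ++l) {
      Geom gp = glev(l - 1, H, W, N);
      maxpool_fwd(s.enc[l - 1].y, gp, s.pooled[l], s.pidx[l]);
      Geom gi = gp;
      gi.H /= 2;
      gi.W /= 2;
      s.enc[l].forward(s.pooled[l], gi);
    }
    if ((int)s.skipsum.size() != depth - 1) s.skipsum.resize(depth - 1);
    const fmat* cur = &s.enc[depth - 1].y;
    for (int i = 0; i < depth - 1; ++i) {
      const int l = depth - 1 - i;
      Geom gi = glev(l, H, W, N);
      s.dec[i].forward(*cur, gi);
      Geom gl = gi;
      gl.C = feat(l - 1);
      fmat up;
      upsample_fwd(s.dec[i].y, gl, up);
      s.skipsum[i] = up + s.enc[l - 1].y;  // additive skip connection
      cur = &s.skipsum[i];
    }
  }

  void stream_bwd(Stream& s, const fmat& dOut, int H, int W, int N) {
    std::vector<fmat> gskip(depth);
    fmat G = dOut;
    for (int i = depth - 2; i >= 0; --i) {
      const int l = depth - 1 - i;
      if (gskip[l - 1].n_elem == 0)
        gskip[l - 1] = G;
      else
        gskip[l - 1] += G;
      Geom gl = glev(l, H, W, N);
      gl.C = feat(l - 1);
      fmat dlow;
      upsample_bwd(G, gl, dlow);
      Geom gi = glev(l, H, W, N);
      fmat dX;
      s.dec[i].backward(dlow, gi, dX);
      G = std::move(dX);
    }
    for (int l = depth - 1; l >= 1; --l) {
      Geom gp = glev(l - 1, H, W, N);
      Geom gi = gp;
      gi.H /= 2;
      gi.W /= 2;
      fmat dPool;
      s.enc[l].backward(G, gi, dPool);
      fmat dPrev;
      maxpool_bwd(dPool, s.pidx[l], gp, dPrev);
      G = std::move(dPrev);
      if (gskip[l - 1].n_elem > 0) G += gskip[l - 1];
    }
    Geom gin = glev(0, H, W, N);
    gin.C = s.is_base ? cin_base : cin_detail;
    fmat unused;
    s.enc[0].backward(G, gin, unused);
  }

  const fmat& forward(const fmat& Xb, const fmat& Xd, int H, int W, int N) {
    stream_fwd(base, Xb, H, W, N);
    stream_fwd(detail, Xd, H, W, N);
    S_ = base.out() + detail.out();
    Geom gf = glev(0, H, W, N);
    const fmat* cur = &S_;
    for (size_t i = 0; i < fus.size(); ++i) {
      fus[i].forward(*cur, gf);
      cur = &fus[i].y;
    }
    outL.forward(*cur, gf);
    f_ = outL.y;  // rows x 1, padded layout
    return f_;
  }

  void backward(fmat& df, int H, int W, int N) {
    Geom gf = glev(0, H, W, N);
    fmat G;
    outL.backward(df, gf, G);
    for (int i = (int)fus.size() - 1; i >= 0; --i) {
      fmat dX;
      fus[i].backward(G, gf, dX);
      G = std::move(dX);
    }
    stream_bwd(base, G, H, W, N);
    stream_bwd(detail, G, H, W, N);
  }

  void adam_step(double lr) {
    ++adam_t;
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    const float c1 = 1.0f - std::pow(b1, (float)adam_t);
    const float c2 = 1.0f - std::pow(b2, (float)adam_t);
    const float a = (float)lr;
    for (ConvLayer* L : layers()) {
      L->mW = b1 * L->mW + (1.0f - b1) * L->dW;
      L->vW = b2 * L->vW + (1.0f - b2) * arma::square(L->dW);
      L->W -= a * (L->mW / c1) / (arma::sqrt(L->vW / c2) + eps);
      L->mb = b1 * L->mb + (1.0f - b1) * L->db;
      L->vb = b2 * L->vb + (1.0f - b2) * arma::square(L->db);
      L->b -= a * (L->mb / c1) / (arma::sqrt(L->vb / c2) + eps);
    }
  }
};

// R array (H, W, C, N) -> padded pixel-major fmat
fmat to_fmat(const Rcpp::NumericVector& a, const Geom& g) {
  fmat out(g.rows(), g.C, arma::fill::zeros);
  const double* p = a.begin();
  const long HW = (long)g.H * g.W;
  for (long n = 0; n < g.N; ++n)
    for (int c = 0; c < g.C; ++c) {
      const double* src = p + HW * (c + (long)g.C * n);
      float* dst = out.colptr(c);
      for (int x = 0; x < g.W; ++x) {
        const long q = g.px(n, x, 0);
        const double* s2 = src + (long)x * g.H;
        for (int y = 0; y < g.H; ++y) dst[q + y] = (float)s2[y];
      }
    }
  return out;
}

}  // namespace

typedef Rcpp::XPtr<Net> NetPtr;

// [[Rcpp::export]]
bool nn_valid(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != nullptr;
}

// [[Rcpp::export]]
SEXP nn_create(int depth, int base_feat, int fusion_blocks, int cin_base,
               int cin_detail) {
  if (depth < 1) Rcpp::stop("stream depth must be >= 1");
  if (fusion_blocks < 1) Rcpp::stop("fusion_blocks must be >= 1");
  Net* net = new Net(depth, base_feat, fusion_blocks, cin_base, cin_detail);
  return NetPtr(net, true);
}

// [[Rcpp::export]]
Rcpp::List nn_param_shapes(SEXP ptr) {
  NetPtr net(ptr);
  auto ls = net->layers();
  Rcpp::List out(ls.size());
  for (size_t i = 0; i < ls.size(); ++i)
    out[i] = Rcpp::List::create(
        Rcpp::Named("w") = Rcpp::IntegerVector::create((int)ls[i]->W.n_rows,
                                                       (int)ls[i]->W.n_cols),
        Rcpp::Named("b") = (int)ls[i]->b.n_elem);
  return out;
}

// [[Rcpp::export]]
double nn_param_count(SEXP ptr) {
  NetPtr net(ptr);
  double n = 0;
  for (ConvLayer* L : net->layers()) n += L->W.n_elem + L->b.n_elem;
  return n;
}

// [[Rcpp::export]]
void nn_set_weights(SEXP ptr, Rcpp::List weights) {
  NetPtr net(ptr);
  auto ls = net->layers();
  if ((size_t)weights.size() != ls.size())
    Rcpp::stop("expected %d weight entries, got %d", (int)ls.size(),
               (int)weights.size());
  for (size_t i = 0; i < ls.size(); ++i) {
    Rcpp::List wi = weights[i];
    Rcpp::NumericMatrix W = wi["w"];
    Rcpp::NumericVector b = wi["b"];
    if ((uword)W.nrow() != ls[i]->W.n_rows ||
        (uword)W.ncol() != ls[i]->W.n_cols)
      Rcpp::stop("weight shape mismatch at layer %d", (int)i + 1);
    for (uword j = 0; j < ls[i]->W.n_elem; ++j) ls[i]->W(j) = (float)W[j];
    for (uword j = 0; j < ls[i]->b.n_elem; ++j) ls[i]->b(j) = (float)b[j];
  }
}

// [[Rcpp::export]]
Rcpp::List nn_get_weights(SEXP ptr) {
  NetPtr net(ptr);
  auto ls = net->layers();
  Rcpp::List out(ls.size());
  for (size_t i = 0; i < ls.size(); ++i) {
    Rcpp::NumericMatrix W((int)ls[i]->W.n_rows, (int)ls[i]->W.n_cols);
    Rcpp::NumericVector b((int)ls[i]->b.n_elem);
    for (uword j = 0; j < ls[i]->W.n_elem; ++j) W[j] = ls[i]->W(j);
    for (uword j = 0; j < ls[i]->b.n_elem; ++j) b[j] = ls[i]->b(j);
    out[i] = Rcpp::List::create(Rcpp::Named("w") = W, Rcpp::Named("b") = b);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_train_step(SEXP ptr, Rcpp::NumericVector base,
                                  Rcpp::NumericVector detail,
                                  Rcpp::NumericVector target,
                                  Rcpp::NumericVector mask, double lr,
                                  double lambda1, double lambda2,
                                  double detail_scale) {
#ifdef __SSE2__
  // flush subnormal floats to zero: near-zero gradients are numerically
  // irrelevant here but catastrophically slow in hardware
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
  NetPtr net(ptr);
  Rcpp::IntegerVector db = base.attr("dim");
  const int H = db[0], W = db[1], N = db[3];
  Geom gb{net->cin_base, H, W, N}, gd{net->cin_detail, H, W, N},
      g1{1, H, W, N};
  net->Xb_ = to_fmat(base, gb);
  net->Xd_ = to_fmat(detail, gd);
  if (detail_scale != 1.0) net->Xd_ *= (float)(1.0 / detail_scale);
  fmat phi = to_fmat(target, g1);
  fmat msk = to_fmat(mask, g1);

  const fmat& f = net->forward(net->Xb_, net->Xd_, H, W, N);
  const double Np = (double)H * W * N;

  fmat gx, gy;
  grad_x(f, g1, gx);
  grad_y(f, g1, gy);
  fmat r = gx - phi;
  const double Ld = arma::accu(arma::square(r)) / Np;
  const double Ltv =
      (arma::accu(arma::abs(gx)) + arma::accu(arma::abs(gy))) / Np;
  const double Lm = arma::accu(msk % arma::square(f)) / Np;
  const double total = Ld + lambda1 * Ltv + lambda2 * Lm;

  fmat df(f.n_rows, 1, arma::fill::zeros), t1, t2;
  grad_x_adj(r, g1, t1);
  df += (float)(2.0 / Np) * t1;
  fmat sx = arma::sign(gx), sy = arma::sign(gy);
  grad_x_adj(sx, g1, t1);
  grad_y_adj(sy, g1, t2);
  df += (float)(lambda1 / Np) * (t1 + t2);
  df += (float)(2.0 * lambda2 / Np) * (msk % f);

  net->backward(df, H, W, N);
  net->adam_step(lr);

  return Rcpp::NumericVector::create(
      Rcpp::Named("total") = total, Rcpp::Named("data") = Ld,
      Rcpp::Named("tv") = Ltv, Rcpp::Named("mask") = Lm);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix nn_predict(SEXP ptr, Rcpp::NumericVector base,
                               Rcpp::NumericVector detail) {
#ifdef __SSE2__
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
  NetPtr net(ptr);
  Rcpp::IntegerVector db = base.attr("dim");
  const int H = db[0], W = db[1];
  Geom gb{net->cin_base, H, W, 1}, gd{net->cin_detail, H, W, 1},
      g1{1, H, W, 1};
  fmat Xb = to_fmat(base, gb);
  fmat Xd = to_fmat(detail, gd);
  const fmat& f = net->forward(Xb, Xd, H, W, 1);
  Rcpp::NumericMatrix out(H, W);
  const float* a = f.memptr();
  for (int x = 0; x < W; ++x) {
    const long q = g1.px(0, x, 0);
    for (int y = 0; y < H; ++y) out(y, x) = a[q + y];
  }
  return out;
}
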