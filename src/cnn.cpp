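// Trainable CNN for spectrogram-image multi-label classification.
//
// Data layout: activations are (B*H*W) x C single-precision matrices,
// row index r = b*H*W + h*W + w (h = time frame, w = mel band), one column
// per channel.  Convolutions are 3x3 "same", realised as im2col + GEMM so
// the heavy lifting goes through BLAS.  Every convolution (and every dense
// head layer, a 1x1 convolution over the 16-step sequence) is preceded by a
// batch-normalisation layer.  All randomness (weight init, shuffling) is
// supplied from R, so results are reproducible given R's RNG state.
//
// Training caches: im2col matrices and BN inputs are retained from the
// forward pass (moved, not copied) and reused in backward; peak memory at
// batch size 8 on a 512x128 input stays under ~0.7 GB.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.9f;   // running-stat momentum
static const float ADAM_B1 = 0.9f, ADAM_B2 = 0.999f, ADAM_EPS = 1e-8f;

struct BNLayer {
  fvec g, b, rm, rv;          // gamma, beta, running mean/var
  fvec mg, vg, mb, vb;        // Adam moments
  fmat xc;                    // cached input (training; moved in)
  fvec mu, var;               // cached batch stats
  void init(int C) {
    g.ones(C); b.zeros(C); rm.zeros(C); rv.ones(C);
    mg.zeros(C); vg.zeros(C); mb.zeros(C); vb.zeros(C);
  }
};

struct LinLayer {             // conv (W: 9*Cin x Cout) or dense (W: Din x Dout)
  fmat W; frowvec b;
  fmat mW, vW; frowvec mb, vb;
  fmat M;                     // cached im2col of the conv input (training)
  fmat out;                   // cached post-ReLU output where needed
  void init(int din, int dout) {
    W.zeros(din, dout); b.zeros(dout);
    mW.zeros(din, dout); vW.zeros(din, dout);
    mb.zeros(dout); vb.zeros(dout);
  }
};

struct Net {
  int H, W, K, headF;
  ivec filters;               // length 5
  std::vector<BNLayer> bn;    // 13: a0,b0,...,a4,b4,h1,h2,out
  std::vector<LinLayer> lin;  // 13: ca0,cb0,...,ca4,cb4,d1,d2,dout
  std::vector<umat> amax;     // pool argmax per block
  long t_adam = 0;
  int Ht, Wt, D;              // head sequence length, width, reshape dim
};

// ---- helpers ---------------------------------------------------------------

// Build the im2col matrix for a 3x3 "same" convolution.  Only the border
// cells are zero-filled; the interior is copied row-wise.
static void im2col(const fmat& x, int B, int H, int W, int C, fmat& M) {
  const uword HW = (uword)H * W;
  M.set_size((uword)B * HW, (uword)9 * C);
  for (int k = 0; k < 9; ++k) {
    const int dh = k / 3 - 1, dw = k % 3 - 1;
    const int h0 = std::max(0, -dh), h1 = H - std::max(0, dh);
    const int w0 = std::max(0, -dw);
    const int L = W - std::abs(dw);
    for (int c = 0; c < C; ++c) {
      const float* src = x.colptr(c);
      float* dst = M.colptr((uword)k * C + c);
      for (int b = 0; b < B; ++b) {
        const uword base = (uword)b * HW;
        for (int h = 0; h < h0; ++h)
          std::memset(dst + base + (uword)h * W, 0, (size_t)W * sizeof(float));
        for (int h = h0; h < h1; ++h) {
          float* drow = dst + base + (uword)h * W;
          if (w0 > 0) drow[0] = 0.0f;
          std::memcpy(drow + w0,
                      src + base + (uword)(h + dh) * W + (w0 + dw),
                      (size_t)L * sizeof(float));
          if (w0 + L < W) drow[W - 1] = 0.0f;
        }
        for (int h = h1; h < H; ++h)
          std::memset(dst + base + (uword)h * W, 0, (size_t)W * sizeof(float));
      }
    }
  }
}

static void col2im(const fmat& G, int B, int H, int W, int C, fmat& dx) {
  const uword HW = (uword)H * W;
  dx.zeros((uword)B * HW, C);
  for (int k = 0; k < 9; ++k) {
    const int dh = k / 3 - 1, dw = k % 3 - 1;
    const int h0 = std::max(0, -dh), h1 = H - std::max(0, dh);
    const int w0 = std::max(0, -dw);
    const int L = W - std::abs(dw);
    for (int c = 0; c < C; ++c) {
      float* dst = dx.colptr(c);
      const float* src = G.colptr((uword)k * C + c);
      for (int b = 0; b < B; ++b) {
        const uword base = (uword)b * HW;
        for (int h = h0; h < h1; ++h) {
          float* d = dst + base + (uword)(h + dh) * W + (w0 + dw);
          const float* s = src + base + (uword)h * W + w0;
          for (int i = 0; i < L; ++i) d[i] += s[i];
        }
      }
    }
  }
}

static void pool_fwd(const fmat& x, int B, int H, int W, int C,
                     fmat& out, umat& am) {
  const int Ho = H / 2, Wo = W / 2;
  const uword HWo = (uword)Ho * Wo, HW = (uword)H * W;
  out.set_size((uword)B * HWo, C);
  am.set_size((uword)B * HWo, C);
  for (int c = 0; c < C; ++c) {
    const float* src = x.colptr(c);
    float* o = out.colptr(c);
    uword* a = am.colptr(c);
    for (int b = 0; b < B; ++b) {
      for (int ho = 0; ho < Ho; ++ho) {
        for (int wo = 0; wo < Wo; ++wo) {
          uword r = (uword)b * HW + (uword)(2 * ho) * W + 2 * wo;
          uword best = r; float bv = src[r];
          if (src[r + 1] > bv) { bv = src[r + 1]; best = r + 1; }
          if (src[r + W] > bv) { bv = src[r + W]; best = r + W; }
          if (src[r + W + 1] > bv) { bv = src[r + W + 1]; best = r + W + 1; }
          uword ro = (uword)b * HWo + (uword)ho * Wo + wo;
          o[ro] = bv; a[ro] = best;
        }
      }
    }
  }
}

static void pool_bwd(const fmat& g, const umat& am, uword rows_in, fmat& dx) {
  dx.zeros(rows_in, g.n_cols);
  for (uword c = 0; c < g.n_cols; ++c) {
    const float* gs = g.colptr(c);
    const uword* a = am.colptr(c);
    float* d = dx.colptr(c);
    for (uword r = 0; r < g.n_rows; ++r) d[a[r]] += gs[r];
  }
}

static inline void relu_(fmat& y) {
  float* p = y.memptr();
  for (uword i = 0; i < y.n_elem; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}

// zero the gradient where the post-ReLU reference output is zero
static inline void relu_mask_(fmat& g, const fmat& ref) {
  float* gp = g.memptr();
  const float* rp = ref.memptr();
  for (uword i = 0; i < g.n_elem; ++i) if (rp[i] <= 0.0f) gp[i] = 0.0f;
}

// training-mode BN: takes ownership of x, caches it, returns normalized out
static fmat bn_fwd_train(BNLayer& L, fmat&& x) {
  const int C = x.n_cols;
  L.xc = std::move(x);
  fmat y(L.xc.n_rows, C);
  L.mu.set_size(C); L.var.set_size(C);
  for (int c = 0; c < C; ++c) {
    L.mu(c) = mean(L.xc.col(c));
    L.var(c) = mean(square(L.xc.col(c) - L.mu(c)));
  }
  L.rm = BN_MOM * L.rm + (1.0f - BN_MOM) * L.mu;
  L.rv = BN_MOM * L.rv + (1.0f - BN_MOM) * L.var;
  for (int c = 0; c < C; ++c) {
    float sd = std::sqrt(L.var(c) + BN_EPS);
    y.col(c) = (L.xc.col(c) - L.mu(c)) * (L.g(c) / sd) + L.b(c);
  }
  return y;
}

static fmat bn_fwd_eval(const BNLayer& L, const fmat& x) {
  const int C = x.n_cols;
  fmat y(x.n_rows, C);
  for (int c = 0; c < C; ++c) {
    float sd = std::sqrt(L.rv(c) + BN_EPS);
    y.col(c) = (x.col(c) - L.rm(c)) * (L.g(c) / sd) + L.b(c);
  }
  return y;
}

// recompute the BN output from cached input/stats (head layers only)
static fmat bn_recompute(const BNLayer& L) {
  const int C = L.xc.n_cols;
  fmat y(L.xc.n_rows, C);
  for (int c = 0; c < C; ++c) {
    float sd = std::sqrt(L.var(c) + BN_EPS);
    y.col(c) = (L.xc.col(c) - L.mu(c)) * (L.g(c) / sd) + L.b(c);
  }
  return y;
}

static void adam_vec(fvec& p, const fvec& g, fvec& m, fvec& v,
                     float lr, long t) {
  m = ADAM_B1 * m + (1.0f - ADAM_B1) * g;
  v = ADAM_B2 * v + (1.0f - ADAM_B2) * square(g);
  float c1 = 1.0f - std::pow(ADAM_B1, (float)t);
  float c2 = 1.0f - std::pow(ADAM_B2, (float)t);
  p -= lr * (m / c1) / (sqrt(v / c2) + ADAM_EPS);
}

static void adam_mat(fmat& p, const fmat& g, fmat& m, fmat& v,
                     float lr, long t) {
  m = ADAM_B1 * m + (1.0f - ADAM_B1) * g;
  v = ADAM_B2 * v + (1.0f - ADAM_B2) * square(g);
  float c1 = 1.0f - std::pow(ADAM_B1, (float)t);
  float c2 = 1.0f - std::pow(ADAM_B2, (float)t);
  p -= lr * (m / c1) / (sqrt(v / c2) + ADAM_EPS);
}

static void adam_row(frowvec& p, const frowvec& g, frowvec& m, frowvec& v,
                     float lr, long t) {
  frowvec gg = g;
  m = ADAM_B1 * m + (1.0f - ADAM_B1) * gg;
  v = ADAM_B2 * v + (1.0f - ADAM_B2) * square(gg);
  float c1 = 1.0f - std::pow(ADAM_B1, (float)t);
  float c2 = 1.0f - std::pow(ADAM_B2, (float)t);
  p -= lr * (m / c1) / (sqrt(v / c2) + ADAM_EPS);
}

// BN backward; updates gamma/beta via Adam, returns dL/dx, releases cache.
static fmat bn_bwd(BNLayer& L, const fmat& dy, float lr, long t) {
  const int C = dy.n_cols;
  const float N = (float)dy.n_rows;
  fmat dx(dy.n_rows, C);
  fvec dg(C), db(C);
  for (int c = 0; c < C; ++c) {
    float sd = std::sqrt(L.var(c) + BN_EPS);
    fvec xhat = (L.xc.col(c) - L.mu(c)) / sd;
    const fvec dyc = dy.col(c);
    dg(c) = dot(dyc, xhat);
    db(c) = accu(dyc);
    dx.col(c) = (L.g(c) / (N * sd)) *
      (N * dyc - db(c) - xhat * dg(c));
  }
  adam_vec(L.g, dg, L.mg, L.vg, lr, t);
  adam_vec(L.b, db, L.mb, L.vb, lr, t);
  // note: xc is kept -- callers may still need it for an upstream ReLU mask
  return dx;
}

// ---- network construction --------------------------------------------------

// [[Rcpp::export(name = ".cnn_new")]]
SEXP cnn_new(Rcpp::IntegerVector filters, int head_filters, int n_classes,
             int H, int W) {
  if (filters.size() != 5) Rcpp::stop("need 5 block filter counts");
  if (H % 32 != 0 || W % 32 != 0) Rcpp::stop("H and W must be divisible by 32");
  Net* net = new Net();
  net->H = H; net->W = W; net->K = n_classes; net->headF = head_filters;
  net->filters = ivec(5);
  for (int i = 0; i < 5; ++i) net->filters(i) = filters[i];
  net->bn.resize(13); net->lin.resize(13); net->amax.resize(5);
  int cin = 1;
  for (int i = 0; i < 5; ++i) {
    int f = filters[i];
    net->bn[2 * i].init(cin);
    net->lin[2 * i].init(9 * cin, f);
    net->bn[2 * i + 1].init(f);
    net->lin[2 * i + 1].init(9 * f, f);
    cin = f;
  }
  net->Ht = H / 32; net->Wt = W / 32; net->D = net->Wt * cin;
  net->bn[10].init(net->D);  net->lin[10].init(net->D, head_filters);
  net->bn[11].init(head_filters); net->lin[11].init(head_filters, head_filters);
  net->bn[12].init(head_filters); net->lin[12].init(head_filters, n_classes);
  Rcpp::XPtr<Net> p(net, true);
  return p;
}

// [[Rcpp::export(name = ".cnn_n_weights")]]
int cnn_n_weights(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  long n = 0;
  for (auto& L : net->lin) n += L.W.n_elem;
  return (int)n;
}

// [[Rcpp::export(name = ".cnn_n_params")]]
double cnn_n_params(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  double n = 0;
  for (auto& L : net->lin) n += L.W.n_elem + L.b.n_elem;
  for (auto& B : net->bn) n += B.g.n_elem + B.b.n_elem;
  return n;
}

// Fill weights from a supplied vector of standard normals (He scaling);
// biases, betas zero; gammas one.
// [[Rcpp::export(name = ".cnn_init_weights")]]
void cnn_init_weights(SEXP ptr, Rcpp::NumericVector z) {
  Rcpp::XPtr<Net> net(ptr);
  long need = 0;
  for (auto& L : net->lin) need += L.W.n_elem;
  if ((long)z.size() != need) Rcpp::stop("init vector has wrong length");
  long off = 0;
  for (auto& L : net->lin) {
    float sc = std::sqrt(2.0f / (float)L.W.n_rows);
    for (uword i = 0; i < L.W.n_elem; ++i)
      L.W(i) = (float)z[off + i] * sc;
    off += L.W.n_elem;
    L.b.zeros(); L.mW.zeros(); L.vW.zeros(); L.mb.zeros(); L.vb.zeros();
  }
  for (auto& B : net->bn) {
    B.g.ones(); B.b.zeros(); B.rm.zeros(); B.rv.ones();
    B.mg.zeros(); B.vg.zeros(); B.mb.zeros(); B.vb.zeros();
  }
  net->t_adam = 0;
}

// ---- state (serialization) -------------------------------------------------

// [[Rcpp::export(name = ".cnn_get_state")]]
Rcpp::List cnn_get_state(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  Rcpp::List out;
  auto put_f = [&](const fmat& m, std::string nm) {
    Rcpp::NumericMatrix r(m.n_rows, m.n_cols);
    for (uword i = 0; i < m.n_elem; ++i) r[i] = m(i);
    out[nm] = r;
  };
  auto put_v = [&](const fvec& v, std::string nm) {
    out[nm] = Rcpp::NumericVector(v.begin(), v.end());
  };
  for (int i = 0; i < 13; ++i) {
    std::string s = std::to_string(i);
    LinLayer& L = net->lin[i];
    put_f(L.W, "W" + s);
    out["wb" + s] = Rcpp::NumericVector(L.b.begin(), L.b.end());
    put_f(L.mW, "mW" + s); put_f(L.vW, "vW" + s);
    out["mwb" + s] = Rcpp::NumericVector(L.mb.begin(), L.mb.end());
    out["vwb" + s] = Rcpp::NumericVector(L.vb.begin(), L.vb.end());
    BNLayer& B = net->bn[i];
    put_v(B.g, "g" + s); put_v(B.b, "bb" + s);
    put_v(B.rm, "rm" + s); put_v(B.rv, "rv" + s);
    put_v(B.mg, "mg" + s); put_v(B.vg, "vg" + s);
    put_v(B.mb, "mbb" + s); put_v(B.vb, "vbb" + s);
  }
  out["t_adam"] = (double)net->t_adam;
  return out;
}

// [[Rcpp::export(name = ".cnn_set_state")]]
void cnn_set_state(SEXP ptr, Rcpp::List st) {
  Rcpp::XPtr<Net> net(ptr);
  auto get_f = [&](fmat& m, std::string nm) {
    Rcpp::NumericMatrix r = st[nm];
    if ((uword)r.nrow() != m.n_rows || (uword)r.ncol() != m.n_cols)
      Rcpp::stop("state shape mismatch at %s", nm.c_str());
    for (uword i = 0; i < m.n_elem; ++i) m(i) = (float)r[i];
  };
  auto get_v = [&](fvec& v, std::string nm) {
    Rcpp::NumericVector r = st[nm];
    if ((uword)r.size() != v.n_elem) Rcpp::stop("state length mismatch");
    for (uword i = 0; i < v.n_elem; ++i) v(i) = (float)r[i];
  };
  auto get_r = [&](frowvec& v, std::string nm) {
    Rcpp::NumericVector r = st[nm];
    if ((uword)r.size() != v.n_elem) Rcpp::stop("state length mismatch");
    for (uword i = 0; i < v.n_elem; ++i) v(i) = (float)r[i];
  };
  for (int i = 0; i < 13; ++i) {
    std::string s = std::to_string(i);
    LinLayer& L = net->lin[i];
    get_f(L.W, "W" + s); get_r(L.b, "wb" + s);
    get_f(L.mW, "mW" + s); get_f(L.vW, "vW" + s);
    get_r(L.mb, "mwb" + s); get_r(L.vb, "vwb" + s);
    BNLayer& B = net->bn[i];
    get_v(B.g, "g" + s); get_v(B.b, "bb" + s);
    get_v(B.rm, "rm" + s); get_v(B.rv, "rv" + s);
    get_v(B.mg, "mg" + s); get_v(B.vg, "vg" + s);
    get_v(B.mb, "mbb" + s); get_v(B.vb, "vbb" + s);
  }
  net->t_adam = (long)Rcpp::as<double>(st["t_adam"]);
}

// ---- forward / training ----------------------------------------------------

// Convert R array (H x W x B, column-major per sample: time fastest) to the
// internal (B*H*W) x 1 layout with row = b*HW + h*W + w.
static fmat to_internal(const Rcpp::NumericVector& x, int B, int H, int W) {
  const uword HW = (uword)H * W;
  if ((uword)x.size() != HW * B) Rcpp::stop("input length != H*W*B");
  fmat out((uword)B * HW, 1);
  const double* src = x.begin();
  float* dst = out.colptr(0);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        dst[(uword)b * HW + (uword)h * W + w] =
          (float)src[(uword)b * HW + (uword)w * H + h];
  return out;
}

static fmat head_reshape(const fmat& x, int B, int Ht, int Wt, int C) {
  fmat R((uword)B * Ht, (uword)Wt * C);
  for (int c = 0; c < C; ++c) {
    const float* src = x.colptr(c);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Ht; ++t)
        for (int w = 0; w < Wt; ++w)
          R((uword)b * Ht + t, (uword)w * C + c) =
            src[(uword)b * Ht * Wt + (uword)t * Wt + w];
  }
  return R;
}

static fmat head_unshape(const fmat& g, int B, int Ht, int Wt, int C) {
  fmat x((uword)B * Ht * Wt, C);
  for (int c = 0; c < C; ++c) {
    float* dst = x.colptr(c);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Ht; ++t)
        for (int w = 0; w < Wt; ++w)
          dst[(uword)b * Ht * Wt + (uword)t * Wt + w] =
            g((uword)b * Ht + t, (uword)w * C + c);
  }
  return x;
}

static fmat forward_eval(Net* net, const fmat& x0, int B) {
  int H = net->H, W = net->W, C = 1;
  fmat x = x0, M, y;
  for (int i = 0; i < 5; ++i) {
    int f = net->filters(i);
    x = bn_fwd_eval(net->bn[2 * i], x);
    im2col(x, B, H, W, C, M);
    y = M * net->lin[2 * i].W;
    y.each_row() += net->lin[2 * i].b;
    relu_(y);
    x = bn_fwd_eval(net->bn[2 * i + 1], y);
    im2col(x, B, H, W, f, M);
    y = M * net->lin[2 * i + 1].W;
    y.each_row() += net->lin[2 * i + 1].b;
    relu_(y);
    umat am;
    fmat pooled;
    pool_fwd(y, B, H, W, f, pooled, am);
    x = pooled; H /= 2; W /= 2; C = f;
  }
  x = head_reshape(x, B, net->Ht, net->Wt, C);
  for (int j = 10; j <= 12; ++j) {
    x = bn_fwd_eval(net->bn[j], x);
    y = x * net->lin[j].W;
    y.each_row() += net->lin[j].b;
    if (j < 12) relu_(y);
    x = y;
  }
  x.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
  return x;
}

// training forward; caches im2col matrices, BN inputs, ReLU outputs
static fmat forward_train(Net* net, fmat&& x0, int B) {
  int H = net->H, W = net->W, C = 1;
  fmat x = std::move(x0), y;
  for (int i = 0; i < 5; ++i) {
    int f = net->filters(i);
    x = bn_fwd_train(net->bn[2 * i], std::move(x));
    im2col(x, B, H, W, C, net->lin[2 * i].M);
    y = net->lin[2 * i].M * net->lin[2 * i].W;
    y.each_row() += net->lin[2 * i].b;
    relu_(y);
    // post-ReLU output doubles as the next BN's cached input
    x = bn_fwd_train(net->bn[2 * i + 1], std::move(y));
    im2col(x, B, H, W, f, net->lin[2 * i + 1].M);
    y = net->lin[2 * i + 1].M * net->lin[2 * i + 1].W;
    y.each_row() += net->lin[2 * i + 1].b;
    relu_(y);
    fmat pooled;
    pool_fwd(y, B, H, W, f, pooled, net->amax[i]);
    net->lin[2 * i + 1].out = std::move(y);   // kept for the ReLU mask
    x = std::move(pooled); H /= 2; W /= 2; C = f;
  }
  x = head_reshape(x, B, net->Ht, net->Wt, C);
  for (int j = 10; j <= 12; ++j) {
    x = bn_fwd_train(net->bn[j], std::move(x));
    y = x * net->lin[j].W;
    y.each_row() += net->lin[j].b;
    if (j < 12) relu_(y);
    x = std::move(y);
  }
  x.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
  return x;
}

// Refresh the batch-norm running statistics under the current weights by
// running training-mode forward passes (no parameter updates); used as a
// final calibration step after the optimizer loop.
// [[Rcpp::export(name = ".cnn_update_stats")]]
void cnn_update_stats(SEXP ptr, Rcpp::NumericVector x, int B) {
  Rcpp::XPtr<Net> net(ptr);
  fmat x0 = to_internal(x, B, net->H, net->W);
  forward_train(net, std::move(x0), B);
}

// [[Rcpp::export(name = ".cnn_forward")]]
Rcpp::NumericMatrix cnn_forward(SEXP ptr, Rcpp::NumericVector x, int B) {
  Rcpp::XPtr<Net> net(ptr);
  fmat x0 = to_internal(x, B, net->H, net->W);
  fmat p = forward_eval(net, x0, B);
  Rcpp::NumericMatrix out(p.n_rows, p.n_cols);
  for (uword i = 0; i < p.n_elem; ++i) out[i] = p(i);
  return out;
}

// One minibatch of training: forward, summed BCE, backward, Adam update.
// y must be (B*Ht) x K with row b*Ht + t.
// [[Rcpp::export(name = ".cnn_train_batch")]]
double cnn_train_batch(SEXP ptr, Rcpp::NumericVector x, Rcpp::NumericMatrix y,
                       int B, double lr) {
  Rcpp::XPtr<Net> net(ptr);
  const float flr = (float)lr;
  fmat x0 = to_internal(x, B, net->H, net->W);
  fmat p = forward_train(net, std::move(x0), B);
  if ((uword)y.nrow() != p.n_rows || (uword)y.ncol() != p.n_cols)
    Rcpp::stop("target matrix has wrong shape");
  fmat Y(p.n_rows, p.n_cols);
  for (uword i = 0; i < Y.n_elem; ++i) Y(i) = (float)y[i];

  double loss = 0;
  for (uword i = 0; i < p.n_elem; ++i) {
    float pi = std::min(std::max(p(i), 1e-7f), 1.0f - 1e-7f);
    loss -= Y(i) * std::log(pi) + (1.0f - Y(i)) * std::log(1.0f - pi);
  }
  if (!std::isfinite(loss)) Rcpp::stop("training loss is not finite");

  net->t_adam += 1;
  const long t = net->t_adam;
  fmat g = p - Y;  // d(sum BCE)/d(logit)

  // head backward (dense layers 12..10); layer j's post-ReLU output is the
  // cached input of BN j+1
  for (int j = 12; j >= 10; --j) {
    LinLayer& L = net->lin[j];
    if (j < 12) relu_mask_(g, net->bn[j + 1].xc);
    fmat in = bn_recompute(net->bn[j]);
    fmat dW = in.t() * g;
    frowvec db = sum(g, 0);
    fmat gprev = g * L.W.t();
    adam_mat(L.W, dW, L.mW, L.vW, flr, t);
    adam_row(L.b, db, L.mb, L.vb, flr, t);
    g = bn_bwd(net->bn[j], gprev, flr, t);
  }
  int C = (int)net->filters(4);
  g = head_unshape(g, B, net->Ht, net->Wt, C);

  int H = net->H / 32, W = net->W / 32;
  for (int i = 4; i >= 0; --i) {
    int f = (int)net->filters(i);
    int cin = (i == 0) ? 1 : (int)net->filters(i - 1);
    H *= 2; W *= 2;  // pre-pool resolution of block i
    fmat dpre;
    pool_bwd(g, net->amax[i], (uword)B * H * W, dpre);
    {   // conv_b
      LinLayer& L = net->lin[2 * i + 1];
      relu_mask_(dpre, L.out);
      L.out.reset();
      fmat dW = L.M.t() * dpre;
      frowvec db = sum(dpre, 0);
      fmat gM = dpre * L.W.t();
      L.M.reset();
      col2im(gM, B, H, W, f, g);
      adam_mat(L.W, dW, L.mW, L.vW, flr, t);
      adam_row(L.b, db, L.mb, L.vb, flr, t);
      g = bn_bwd(net->bn[2 * i + 1], g, flr, t);
    }
    {   // conv_a; its post-ReLU output is BN(2i+1)'s cached input
      LinLayer& L = net->lin[2 * i];
      relu_mask_(g, net->bn[2 * i + 1].xc);
      net->bn[2 * i + 1].xc.reset();
      fmat dW = L.M.t() * g;
      frowvec db = sum(g, 0);
      fmat gM = g * L.W.t();
      L.M.reset();
      fmat dx;
      col2im(gM, B, H, W, cin, dx);
      adam_mat(L.W, dW, L.mW, L.vW, flr, t);
      adam_row(L.b, db, L.mb, L.vb, flr, t);
      g = bn_bwd(net->bn[2 * i], dx, flr, t);
    }
  }
  return loss;
}
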