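// Self-contained 1-D residual CNN + bidirectional GRU regression network.
//
// Feature maps are single-precision matrices with rows = channels and
// columns = sample-major time (column index n*L + t for sample n, step t).
// Convolutions are im2col + sgemm; backward recomputes im2col from the
// cached layer input rather than storing the unrolled matrix.
//
// All randomness (weight init, dropout masks, epoch shuffling) flows from
// one std::mt19937 seeded at construction, so training is bit-reproducible
// on a fixed BLAS.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>

// HEMONET_DOUBLE switches the element type to double; used only by the
// gradient-verification harness, where float32 finite differences are too
// noisy to be conclusive.
#ifdef HEMONET_DOUBLE
typedef arma::mat fmat;
typedef arma::vec fvec;
#else
using arma::fmat;
using arma::fvec;
#endif
typedef fmat::elem_type elem_t;
using arma::uword;

struct Param {
  std::string name;
  fmat value, grad, m, v;
  Param() {}
  Param(const std::string& nm, uword r, uword c)
    : name(nm), value(r, c), grad(r, c, arma::fill::zeros),
      m(r, c, arma::fill::zeros), v(r, c, arma::fill::zeros) {}
};

static inline fmat sigmoidf(const fmat& x) { return 1.0f / (1.0f + arma::exp(-x)); }

// ---------------------------------------------------------------- Conv1d
// 'same' padding: L_out = ceil(L_in / stride); pad_left = floor(pad_total/2).
struct Conv1d {
  int Cin, Cout, K, stride;
  Param W; // Cout x (K*Cin), column block k*Cin..k*Cin+Cin-1 holds tap k
  Param b; // Cout x 1
  // caches
  fmat Xin;
  int N = 0, Lin = 0, Lout = 0, pad_left = 0;

  void init(const std::string& nm, int cin, int cout, int k, int s, std::mt19937& rng) {
    Cin = cin; Cout = cout; K = k; stride = s;
    W = Param(nm + ".W", cout, (uword)(k * cin));
    b = Param(nm + ".b", cout, 1);
    float sd = std::sqrt(2.0f / (float)(k * cin));
    std::normal_distribution<float> nd(0.0f, sd);
    for (uword i = 0; i < W.value.n_elem; ++i) W.value[i] = nd(rng);
    b.value.zeros();
  }

  void geometry(int lin) {
    Lin = lin;
    Lout = (lin + stride - 1) / stride;
    int pad_total = (Lout - 1) * stride + K - lin;
    if (pad_total < 0) pad_total = 0;
    pad_left = pad_total / 2;
  }

  void im2col(const fmat& X, fmat& Xcol) const {
    Xcol.set_size((uword)(K * Cin), (uword)(Lout * N));
    for (int n = 0; n < N; ++n) {
      const uword in0 = (uword)n * Lin, out0 = (uword)n * Lout;
      for (int t = 0; t < Lout; ++t) {
        const int t_base = t * stride - pad_left;
        elem_t* dst = Xcol.colptr(out0 + t);
        const bool interior = (t_base >= 0) && (t_base + K <= Lin);
        if (!interior) std::memset(dst, 0, sizeof(elem_t) * K * Cin);
        for (int k = 0; k < K; ++k) {
          const int ti = t_base + k;
          if (interior || (ti >= 0 && ti < Lin))
            std::memcpy(dst + (size_t)k * Cin, X.colptr(in0 + ti), sizeof(elem_t) * Cin);
        }
      }
    }
  }

  fmat forward(const fmat& X, int n_samples, int lin) {
    N = n_samples; geometry(lin);
    Xin = X;
    fmat Xcol; im2col(X, Xcol);
    fmat Y = W.value * Xcol;
    Y.each_col() += b.value.col(0);
    return Y;
  }

  fmat backward(const fmat& dY, bool need_dx = true) {
    fmat Xcol; im2col(Xin, Xcol);
    W.grad += dY * Xcol.t();
    b.grad += arma::sum(dY, 1);
    if (!need_dx) return fmat();
    fmat dXcol = W.value.t() * dY; // (K*Cin) x (Lout*N)
    fmat dX(Cin, (uword)(Lin * N), arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      const uword in0 = (uword)n * Lin, out0 = (uword)n * Lout;
      for (int t = 0; t < Lout; ++t) {
        const int t_base = t * stride - pad_left;
        const elem_t* src = dXcol.colptr(out0 + t);
        for (int k = 0; k < K; ++k) {
          const int ti = t_base + k;
          if (ti >= 0 && ti < Lin) {
            elem_t* dst = dX.colptr(in0 + ti);
            const elem_t* s = src + (size_t)k * Cin;
            for (int c = 0; c < Cin; ++c) dst[c] += s[c];
          }
        }
      }
    }
    return dX;
  }
};

// ------------------------------------------------------------- BatchNorm
struct BatchNorm {
  int C;
  Param gamma, beta;
  fvec running_mean, running_var;
  float eps = 1e-5f, momentum = 0.1f;
  // caches
  fmat xhat;
  fvec inv_std;

  void init(const std::string& nm, int c) {
    C = c;
    gamma = Param(nm + ".gamma", c, 1); gamma.value.ones();
    beta  = Param(nm + ".beta",  c, 1); beta.value.zeros();
    running_mean.zeros(c); running_var.ones(c);
  }

  fmat forward(const fmat& X, bool training, bool update_stats) {
    const uword M = X.n_cols, Cr = X.n_rows;
    fvec mu(Cr), istd(Cr);
    if (training) {
      fvec var(Cr, arma::fill::zeros);
      mu.zeros();
      const elem_t* x = X.memptr();
      for (uword j = 0; j < M; ++j) {
        const elem_t* col = x + j * Cr;
        for (uword c = 0; c < Cr; ++c) mu[c] += col[c];
      }
      mu /= (elem_t)M;
      for (uword j = 0; j < M; ++j) {
        const elem_t* col = x + j * Cr;
        for (uword c = 0; c < Cr; ++c) {
          const elem_t d = col[c] - mu[c];
          var[c] += d * d;
        }
      }
      var /= (elem_t)M;
      istd = 1.0f / arma::sqrt(var + eps);
      if (update_stats) {
        running_mean = (1.0f - momentum) * running_mean + momentum * mu;
        // unbiased running variance, as is conventional
        elem_t corr = M > 1 ? (elem_t)M / (elem_t)(M - 1) : (elem_t)1;
        running_var = (1.0f - momentum) * running_var + momentum * (var * corr);
      }
    } else {
      mu = running_mean;
      istd = 1.0f / arma::sqrt(running_var + eps);
    }
    inv_std = istd;
    // one fused pass: xhat and the affine output
    xhat.set_size(Cr, M);
    fmat Y(Cr, M);
    const elem_t* x = X.memptr();
    elem_t* xh = xhat.memptr();
    elem_t* y = Y.memptr();
    const elem_t* g = gamma.value.memptr();
    const elem_t* bt = beta.value.memptr();
    for (uword j = 0; j < M; ++j) {
      const uword off = j * Cr;
      for (uword c = 0; c < Cr; ++c) {
        const elem_t v = (x[off + c] - mu[c]) * istd[c];
        xh[off + c] = v;
        y[off + c] = g[c] * v + bt[c];
      }
    }
    return Y;
  }

  // training-mode backward (batch statistics)
  fmat backward(const fmat& dY) {
    const uword M = dY.n_cols, Cr = dY.n_rows;
    fvec sum_dy(Cr, arma::fill::zeros), sum_dy_xhat(Cr, arma::fill::zeros);
    const elem_t* dy = dY.memptr();
    const elem_t* xh = xhat.memptr();
    for (uword j = 0; j < M; ++j) {
      const uword off = j * Cr;
      for (uword c = 0; c < Cr; ++c) {
        sum_dy[c] += dy[off + c];
        sum_dy_xhat[c] += dy[off + c] * xh[off + c];
      }
    }
    gamma.grad += sum_dy_xhat;
    beta.grad  += sum_dy;
    fvec scale = (gamma.value.col(0) % inv_std) / (elem_t)M;
    fmat dX(Cr, M);
    elem_t* dx = dX.memptr();
    for (uword j = 0; j < M; ++j) {
      const uword off = j * Cr;
      for (uword c = 0; c < Cr; ++c)
        dx[off + c] = scale[c] * ((elem_t)M * dy[off + c] - sum_dy[c]
                                  - xh[off + c] * sum_dy_xhat[c]);
    }
    return dX;
  }
};

// ------------------------------------------------------ small activations
struct ReLU {
  fmat mask; // 1 where input > 0
  fmat forward(const fmat& X) {
    mask.set_size(X.n_rows, X.n_cols);
    fmat Y(X.n_rows, X.n_cols);
    const elem_t* x = X.memptr();
    elem_t* m = mask.memptr();
    elem_t* y = Y.memptr();
    const uword ne = X.n_elem;
    for (uword i = 0; i < ne; ++i) {
      const elem_t v = x[i];
      if (v > 0) { y[i] = v; m[i] = 1; } else { y[i] = 0; m[i] = 0; }
    }
    return Y;
  }
  fmat backward(const fmat& dY) const { return dY % mask; }
};

struct LeakyReLU {
  float slope = 0.01f;
  fmat Xc;
  fmat forward(const fmat& X) { Xc = X; return arma::max(X, slope * X); }
  fmat backward(const fmat& dY) const {
    fmat g = dY;
    for (uword i = 0; i < g.n_elem; ++i) if (Xc[i] <= 0.0f) g[i] *= slope;
    return g;
  }
};

struct Dropout {
  float p = 0.0f;
  fmat mask;
  fmat forward(const fmat& X, bool training, std::mt19937& rng) {
    if (!training || p <= 0.0f) { mask.reset(); return X; }
    std::uniform_real_distribution<float> ud(0.0f, 1.0f);
    mask.set_size(X.n_rows, X.n_cols);
    const float scale = 1.0f / (1.0f - p);
    for (uword i = 0; i < mask.n_elem; ++i) mask[i] = ud(rng) < p ? 0.0f : scale;
    return X % mask;
  }
  fmat backward(const fmat& dY) const { return mask.is_empty() ? dY : dY % mask; }
};

// ------------------------------------------------------------- MaxPool1d
// pool size == stride (1 or 2); 'same' semantics: L_out = ceil(L_in/size).
struct MaxPool {
  int size;
  int N = 0, Lin = 0, Lout = 0, C = 0;
  arma::uvec argmax; // flat col index into input, one per (channel, out col)? store per out col x channel

  fmat forward(const fmat& X, int n_samples, int lin) {
    N = n_samples; Lin = lin; C = X.n_rows;
    if (size == 1) { Lout = lin; return X; }
    Lout = (lin + size - 1) / size;
    fmat Y(C, (uword)(Lout * N));
    argmax.set_size((uword)C * Lout * N);
    for (int n = 0; n < N; ++n) {
      for (int t = 0; t < Lout; ++t) {
        const uword oc = (uword)n * Lout + t;
        const int i0 = t * size;
        for (int c = 0; c < C; ++c) {
          elem_t best = -std::numeric_limits<elem_t>::infinity();
          uword bidx = 0;
          for (int j = i0; j < std::min(i0 + size, Lin); ++j) {
            const uword ic = (uword)n * Lin + j;
            const elem_t v = X(c, ic);
            if (v > best) { best = v; bidx = ic; }
          }
          Y(c, oc) = best;
          argmax[oc * C + c] = bidx;
        }
      }
    }
    return Y;
  }

  fmat backward(const fmat& dY) const {
    if (size == 1) return dY;
    fmat dX(C, (uword)(Lin * N), arma::fill::zeros);
    for (uword oc = 0; oc < (uword)Lout * N; ++oc)
      for (int c = 0; c < C; ++c)
        dX(c, argmax[oc * C + c]) += dY(c, oc);
    return dX;
  }
};

// --------------------------------------------------------- residual block
struct ResBlock {
  bool first_block = false, project = false;
  int Cin, Cout, stride;
  BatchNorm bn_pre, bn_mid;
  ReLU relu_pre, relu_mid;
  Dropout drop;
  Conv1d conv1, conv2, proj; // proj is 1x1 on pooled shortcut
  MaxPool pool;
  int Lin = 0, Lout = 0;

  void init(int idx, int cin, int cout, int k, int s, float dropout_p, std::mt19937& rng) {
    first_block = (idx == 0);
    Cin = cin; Cout = cout; stride = s;
    project = (cin != cout);
    std::string nm = "block" + std::to_string(idx + 1);
    if (!first_block) bn_pre.init(nm + ".bn_pre", cin);
    conv1.init(nm + ".conv1", cin, cout, k, 1, rng);
    bn_mid.init(nm + ".bn_mid", cout);
    drop.p = dropout_p;
    conv2.init(nm + ".conv2", cout, cout, k, s, rng);
    pool.size = s;
    if (project) proj.init(nm + ".proj", cin, cout, 1, 1, rng);
  }

  fmat forward(const fmat& X, int N, int lin, bool training, bool update_stats,
               std::mt19937& rng) {
    Lin = lin;
    fmat A = first_block ? X : relu_pre.forward(bn_pre.forward(X, training, update_stats));
    fmat C1 = conv1.forward(A, N, lin);
    fmat D1 = drop.forward(relu_mid.forward(bn_mid.forward(C1, training, update_stats)),
                           training, rng);
    fmat C2 = conv2.forward(D1, N, lin);
    Lout = conv2.Lout;
    fmat S = pool.forward(X, N, lin);
    if (project) S = proj.forward(S, N, pool.Lout);
    return C2 + S;
  }

  fmat backward(const fmat& dY, bool need_dx = true) {
    fmat dD1 = conv2.backward(dY);
    fmat dC1 = bn_mid.backward(relu_mid.backward(drop.backward(dD1)));
    fmat dA = conv1.backward(dC1, need_dx);
    fmat dS;
    if (project) dS = proj.backward(dY, need_dx); // proj params need grads either way
    if (!need_dx) return fmat();
    fmat dX_short = pool.backward(project ? dS : dY);
    fmat dX_main = first_block ? dA : bn_pre.backward(relu_pre.backward(dA));
    return dX_main + dX_short;
  }

  void collect(std::vector<Param*>& ps) {
    if (!first_block) { ps.push_back(&bn_pre.gamma); ps.push_back(&bn_pre.beta); }
    ps.push_back(&conv1.W); ps.push_back(&conv1.b);
    ps.push_back(&bn_mid.gamma); ps.push_back(&bn_mid.beta);
    ps.push_back(&conv2.W); ps.push_back(&conv2.b);
    if (project) { ps.push_back(&proj.W); ps.push_back(&proj.b); }
  }
};

// ------------------------------------------------------------------- GRU
// One direction. Gate order in the stacked weight matrices: r, z, n.
//   r = sig(Wx_r x + bx_r + Wh_r h + bh_r)
//   z = sig(Wx_z x + bx_z + Wh_z h + bh_z)
//   n = tanh(Wx_n x + bx_n + r .* (Wh_n h + bh_n))
//   h' = (1 - z) .* n + z .* h
// Only the final hidden state is consumed downstream.
struct GRU {
  int H, Cin, T = 0, N = 0;
  bool reverse = false;
  Param Wx, Wh, bx, bh; // (3H x Cin), (3H x H), (3H x 1), (3H x 1)
  std::vector<fmat> rs, zs, ns, ghn, hprev;
  fmat Fin, GxAll;

  void init(const std::string& nm, int cin, int h, bool rev, std::mt19937& rng) {
    H = h; Cin = cin; reverse = rev;
    Wx = Param(nm + ".Wx", 3 * h, cin);
    Wh = Param(nm + ".Wh", 3 * h, h);
    bx = Param(nm + ".bx", 3 * h, 1);
    bh = Param(nm + ".bh", 3 * h, 1);
    float lim = 1.0f / std::sqrt((float)h);
    std::uniform_real_distribution<float> ud(-lim, lim);
    for (uword i = 0; i < Wx.value.n_elem; ++i) Wx.value[i] = ud(rng);
    for (uword i = 0; i < Wh.value.n_elem; ++i) Wh.value[i] = ud(rng);
    bx.value.zeros(); bh.value.zeros();
  }

  // F: Cin x (N*T), sample-major; returns final hidden H x N.
  // The input projection Wx*F for all timesteps is one gemm; only the
  // recurrent Wh*h products run step by step.
  fmat forward(const fmat& F, int n_samples, int t_steps) {
    N = n_samples; T = t_steps;
    Fin = F;
    GxAll = Wx.value * F;
    GxAll.each_col() += bx.value.col(0);
    rs.assign(T, fmat()); zs.assign(T, fmat());
    ns.assign(T, fmat()); ghn.assign(T, fmat()); hprev.assign(T, fmat());
    fmat h(H, N, arma::fill::zeros);
    fmat gx(3 * H, N);
    for (int step = 0; step < T; ++step) {
      const int t = reverse ? (T - 1 - step) : step;
      for (int n = 0; n < N; ++n) gx.col(n) = GxAll.col((uword)n * T + t);
      fmat gh = Wh.value * h; gh.each_col() += bh.value.col(0);
      fmat r = sigmoidf(gx.rows(0, H - 1) + gh.rows(0, H - 1));
      fmat z = sigmoidf(gx.rows(H, 2 * H - 1) + gh.rows(H, 2 * H - 1));
      fmat gn = gh.rows(2 * H, 3 * H - 1);
      fmat nn = arma::tanh(gx.rows(2 * H, 3 * H - 1) + r % gn);
      rs[step] = r; zs[step] = z; ns[step] = nn;
      ghn[step] = std::move(gn); hprev[step] = h;
      h = (1.0f - z) % nn + z % h;
    }
    return h;
  }

  // dh_final: H x N; returns gradient w.r.t. the input sequence (Cin x N*T)
  fmat backward(const fmat& dh_final) {
    fmat GxGrad(3 * H, (uword)N * T);
    fmat dh = dh_final;
    for (int step = T - 1; step >= 0; --step) {
      const int t = reverse ? (T - 1 - step) : step;
      const fmat& r = rs[step]; const fmat& z = zs[step];
      const fmat& nn = ns[step]; const fmat& gn = ghn[step];
      const fmat& hp = hprev[step];
      fmat dn = dh % (1.0f - z);
      fmat dz = dh % (hp - nn);
      fmat dhp = dh % z;
      fmat dn_pre = dn % (1.0f - nn % nn);
      fmat dr = dn_pre % gn;
      fmat dghn = dn_pre % r;
      fmat dz_pre = dz % z % (1.0f - z);
      fmat dr_pre = dr % r % (1.0f - r);
      fmat Gh(3 * H, N);
      Gh.rows(0, H - 1) = dr_pre; Gh.rows(H, 2 * H - 1) = dz_pre;
      Gh.rows(2 * H, 3 * H - 1) = dghn;
      for (int n = 0; n < N; ++n) {
        elem_t* dst = GxGrad.colptr((uword)n * T + t);
        for (int c = 0; c < H; ++c) {
          dst[c] = dr_pre(c, n);
          dst[H + c] = dz_pre(c, n);
          dst[2 * H + c] = dn_pre(c, n);
        }
      }
      Wh.grad += Gh * hp.t();
      bh.grad += arma::sum(Gh, 1);
      dh = dhp + Wh.value.t() * Gh;
    }
    Wx.grad += GxGrad * Fin.t();
    bx.grad += arma::sum(GxGrad, 1);
    return Wx.value.t() * GxGrad;
  }

  void collect(std::vector<Param*>& ps) {
    ps.push_back(&Wx); ps.push_back(&Wh); ps.push_back(&bx); ps.push_back(&bh);
  }
};

// -------------------------------------------------------------------- Net
struct Net {
  // config
  int input_len, in_ch, n_out, gru_units, kernel;
  std::vector<int> channels, strides;
  float dropout_p, leaky_slope;
  std::mt19937 rng;

  std::vector<ResBlock> blocks;
  GRU gru_f, gru_b;
  BatchNorm bn_head;
  LeakyReLU lrelu_head;
  Param Wd, bd;

  std::vector<Param*> params;
  // Adam state
  float beta1 = 0.9f, beta2 = 0.999f, adam_eps = 1e-8f;
  long adam_t = 0;

  // snapshots for best-epoch checkpointing
  std::vector<fmat> best_values;
  std::vector<fvec> best_rstats;
  bool has_best = false;

  // probe info from the last forward pass
  int last_res_len = 0, last_head_dim = 0, last_out_dim = 0;

  Net(int in_len, int in_c, const std::vector<int>& ch, const std::vector<int>& st,
      int k, int gru_h, int nout, float dp, float slope, unsigned int seed)
    : input_len(in_len), in_ch(in_c), n_out(nout), gru_units(gru_h), kernel(k),
      channels(ch), strides(st), dropout_p(dp), leaky_slope(slope), rng(seed) {
    const int nb = (int)ch.size();
    blocks.resize(nb);
    int cin = in_c;
    for (int i = 0; i < nb; ++i) {
      blocks[i].init(i, cin, ch[i], k, st[i], dp, rng);
      cin = ch[i];
    }
    gru_f.init("gru_fwd", cin, gru_h, false, rng);
    gru_b.init("gru_bwd", cin, gru_h, true, rng);
    bn_head.init("head.bn", 2 * gru_h);
    lrelu_head.slope = slope;
    Wd = Param("head.dense.W", nout, 2 * gru_h);
    bd = Param("head.dense.b", nout, 1);
    float lim = std::sqrt(6.0f / (float)(2 * gru_h + nout));
    std::uniform_real_distribution<float> ud(-lim, lim);
    for (uword i = 0; i < Wd.value.n_elem; ++i) Wd.value[i] = ud(rng);
    bd.value.zeros();
    for (auto& b : blocks) b.collect(params);
    gru_f.collect(params); gru_b.collect(params);
    params.push_back(&bn_head.gamma); params.push_back(&bn_head.beta);
    params.push_back(&Wd); params.push_back(&bd);
  }

  // X: in_ch x (N*input_len) -> n_out x N
  fmat forward(const fmat& X, int N, bool training, bool update_stats) {
    fmat A = X;
    int L = input_len;
    for (auto& b : blocks) {
      A = b.forward(A, N, L, training, update_stats, rng);
      L = b.Lout;
    }
    last_res_len = L;
    fmat hf = gru_f.forward(A, N, L);
    fmat hb = gru_b.forward(A, N, L);
    fmat feat = arma::join_cols(hf, hb); // 2H x N
    last_head_dim = (int)feat.n_rows;
    fmat z = lrelu_head.forward(bn_head.forward(feat, training, update_stats));
    fmat Y = Wd.value * z; Y.each_col() += bd.value.col(0);
    last_out_dim = (int)Y.n_rows;
    return Y;
  }

  void zero_grad() { for (auto* p : params) p->grad.zeros(); }

  // dY: n_out x N (training-mode caches must be populated)
  void backward(const fmat& dY) {
    // dense head; the LeakyReLU output is recomputed from its cached input
    fmat zpost = arma::max(lrelu_head.Xc, lrelu_head.slope * lrelu_head.Xc);
    Wd.grad += dY * zpost.t();
    bd.grad += arma::sum(dY, 1);
    fmat dz = Wd.value.t() * dY;
    fmat dfeat = bn_head.backward(lrelu_head.backward(dz));
    const int H = gru_units;
    fmat dhf = dfeat.rows(0, H - 1);
    fmat dhb = dfeat.rows(H, 2 * H - 1);
    fmat dA = gru_f.backward(dhf) + gru_b.backward(dhb);
    for (int i = (int)blocks.size() - 1; i >= 0; --i)
      dA = blocks[i].backward(dA, need_input_grad || i > 0);
    last_dX = dA;
  }
  bool need_input_grad = false;
  fmat last_dX;

  void adam_step(float lr) {
    ++adam_t;
    const float bc1 = 1.0f - std::pow(beta1, (float)adam_t);
    const float bc2 = 1.0f - std::pow(beta2, (float)adam_t);
    for (auto* p : params) {
      p->m = beta1 * p->m + (1.0f - beta1) * p->grad;
      p->v = beta2 * p->v + (1.0f - beta2) * (p->grad % p->grad);
      p->value -= lr * (p->m / bc1) / (arma::sqrt(p->v / bc2) + adam_eps);
    }
  }

  void sgd_step(float lr) { for (auto* p : params) p->value -= lr * p->grad; }

  std::vector<BatchNorm*> bns() {
    std::vector<BatchNorm*> out;
    for (auto& b : blocks) {
      if (!b.first_block) out.push_back(&b.bn_pre);
      out.push_back(&b.bn_mid);
    }
    out.push_back(&bn_head);
    return out;
  }

  void snapshot_best() {
    best_values.clear(); best_rstats.clear();
    for (auto* p : params) best_values.push_back(p->value);
    for (auto* bn : bns()) { best_rstats.push_back(bn->running_mean); best_rstats.push_back(bn->running_var); }
    has_best = true;
  }
  void restore_best() {
    if (!has_best) return;
    for (size_t i = 0; i < params.size(); ++i) params[i]->value = best_values[i];
    auto v = bns();
    for (size_t i = 0; i < v.size(); ++i) { v[i]->running_mean = best_rstats[2 * i]; v[i]->running_var = best_rstats[2 * i + 1]; }
  }
};

// ------------------------------------------------------------ R interface

static fmat array_to_fmat(const Rcpp::NumericVector& arr) {
  // arr has dim (L, C, N); output C x (N*L), sample-major columns
  Rcpp::IntegerVector d = arr.attr("dim");
  const int L = d[0], C = d[1], N = d.size() >= 3 ? d[2] : 1;
  fmat X((uword)C, (uword)N * L);
  const double* p = arr.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = p + (size_t)L * (c + (size_t)C * n);
      for (int t = 0; t < L; ++t) X(c, (uword)n * L + t) = (elem_t)src[t];
    }
  return X;
}

static fmat ymat_to_fmat(const Rcpp::NumericMatrix& Y) {
  // Y: N x n_out -> n_out x N
  fmat out(Y.ncol(), Y.nrow());
  for (int i = 0; i < Y.nrow(); ++i)
    for (int j = 0; j < Y.ncol(); ++j) out(j, i) = (elem_t)Y(i, j);
  return out;
}

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(Rcpp::List cfg) {
  std::vector<int> ch = Rcpp::as<std::vector<int>>(cfg["channels"]);
  std::vector<int> st = Rcpp::as<std::vector<int>>(cfg["strides"]);
  Rcpp::XPtr<Net> ptr(new Net(
    Rcpp::as<int>(cfg["input_length"]), Rcpp::as<int>(cfg["input_channels"]),
    ch, st,
    Rcpp::as<int>(cfg["kernel_length"]), Rcpp::as<int>(cfg["gru_units"]),
    Rcpp::as<int>(cfg["dense_cells"]), (float)Rcpp::as<double>(cfg["dropout_rate"]),
    (float)Rcpp::as<double>(cfg["leaky_slope"]), (unsigned int)Rcpp::as<int>(cfg["seed"])),
    true);
  return ptr;
}

// [[Rcpp::export(name = ".net_predict")]]
Rcpp::NumericMatrix net_predict(SEXP net_ptr, Rcpp::NumericVector X, int chunk = 256) {
  Rcpp::XPtr<Net> net(net_ptr);
  Rcpp::IntegerVector d = X.attr("dim");
  const int L = d[0], C = d[1], N = d.size() >= 3 ? d[2] : 1;
  fmat Xall = array_to_fmat(X);
  Rcpp::NumericMatrix out(N, net->n_out);
  for (int start = 0; start < N; start += chunk) {
    const int nb = std::min(chunk, N - start);
    fmat Xb(C, (uword)nb * L);
    Xb = Xall.cols((uword)start * L, (uword)(start + nb) * L - 1);
    fmat Yb = net->forward(Xb, nb, false, false);
    for (int i = 0; i < nb; ++i)
      for (int j = 0; j < net->n_out; ++j) out(start + i, j) = (double)Yb(j, i);
  }
  return out;
}

// [[Rcpp::export(name = ".net_probe_shapes")]]
Rcpp::List net_probe_shapes(SEXP net_ptr, Rcpp::NumericVector X) {
  Rcpp::XPtr<Net> net(net_ptr);
  Rcpp::IntegerVector d = X.attr("dim");
  const int N = d.size() >= 3 ? d[2] : 1;
  fmat Xm = array_to_fmat(X);
  fmat Y = net->forward(Xm, N, false, false);
  return Rcpp::List::create(
    Rcpp::Named("res_seq_len") = net->last_res_len,
    Rcpp::Named("gru_feature_dim") = net->last_head_dim,
    Rcpp::Named("output_dim") = net->last_out_dim,
    Rcpp::Named("n") = (int)Y.n_cols);
}

static double mse_loss(const fmat& Yhat, const fmat& Y) {
  fmat diff = Yhat - Y;
  return (double)arma::accu(diff % diff) / (double)diff.n_elem;
}

// [[Rcpp::export(name = ".net_loss")]]
double net_loss(SEXP net_ptr, Rcpp::NumericVector X, Rcpp::NumericMatrix Y,
                bool training = false) {
  Rcpp::XPtr<Net> net(net_ptr);
  Rcpp::IntegerVector d = X.attr("dim");
  const int N = d.size() >= 3 ? d[2] : 1;
  fmat Xm = array_to_fmat(X), Ym = ymat_to_fmat(Y);
  fmat Yhat = net->forward(Xm, N, training, false);
  return mse_loss(Yhat, Ym);
}

// [[Rcpp::export(name = ".net_gradients")]]
Rcpp::List net_gradients(SEXP net_ptr, Rcpp::NumericVector X, Rcpp::NumericMatrix Y) {
  Rcpp::XPtr<Net> net(net_ptr);
  Rcpp::IntegerVector d = X.attr("dim");
  const int N = d.size() >= 3 ? d[2] : 1;
  fmat Xm = array_to_fmat(X), Ym = ymat_to_fmat(Y);
  net->zero_grad();
  fmat Yhat = net->forward(Xm, N, true, false);
  fmat dY = 2.0f * (Yhat - Ym) / (float)Yhat.n_elem;
  net->backward(dY);
  Rcpp::List out(net->params.size());
  Rcpp::CharacterVector nms(net->params.size());
  for (size_t i = 0; i < net->params.size(); ++i) {
    const fmat& g = net->params[i]->grad;
    Rcpp::NumericMatrix m(g.n_rows, g.n_cols);
    for (uword r = 0; r < g.n_rows; ++r)
      for (uword c = 0; c < g.n_cols; ++c) m(r, c) = (double)g(r, c);
    out[i] = m;
    nms[i] = net->params[i]->name;
  }
  out.attr("names") = nms;
  return out;
}

// Gradient of the loss w.r.t. the input window; used by the gradient tests.
// [[Rcpp::export(name = ".net_input_gradient")]]
Rcpp::NumericVector net_input_gradient(SEXP net_ptr, Rcpp::NumericVector X,
                                       Rcpp::NumericMatrix Y) {
  Rcpp::XPtr<Net> net(net_ptr);
  Rcpp::IntegerVector d = X.attr("dim");
  const int L = d[0], C = d[1], N = d.size() >= 3 ? d[2] : 1;
  fmat Xm = array_to_fmat(X), Ym = ymat_to_fmat(Y);
  net->zero_grad();
  net->need_input_grad = true;
  fmat Yhat = net->forward(Xm, N, true, false);
  fmat dY = 2.0f * (Yhat - Ym) / (float)Yhat.n_elem;
  net->backward(dY);
  net->need_input_grad = false;
  Rcpp::NumericVector out(Rcpp::Dimension(L, C, N));
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < L; ++t)
        out[t + (size_t)L * (c + (size_t)C * n)] = (double)net->last_dX(c, (uword)n * L + t);
  return out;
}

// [[Rcpp::export(name = ".net_get_weights")]]
Rcpp::List net_get_weights(SEXP net_ptr) {
  Rcpp::XPtr<Net> net(net_ptr);
  const size_t np = net->params.size();
  auto bns = net->bns();
  Rcpp::List vals(np), stats(bns.size() * 2);
  Rcpp::CharacterVector vn(np), sn(bns.size() * 2);
  for (size_t i = 0; i < np; ++i) {
    const fmat& v = net->params[i]->value;
    Rcpp::NumericMatrix m(v.n_rows, v.n_cols);
    for (uword r = 0; r < v.n_rows; ++r)
      for (uword c = 0; c < v.n_cols; ++c) m(r, c) = (double)v(r, c);
    vals[i] = m; vn[i] = net->params[i]->name;
  }
  for (size_t i = 0; i < bns.size(); ++i) {
    Rcpp::NumericVector rm(bns[i]->running_mean.n_elem), rv(bns[i]->running_var.n_elem);
    for (uword j = 0; j < bns[i]->running_mean.n_elem; ++j) {
      rm[j] = bns[i]->running_mean[j]; rv[j] = bns[i]->running_var[j];
    }
    stats[2 * i] = rm; stats[2 * i + 1] = rv;
    sn[2 * i] = bns[i]->gamma.name + ".running_mean";
    sn[2 * i + 1] = bns[i]->gamma.name + ".running_var";
  }
  vals.attr("names") = vn; stats.attr("names") = sn;
  return Rcpp::List::create(Rcpp::Named("params") = vals, Rcpp::Named("bn_stats") = stats);
}

// [[Rcpp::export(name = ".net_set_weights")]]
void net_set_weights(SEXP net_ptr, Rcpp::List weights) {
  Rcpp::XPtr<Net> net(net_ptr);
  Rcpp::List vals = weights["params"], stats = weights["bn_stats"];
  if ((size_t)vals.size() != net->params.size())
    Rcpp::stop("weight list does not match network topology");
  for (size_t i = 0; i < net->params.size(); ++i) {
    Rcpp::NumericMatrix m = vals[i];
    fmat& v = net->params[i]->value;
    if ((uword)m.nrow() != v.n_rows || (uword)m.ncol() != v.n_cols)
      Rcpp::stop("weight dimensions mismatch at '%s'", net->params[i]->name.c_str());
    for (uword r = 0; r < v.n_rows; ++r)
      for (uword c = 0; c < v.n_cols; ++c) v(r, c) = (elem_t)m(r, c);
  }
  auto bns = net->bns();
  for (size_t i = 0; i < bns.size(); ++i) {
    Rcpp::NumericVector rm = stats[2 * i], rv = stats[2 * i + 1];
    for (uword j = 0; j < bns[i]->running_mean.n_elem; ++j) {
      bns[i]->running_mean[j] = (elem_t)rm[j]; bns[i]->running_var[j] = (elem_t)rv[j];
    }
  }
}

// Trains for `epochs` epochs; logs per-epoch mean training-batch loss and
// evaluation-mode validation loss; keeps an internal snapshot of the weights
// at the epoch with the smallest validation loss. `use_adam = false` selects
// plain SGD. Incomplete trailing batches are dropped (batch statistics).
// [[Rcpp::export(name = ".net_train")]]
Rcpp::List net_train(SEXP net_ptr, Rcpp::NumericVector Xtr, Rcpp::NumericMatrix Ytr,
                     Rcpp::NumericVector Xval, Rcpp::NumericMatrix Yval,
                     int epochs, int batch_size, double lr,
                     bool use_adam = true, bool restore_best = true) {
  Rcpp::XPtr<Net> net(net_ptr);
  Rcpp::IntegerVector dtr = Xtr.attr("dim");
  const int L = dtr[0], C = dtr[1], Ntr = dtr.size() >= 3 ? dtr[2] : 1;
  Rcpp::IntegerVector dv = Xval.attr("dim");
  const int Nval = dv.size() >= 3 ? dv[2] : 1;
  fmat Xt = array_to_fmat(Xtr), Yt = ymat_to_fmat(Ytr);
  fmat Xv = array_to_fmat(Xval), Yv = ymat_to_fmat(Yval);

  const int bs = std::min(batch_size, Ntr);
  std::vector<int> idx(Ntr);
  for (int i = 0; i < Ntr; ++i) idx[i] = i;

  Rcpp::NumericVector train_hist(epochs), val_hist(epochs);
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0;

  fmat Xb(C, (uword)bs * L), Yb(net->n_out, bs);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), net->rng);
    double tl = 0.0; int nb = 0;
    for (int start = 0; start + bs <= Ntr; start += bs) {
      for (int i = 0; i < bs; ++i) {
        const int s = idx[start + i];
        Xb.cols((uword)i * L, (uword)(i + 1) * L - 1) =
          Xt.cols((uword)s * L, (uword)(s + 1) * L - 1);
        Yb.col(i) = Yt.col(s);
      }
      net->zero_grad();
      fmat Yhat = net->forward(Xb, bs, true, true);
      fmat diff = Yhat - Yb;
      tl += (double)arma::accu(diff % diff) / (double)diff.n_elem;
      ++nb;
      fmat dY = 2.0f * diff / (float)diff.n_elem;
      net->backward(dY);
      if (use_adam) net->adam_step((float)lr); else net->sgd_step((float)lr);
      Rcpp::checkUserInterrupt();
    }
    train_hist[ep] = nb > 0 ? tl / nb : NA_REAL;
    // validation loss, evaluation mode, chunked
    double vl = 0.0; long nv = 0;
    const int chunk = 256;
    for (int start = 0; start < Nval; start += chunk) {
      const int nbv = std::min(chunk, Nval - start);
      fmat Xc = Xv.cols((uword)start * L, (uword)(start + nbv) * L - 1);
      fmat Yc = Yv.cols(start, start + nbv - 1);
      fmat Yhat = net->forward(Xc, nbv, false, false);
      fmat diff = Yhat - Yc;
      vl += (double)arma::accu(diff % diff);
      nv += (long)diff.n_elem;
    }
    vl /= (double)nv;
    val_hist[ep] = vl;
    if (vl < best_val) { best_val = vl; best_epoch = ep + 1; net->snapshot_best(); }
  }
  if (restore_best) net->restore_best();
  return Rcpp::List::create(
    Rcpp::Named("train_loss") = train_hist,
    Rcpp::Named("val_loss") = val_hist,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_loss") = best_val);
}
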