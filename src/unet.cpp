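// Compact encoder-decoder segmentation engine (U-net-like), single precision.
//
// Feature maps are stored as (H*W) x C matrices, pixels in R's column-major
// image order, so an R matrix maps onto one channel column without
// reshuffling. 3x3 convolutions run as im2col + sgemm; 2x2 stride-2
// transposed convolutions as gemm + scatter; 2x2 max-pooling stores argmax
// indices for the backward pass. All multi-task heads are 1x1 convolutions
// on the last decoder feature. Forward/backward buffers persist on the
// network object between calls: repeated allocation of multi-megabyte
// temporaries would otherwise dominate the runtime of desk-scale training.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

// Converged Dice training produces streams of subnormal single-precision
// gradients; x86 handles subnormals via microcode assists that slow the
// arithmetic by an order of magnitude. Flush them to zero inside the engine
// entry points (restoring the caller's FP environment on exit) — at 1e-38
// they are far below any quantity that matters here.
#if defined(__x86_64__) || defined(__SSE2__)
#include <xmmintrin.h>
struct FlushDenormals {
  unsigned int old_csr;
  FlushDenormals() : old_csr(_mm_getcsr()) {
    _mm_setcsr(old_csr | 0x8040);  // FTZ | DAZ
  }
  ~FlushDenormals() { _mm_setcsr(old_csr); }
};
#else
struct FlushDenormals {};
#endif

using arma::fmat;
using arma::fvec;
using arma::uvec;
using Rcpp::List;
using Rcpp::stop;

enum LayerKind { L_CONV3 = 0, L_POOL = 1, L_UP2 = 2, L_HEAD = 3 };
enum ActKind { A_NONE = 0, A_RELU = 1, A_SIGMOID = 2 };
enum LossKind { LO_NONE = -1, LO_DICE = 0, LO_SSE = 1 };

struct Layer {
  int kind;
  std::string name;
  int in_ch, out_ch;
  int act;
  int loss;        // heads only
  int level;       // resolution level: spatial size (H >> level, W >> level)
  int input_idx;   // producing layer index; -1 = network input
  int concat_src;  // encoder layer concatenated on the input side, or -1
  fmat W;          // conv3: (in*9) x out ; up2: in x (out*4) ; head: in x out
  fvec b;
  fmat gW, mW, vW;
  fvec gb, mb, vb;
};

struct UNet {
  int depth, base, in_ch;
  std::vector<Layer> layers;
  std::vector<int> head_idx;
  int final_feat_idx;
  long adam_t;
  // persistent per-sample workspace
  int wsH, wsW;
  std::vector<fmat> A;        // post-activation output per layer
  std::vector<fmat> cols;     // im2col buffer per conv3 layer
  std::vector<fmat> cat;      // concatenated input for decoder conv1 layers
  std::vector<uvec> poolix;   // argmax source index per pooled element
  std::vector<fmat> T;        // up2 pre-scatter buffer
  // backward scratch
  std::vector<fmat> dA;
  std::vector<char> dAset;
  std::vector<fmat> dZ, dCols, dXin, dT;
  UNet() : adam_t(0), wsH(-1), wsW(-1) {}
};

static void im2col3(const fmat& X, int H, int Wd, fmat& out) {
  const int C = X.n_cols;
  out.set_size((arma::uword)H * Wd, (arma::uword)C * 9);
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = c * 9 + (dj + 1) * 3 + (di + 1);
        float* dst = out.colptr(k);
        for (int j = 0; j < Wd; ++j) {
          float* dcol = dst + (size_t)j * H;
          const int js = j + dj;
          if (js < 0 || js >= Wd) {
            std::memset(dcol, 0, sizeof(float) * H);
            continue;
          }
          const float* scol = src + (size_t)js * H;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          if (i0 > 0) std::memset(dcol, 0, sizeof(float) * i0);
          std::memcpy(dcol + i0, scol + i0 + di, sizeof(float) * (i1 - i0));
          if (i1 < H) std::memset(dcol + i1, 0, sizeof(float) * (H - i1));
        }
      }
    }
  }
}

// scatter-add transpose of im2col3; dX must be pre-zeroed
static void col2im3(const fmat& cols, int H, int Wd, fmat& dX) {
  const int C = dX.n_cols;
  for (int c = 0; c < C; ++c) {
    float* dst = dX.colptr(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = c * 9 + (dj + 1) * 3 + (di + 1);
        const float* src = cols.colptr(k);
        for (int j = 0; j < Wd; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= Wd) continue;
          const float* scol = src + (size_t)j * H;
          float* dcol = dst + (size_t)js * H + di;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) dcol[i] += scol[i];
        }
      }
    }
  }
}

static inline void relu_inplace(fmat& M) {
  float* p = M.memptr();
  const size_t n = M.n_elem;
  for (size_t i = 0; i < n; ++i) p[i] = p[i] > 0.0f ? p[i] : 0.0f;
}

static inline void sigmoid_inplace(fmat& M) {
  float* p = M.memptr();
  const size_t n = M.n_elem;
  for (size_t i = 0; i < n; ++i) p[i] = 1.0f / (1.0f + std::exp(-p[i]));
}

static UNet* get_net(SEXP ptr) {
  Rcpp::XPtr<UNet> p(ptr);
  if (!p) stop("invalid network handle");
  return p.get();
}

// [[Rcpp::export(name = ".unet_create")]]
SEXP unet_create(int depth, int base_filters, int in_channels,
                 std::vector<std::string> head_names,
                 std::vector<int> head_act, std::vector<int> head_loss,
                 int seed) {
  if (depth < 2) stop("depth must be >= 2");
  if (base_filters < 1) stop("base_filters must be >= 1");
  if (head_names.empty()) stop("at least one head is required");
  UNet* net = new UNet();
  net->depth = depth;
  net->base = base_filters;
  net->in_ch = in_channels;

  std::mt19937 rng((unsigned)seed);
  auto he_uniform = [&](fmat& W, int fan_in) {
    const float lim = std::sqrt(6.0f / (float)fan_in);
    std::uniform_real_distribution<float> U(-lim, lim);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = U(rng);
  };
  auto add_conv3 = [&](const std::string& nm, int ic, int oc, int level,
                       int input_idx, int concat_src) {
    Layer L;
    L.kind = L_CONV3; L.name = nm; L.in_ch = ic; L.out_ch = oc;
    L.act = A_RELU; L.loss = LO_NONE; L.level = level;
    L.input_idx = input_idx; L.concat_src = concat_src;
    L.W.set_size((arma::uword)ic * 9, oc); he_uniform(L.W, ic * 9);
    L.b.zeros(oc);
    net->layers.push_back(L);
    return (int)net->layers.size() - 1;
  };

  std::vector<int> enc_out(depth - 1, -1);
  int prev = -1;
  int prev_ch = in_channels;
  for (int l = 0; l < depth - 1; ++l) {
    const int f = base_filters << l;
    prev = add_conv3("enc" + std::to_string(l + 1) + "_conv1", prev_ch, f, l,
                     prev, -1);
    prev = add_conv3("enc" + std::to_string(l + 1) + "_conv2", f, f, l,
                     prev, -1);
    enc_out[l] = prev;
    Layer P;
    P.kind = L_POOL; P.name = "pool" + std::to_string(l + 1);
    P.in_ch = f; P.out_ch = f; P.act = A_NONE; P.loss = LO_NONE;
    P.level = l + 1; P.input_idx = prev; P.concat_src = -1;
    net->layers.push_back(P);
    prev = (int)net->layers.size() - 1;
    prev_ch = f;
  }
  const int fb = base_filters << (depth - 1);
  prev = add_conv3("bottleneck_conv1", prev_ch, fb, depth - 1, prev, -1);
  prev = add_conv3("bottleneck_conv2", fb, fb, depth - 1, prev, -1);
  int cur_ch = fb;
  for (int l = depth - 2; l >= 0; --l) {
    const int f = base_filters << l;
    Layer U;
    U.kind = L_UP2; U.name = "dec" + std::to_string(l + 1) + "_up";
    U.in_ch = cur_ch; U.out_ch = f; U.act = A_NONE; U.loss = LO_NONE;
    U.level = l; U.input_idx = prev; U.concat_src = -1;
    U.W.set_size(cur_ch, (arma::uword)f * 4); he_uniform(U.W, cur_ch * 4);
    U.b.zeros(f);
    net->layers.push_back(U);
    prev = (int)net->layers.size() - 1;
    prev = add_conv3("dec" + std::to_string(l + 1) + "_conv1", 2 * f, f, l,
                     prev, enc_out[l]);
    prev = add_conv3("dec" + std::to_string(l + 1) + "_conv2", f, f, l,
                     prev, -1);
    cur_ch = f;
  }
  net->final_feat_idx = prev;
  for (size_t h = 0; h < head_names.size(); ++h) {
    Layer Hd;
    Hd.kind = L_HEAD; Hd.name = "head_" + head_names[h];
    Hd.in_ch = cur_ch; Hd.out_ch = 1;
    Hd.act = head_act[h]; Hd.loss = head_loss[h];
    Hd.level = 0; Hd.input_idx = prev; Hd.concat_src = -1;
    // prior-probability head initialisation: small weights and, for sigmoid
    // heads, a negative bias so the initial foreground probability is low
    // (~0.12). Organ foregrounds are a small fraction of the image; starting
    // the heads saturated at p ~ 0.5 destabilises joint Dice training of the
    // smallest organ.
    Hd.W.set_size(cur_ch, 1); he_uniform(Hd.W, cur_ch);
    Hd.W *= 0.1f;
    Hd.b.set_size(1);
    Hd.b(0) = (Hd.act == A_SIGMOID) ? -2.0f : 0.0f;
    net->layers.push_back(Hd);
    net->head_idx.push_back((int)net->layers.size() - 1);
  }
  const size_t n = net->layers.size();
  for (auto& L : net->layers) {
    L.gW.zeros(arma::size(L.W)); L.mW.zeros(arma::size(L.W));
    L.vW.zeros(arma::size(L.W));
    L.gb.zeros(L.b.n_elem); L.mb.zeros(L.b.n_elem); L.vb.zeros(L.b.n_elem);
  }
  net->A.resize(n); net->cols.resize(n); net->cat.resize(n);
  net->poolix.resize(n); net->T.resize(n);
  net->dA.resize(n); net->dAset.assign(n, 0);
  net->dZ.resize(n); net->dCols.resize(n); net->dXin.resize(n);
  net->dT.resize(n);
  Rcpp::XPtr<UNet> p(net, true);
  return p;
}

static void check_dims(const UNet* net, int H, int W) {
  const int div = 1 << (net->depth - 1);
  if (H % div != 0 || W % div != 0)
    stop("input size %dx%d not divisible by 2^(depth-1) = %d", H, W, div);
}

// forward one sample into the persistent workspace
static void forward_one(UNet* net, const fmat& X0, int H, int W) {
  const size_t n = net->layers.size();
  net->wsH = H; net->wsW = W;
  for (size_t i = 0; i < n; ++i) {
    Layer& L = net->layers[i];
    const fmat& Xin = (L.input_idx < 0) ? X0 : net->A[L.input_idx];
    const int h = H >> L.level, w = W >> L.level;
    if (L.kind == L_CONV3) {
      const fmat* src = &Xin;
      if (L.concat_src >= 0) {
        fmat& cc = net->cat[i];
        cc.set_size(Xin.n_rows, (arma::uword)L.in_ch);
        cc.cols(0, L.out_ch - 1) = Xin;
        cc.cols(L.out_ch, L.in_ch - 1) = net->A[L.concat_src];
        src = &cc;
      }
      im2col3(*src, h, w, net->cols[i]);
      fmat& out = net->A[i];
      out = net->cols[i] * L.W;
      out.each_row() += L.b.t();
      if (L.act == A_RELU) relu_inplace(out);
    } else if (L.kind == L_POOL) {
      const int hin = H >> (L.level - 1), win = W >> (L.level - 1);
      const int ho = hin / 2, wo = win / 2;
      fmat& out = net->A[i];
      out.set_size((arma::uword)ho * wo, L.out_ch);
      uvec& idx = net->poolix[i];
      idx.set_size((arma::uword)ho * wo * L.out_ch);
      for (int c = 0; c < L.out_ch; ++c) {
        const float* src = Xin.colptr(c);
        float* dst = out.colptr(c);
        arma::uword* ixp = idx.memptr() + (size_t)c * ho * wo;
        for (int j = 0; j < wo; ++j) {
          for (int i2 = 0; i2 < ho; ++i2) {
            const size_t p00 = (size_t)(2 * j) * hin + 2 * i2;
            const size_t cand[4] = {p00, p00 + 1, p00 + hin, p00 + hin + 1};
            float best = src[cand[0]];
            size_t bix = cand[0];
            for (int q = 1; q < 4; ++q)
              if (src[cand[q]] > best) { best = src[cand[q]]; bix = cand[q]; }
            dst[(size_t)j * ho + i2] = best;
            ixp[(size_t)j * ho + i2] = bix;
          }
        }
      }
    } else if (L.kind == L_UP2) {
      const int hin = h / 2, win = w / 2;
      fmat& T = net->T[i];
      T = Xin * L.W;  // (hin*win) x (out*4)
      fmat& out = net->A[i];
      out.set_size((arma::uword)h * w, L.out_ch);
      for (int f = 0; f < L.out_ch; ++f) {
        float* dst = out.colptr(f);
        const float bias = L.b(f);
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const float* src = T.colptr(f * 4 + dj * 2 + di);
            for (int j = 0; j < win; ++j) {
              const float* scol = src + (size_t)j * hin;
              float* dcol = dst + (size_t)(2 * j + dj) * h + di;
              for (int i2 = 0; i2 < hin; ++i2)
                dcol[2 * i2] = scol[i2] + bias;
            }
          }
        }
      }
    } else {  // head
      fmat& out = net->A[i];
      out = Xin * L.W;
      out.each_row() += L.b.t();
      if (L.act == A_SIGMOID) sigmoid_inplace(out);
    }
  }
}

static inline void add_or_set(UNet* net, int idx, const fmat& v) {
  if (!net->dAset[idx]) { net->dA[idx] = v; net->dAset[idx] = 1; }
  else net->dA[idx] += v;
}

// backward one sample given dL/d(head output p) per head (post-activation).
// guided: guided-backprop rectification at every ReLU.
// cam_layer_idx >= 0: record the gradient arriving at that layer's output.
// accumulate: add parameter gradients into gW/gb.
// dX0_out: if non-null, receive the input-image gradient.
static void backward_one(UNet* net, const fmat& X0,
                         const std::vector<fmat>& dHead, bool accumulate,
                         bool guided, int cam_layer_idx, fmat* cam_grad_out,
                         fmat* dX0_out) {
  const size_t n = net->layers.size();
  std::fill(net->dAset.begin(), net->dAset.end(), 0);
  fmat dX0;
  if (dX0_out) dX0.zeros(arma::size(X0));
  for (size_t h = 0; h < net->head_idx.size(); ++h) {
    const int i = net->head_idx[h];
    if (dHead[h].n_elem == 0) continue;
    Layer& L = net->layers[i];
    fmat& dZ = net->dZ[i];
    dZ = dHead[h];
    if (L.act == A_SIGMOID) dZ %= net->A[i] % (1.0f - net->A[i]);
    const fmat& Xin = net->A[L.input_idx];
    if (accumulate) {
      L.gW += Xin.t() * dZ;
      L.gb += arma::sum(dZ, 0).t();
    }
    add_or_set(net, L.input_idx, dZ * L.W.t());
  }
  for (int i = (int)n - 1; i >= 0; --i) {
    Layer& L = net->layers[i];
    if (L.kind == L_HEAD) continue;
    if (!net->dAset[i]) continue;
    if (cam_layer_idx == i && cam_grad_out) *cam_grad_out = net->dA[i];
    const int h = net->wsH >> L.level, w = net->wsW >> L.level;
    if (L.kind == L_CONV3) {
      fmat& dZ = net->dZ[i];
      dZ.set_size(arma::size(net->dA[i]));
      {
        const float* g = net->dA[i].memptr();
        const float* a = net->A[i].memptr();
        float* z = dZ.memptr();
        const size_t m = dZ.n_elem;
        if (L.act == A_RELU) {
          if (guided)
            for (size_t q = 0; q < m; ++q)
              z[q] = (a[q] > 0.0f && g[q] > 0.0f) ? g[q] : 0.0f;
          else
            for (size_t q = 0; q < m; ++q)
              z[q] = a[q] > 0.0f ? g[q] : 0.0f;
        } else {
          std::memcpy(z, g, m * sizeof(float));
        }
      }
      const fmat& in_cols = net->cols[i];
      if (accumulate) {
        L.gW += in_cols.t() * dZ;
        L.gb += arma::sum(dZ, 0).t();
      }
      if (L.input_idx < 0 && !dX0_out) continue;  // input gradient not needed
      fmat& dCols = net->dCols[i];
      dCols = dZ * L.W.t();
      fmat& dXin = net->dXin[i];
      dXin.zeros((arma::uword)h * w, L.in_ch);
      col2im3(dCols, h, w, dXin);
      if (L.concat_src >= 0) {
        const int f = L.out_ch;
        add_or_set(net, L.input_idx, dXin.cols(0, f - 1));
        add_or_set(net, L.concat_src, dXin.cols(f, L.in_ch - 1));
      } else if (L.input_idx >= 0) {
        add_or_set(net, L.input_idx, dXin);
      } else if (dX0_out) {
        dX0 += dXin;
      }
    } else if (L.kind == L_POOL) {
      const int hin = net->wsH >> (L.level - 1), win = net->wsW >> (L.level - 1);
      const int ho = hin / 2, wo = win / 2;
      fmat& dXin = net->dXin[i];
      dXin.zeros((arma::uword)hin * win, L.in_ch);
      const uvec& idx = net->poolix[i];
      for (int c = 0; c < L.in_ch; ++c) {
        const float* g = net->dA[i].colptr(c);
        float* d = dXin.colptr(c);
        const arma::uword* ixp = idx.memptr() + (size_t)c * ho * wo;
        for (size_t q = 0; q < (size_t)ho * wo; ++q) d[ixp[q]] += g[q];
      }
      add_or_set(net, L.input_idx, dXin);
    } else if (L.kind == L_UP2) {
      const int hin = h / 2, win = w / 2;
      fmat& dT = net->dT[i];
      dT.set_size((arma::uword)hin * win, (arma::uword)L.out_ch * 4);
      for (int f = 0; f < L.out_ch; ++f) {
        const float* src = net->dA[i].colptr(f);
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            float* dst = dT.colptr(f * 4 + dj * 2 + di);
            for (int j = 0; j < win; ++j) {
              const float* scol = src + (size_t)(2 * j + dj) * h + di;
              float* dcol = dst + (size_t)j * hin;
              for (int i2 = 0; i2 < hin; ++i2) dcol[i2] = scol[2 * i2];
            }
          }
        }
      }
      const fmat& Xin = net->A[L.input_idx];
      if (accumulate) {
        L.gW += Xin.t() * dT;
        for (int f = 0; f < L.out_ch; ++f)
          L.gb(f) += arma::accu(net->dA[i].col(f));
      }
      add_or_set(net, L.input_idx, dT * L.W.t());
    }
  }
  if (dX0_out) *dX0_out = dX0;
}

static std::vector<fmat> batch_from_R(const Rcpp::NumericVector& arr,
                                      int& H, int& W, int& N) {
  Rcpp::IntegerVector d;
  if (arr.hasAttribute("dim")) d = arr.attr("dim");
  else stop("batch must be an array");
  if (d.size() == 2) { H = d[0]; W = d[1]; N = 1; }
  else if (d.size() == 3) { H = d[0]; W = d[1]; N = d[2]; }
  else stop("batch must be H x W or H x W x N");
  std::vector<fmat> out(N);
  const double* src = arr.begin();
  const size_t np = (size_t)H * W;
  for (int s = 0; s < N; ++s) {
    out[s].set_size(np, 1);
    float* dst = out[s].memptr();
    for (size_t q = 0; q < np; ++q) dst[q] = (float)src[s * np + q];
  }
  return out;
}

struct LossAcc {
  double total = 0.0;
  std::map<std::string, double> per_term;
};

static List loss_to_R(const LossAcc& acc);

// per-head loss value + gradient for one sample; scale = 1/N folded in
static void head_loss_grad(const Layer& L, const fmat& p, const fvec& t,
                           double smooth, double scale, double& value,
                           fmat& dP) {
  if (L.loss == LO_DICE) {
    const double A = 2.0 * arma::dot(p.col(0), t) + smooth;
    const double B = (double)arma::accu(p.col(0)) + (double)arma::accu(t) +
                     smooth;
    value = A / B;
    dP.set_size(p.n_rows, 1);
    const float Bf = (float)B, Af = (float)A;
    const float sc = (float)(-scale) / (Bf * Bf);
    const float* tp = t.memptr();
    float* dp = dP.memptr();
    for (size_t q = 0; q < p.n_rows; ++q)
      dp[q] = sc * (2.0f * tp[q] * Bf - Af);
  } else {  // sum of squared errors over pixels
    dP.set_size(p.n_rows, 1);
    const float* pp = p.memptr();
    const float* tp = t.memptr();
    float* dp = dP.memptr();
    double s = 0.0;
    const float sc = (float)(2.0 * scale);
    for (size_t q = 0; q < p.n_rows; ++q) {
      const float r = pp[q] - tp[q];
      s += (double)r * r;
      dp[q] = sc * r;
    }
    value = s;
  }
}

// run one mini-batch: forward (+ optional backward with gradient
// accumulation); T[h][s] points at sample s's np-double target for head h;
// per-head loss values are added into val_sum.
static void run_batch(UNet* net, const std::vector<fmat>& X,
                      const std::vector<std::vector<const double*>>& T,
                      double smooth, int H, int W, bool do_grad,
                      std::vector<double>& val_sum) {
  const int N = (int)X.size();
  const size_t nh = net->head_idx.size();
  const size_t np = (size_t)H * W;
  if (do_grad)
    for (auto& L : net->layers) { L.gW.zeros(); L.gb.zeros(); }
  std::vector<fmat> dHead(nh);
  fvec t(np);
  for (int s = 0; s < N; ++s) {
    forward_one(net, X[s], H, W);
    for (size_t h = 0; h < nh; ++h) {
      const Layer& L = net->layers[net->head_idx[h]];
      float* tp = t.memptr();
      const double* src = T[h][s];
      for (size_t q = 0; q < np; ++q) tp[q] = (float)src[q];
      double v;
      head_loss_grad(L, net->A[net->head_idx[h]], t, smooth, 1.0 / N, v,
                     dHead[h]);
      val_sum[h] += v;
    }
    if (do_grad)
      backward_one(net, X[s], dHead, true, false, -1, nullptr, nullptr);
  }
}

static void adam_update(UNet* net, double lr) {
  net->adam_t += 1;
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  const float c1 = 1.0f - (float)std::pow((double)b1, (double)net->adam_t);
  const float c2 = 1.0f - (float)std::pow((double)b2, (double)net->adam_t);
  const float lrf = (float)lr;
  auto upd = [&](float* w, float* m, float* v, const float* g, size_t n) {
    for (size_t i = 0; i < n; ++i) {
      m[i] = b1 * m[i] + (1.0f - b1) * g[i];
      v[i] = b2 * v[i] + (1.0f - b2) * g[i] * g[i];
      w[i] -= lrf * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
    }
  };
  for (auto& L : net->layers) {
    if (L.W.n_elem == 0) continue;
    upd(L.W.memptr(), L.mW.memptr(), L.vW.memptr(), L.gW.memptr(),
        L.W.n_elem);
    upd(L.b.memptr(), L.mb.memptr(), L.vb.memptr(), L.gb.memptr(),
        L.b.n_elem);
  }
}

// target pointers for a list of full H x W x N arrays, one per head name
static std::vector<Rcpp::NumericVector> bind_targets(
    UNet* net, const Rcpp::List& targets, size_t expected) {
  const size_t nh = net->head_idx.size();
  std::vector<Rcpp::NumericVector> tarr(nh);
  for (size_t h = 0; h < nh; ++h) {
    const Layer& L = net->layers[net->head_idx[h]];
    const std::string nm = L.name.substr(5);  // strip "head_"
    if (!targets.containsElementNamed(nm.c_str()))
      stop("missing target for head '%s'", nm.c_str());
    tarr[h] = Rcpp::as<Rcpp::NumericVector>(targets[nm]);
    if ((size_t)tarr[h].size() != expected)
      stop("target '%s' has wrong size", nm.c_str());
  }
  return tarr;
}

static void finish_loss(UNet* net, const std::vector<double>& val_sum, int N,
                        LossAcc& acc) {
  const size_t nh = net->head_idx.size();
  double total = 0.0;
  for (size_t h = 0; h < nh; ++h) {
    const Layer& L = net->layers[net->head_idx[h]];
    const std::string nm = L.name.substr(5);
    const double mean_v = val_sum[h] / N;
    if (L.loss == LO_DICE) {
      acc.per_term["dice_" + nm] = mean_v;
      total -= mean_v;
    } else {
      acc.per_term[nm] = mean_v;  // sum-of-squares term keeps the head name
      total += mean_v;
    }
  }
  acc.total = total;
}

static void eval_losses(UNet* net, const std::vector<fmat>& X,
                        const Rcpp::List& targets, double smooth, int H,
                        int W, bool do_grad, double lr, LossAcc& acc,
                        bool update = true) {
  const int N = (int)X.size();
  const size_t nh = net->head_idx.size();
  const size_t np = (size_t)H * W;
  std::vector<Rcpp::NumericVector> tarr = bind_targets(net, targets, np * N);
  std::vector<std::vector<const double*>> T(nh,
                                            std::vector<const double*>(N));
  for (size_t h = 0; h < nh; ++h)
    for (int s = 0; s < N; ++s) T[h][s] = tarr[h].begin() + (size_t)s * np;
  std::vector<double> val_sum(nh, 0.0);
  run_batch(net, X, T, smooth, H, W, do_grad, val_sum);
  finish_loss(net, val_sum, N, acc);
  if (do_grad && update) adam_update(net, lr);
}

// One full epoch over images (H x W x N) in the given 1-based sample order,
// split into batches of batch_size, one Adam step per batch. The mean of
// the per-batch losses, weighted by batch size, is returned.
// [[Rcpp::export(name = ".unet_train_epoch")]]
List unet_train_epoch(SEXP ptr, Rcpp::NumericVector images, List targets,
                      Rcpp::IntegerVector order, int batch_size, double lr,
                      double smooth) {
  FlushDenormals ftz;
  UNet* net = get_net(ptr);
  Rcpp::IntegerVector d = images.attr("dim");
  if (d.size() != 3) stop("images must be H x W x N");
  const int H = d[0], W = d[1], N = d[2];
  check_dims(net, H, W);
  if (batch_size < 1) stop("batch_size must be >= 1");
  const size_t np = (size_t)H * W;
  const size_t nh = net->head_idx.size();
  std::vector<Rcpp::NumericVector> tarr =
      bind_targets(net, targets, np * (size_t)N);
  const double* img = images.begin();
  std::vector<double> total_sum(nh, 0.0);
  LossAcc acc;
  for (int b0 = 0; b0 < (int)order.size(); b0 += batch_size) {
    const int nb = std::min(batch_size, (int)order.size() - b0);
    std::vector<fmat> X(nb);
    std::vector<std::vector<const double*>> T(
        nh, std::vector<const double*>(nb));
    for (int s = 0; s < nb; ++s) {
      const int ix = order[b0 + s] - 1;
      if (ix < 0 || ix >= N) stop("order index out of range");
      X[s].set_size(np, 1);
      float* dst = X[s].memptr();
      const double* src = img + (size_t)ix * np;
      for (size_t q = 0; q < np; ++q) dst[q] = (float)src[q];
      for (size_t h = 0; h < nh; ++h)
        T[h][s] = tarr[h].begin() + (size_t)ix * np;
    }
    std::vector<double> val_sum(nh, 0.0);
    run_batch(net, X, T, smooth, H, W, true, val_sum);
    // losses are batch means; re-weight by batch size for the epoch mean
    for (size_t h = 0; h < nh; ++h) total_sum[h] += val_sum[h];
    adam_update(net, lr);
  }
  finish_loss(net, total_sum, (int)order.size(), acc);
  return loss_to_R(acc);
}

static List loss_to_R(const LossAcc& acc) {
  List per;
  for (auto& kv : acc.per_term) per[kv.first] = kv.second;
  return List::create(Rcpp::Named("total") = acc.total,
                      Rcpp::Named("per_term") = per);
}

// [[Rcpp::export(name = ".unet_train_step")]]
List unet_train_step(SEXP ptr, Rcpp::NumericVector batch, List targets,
                     double lr, double smooth) {
  FlushDenormals ftz;
  UNet* net = get_net(ptr);
  int H, W, N;
  std::vector<fmat> X = batch_from_R(batch, H, W, N);
  check_dims(net, H, W);
  LossAcc acc;
  eval_losses(net, X, targets, smooth, H, W, true, lr, acc);
  return loss_to_R(acc);
}

// Analytic loss gradients (no parameter update); validated against finite
// differences in the tests.
// [[Rcpp::export(name = ".unet_grads")]]
List unet_grads(SEXP ptr, Rcpp::NumericVector batch, List targets,
                double smooth) {
  FlushDenormals ftz;
  UNet* net = get_net(ptr);
  int H, W, N;
  std::vector<fmat> X = batch_from_R(batch, H, W, N);
  check_dims(net, H, W);
  LossAcc acc;
  eval_losses(net, X, targets, smooth, H, W, true, 0.0, acc, false);
  List res;
  for (auto& L : net->layers) {
    if (L.W.n_elem == 0) continue;
    Rcpp::NumericMatrix gW((int)L.gW.n_rows, (int)L.gW.n_cols);
    std::copy(L.gW.begin(), L.gW.end(), gW.begin());
    Rcpp::NumericVector gb((R_xlen_t)L.gb.n_elem);
    std::copy(L.gb.begin(), L.gb.end(), gb.begin());
    res[L.name] = List::create(Rcpp::Named("W") = gW, Rcpp::Named("b") = gb);
  }
  res.attr("total") = acc.total;
  return res;
}

// [[Rcpp::export(name = ".unet_loss")]]
List unet_loss(SEXP ptr, Rcpp::NumericVector batch, List targets,
               double smooth) {
  FlushDenormals ftz;
  UNet* net = get_net(ptr);
  int H, W, N;
  std::vector<fmat> X = batch_from_R(batch, H, W, N);
  check_dims(net, H, W);
  LossAcc acc;
  eval_losses(net, X, targets, smooth, H, W, false, 0.0, acc);
  return loss_to_R(acc);
}

// [[Rcpp::export(name = ".unet_predict")]]
List unet_predict(SEXP ptr, Rcpp::NumericVector batch) {
  FlushDenormals ftz;
  UNet* net = get_net(ptr);
  int H, W, N;
  std::vector<fmat> X = batch_from_R(batch, H, W, N);
  check_dims(net, H, W);
  const size_t np = (size_t)H * W;
  const size_t nh = net->head_idx.size();
  std::vector<Rcpp::NumericVector> out(nh);
  for (size_t h = 0; h < nh; ++h) {
    out[h] = Rcpp::NumericVector((R_xlen_t)(np * N));
    out[h].attr("dim") = Rcpp::IntegerVector::create(H, W, N);
  }
  for (int s = 0; s < N; ++s) {
    forward_one(net, X[s], H, W);
    for (size_t h = 0; h < nh; ++h) {
      const fmat& p = net->A[net->head_idx[h]];
      double* dst = out[h].begin() + s * np;
      for (size_t q = 0; q < np; ++q) dst[q] = p(q, 0);
    }
  }
  List res;
  for (size_t h = 0; h < nh; ++h) {
    const Layer& L = net->layers[net->head_idx[h]];
    res[L.name.substr(5)] = out[h];
  }
  return res;
}

// [[Rcpp::export(name = ".unet_forward_capture")]]
List unet_forward_capture(SEXP ptr, Rcpp::NumericVector image) {
  FlushDenormals ftz;
  UNet* net = get_net(ptr);
  int H, W, N;
  std::vector<fmat> X = batch_from_R(image, H, W, N);
  if (N != 1) stop("capture expects a single image");
  check_dims(net, H, W);
  forward_one(net, X[0], H, W);
  List res;
  for (size_t i = 0; i < net->layers.size(); ++i) {
    const Layer& L = net->layers[i];
    const int h = H >> L.level, w = W >> L.level;
    Rcpp::NumericVector a((R_xlen_t)net->A[i].n_elem);
    std::copy(net->A[i].begin(), net->A[i].end(), a.begin());
    a.attr("dim") = Rcpp::IntegerVector::create(h, w, (int)net->A[i].n_cols);
    res[L.name] = a;
  }
  return res;
}

// [[Rcpp::export(name = ".unet_attribution")]]
List unet_attribution(SEXP ptr, Rcpp::NumericVector image,
                      std::string head, Rcpp::NumericVector out_weight,
                      bool guided, std::string cam_layer) {
  FlushDenormals ftz;
  UNet* net = get_net(ptr);
  int H, W, N;
  std::vector<fmat> X = batch_from_R(image, H, W, N);
  if (N != 1) stop("attribution expects a single image");
  check_dims(net, H, W);
  const size_t np = (size_t)H * W;
  if ((size_t)out_weight.size() != np)
    stop("out_weight must match image size");
  int hsel = -1;
  for (size_t h = 0; h < net->head_idx.size(); ++h)
    if (net->layers[net->head_idx[h]].name == "head_" + head) hsel = (int)h;
  if (hsel < 0) stop("no head named '%s'", head.c_str());
  int cam_idx = -1;
  if (!cam_layer.empty()) {
    for (size_t i = 0; i < net->layers.size(); ++i)
      if (net->layers[i].name == cam_layer) cam_idx = (int)i;
    if (cam_idx < 0) stop("no layer named '%s'", cam_layer.c_str());
  }
  forward_one(net, X[0], H, W);
  std::vector<fmat> dHead(net->head_idx.size());
  fmat wv(np, 1);
  for (size_t q = 0; q < np; ++q) wv(q, 0) = (float)out_weight[q];
  dHead[hsel] = wv;
  fmat cam_grad, dX0;
  backward_one(net, X[0], dHead, false, guided, cam_idx, &cam_grad, &dX0);
  List res;
  Rcpp::NumericVector g((R_xlen_t)np);
  std::copy(dX0.begin(), dX0.end(), g.begin());
  g.attr("dim") = Rcpp::IntegerVector::create(H, W);
  res["input_grad"] = g;
  if (cam_idx >= 0) {
    const Layer& L = net->layers[cam_idx];
    const int h = H >> L.level, w = W >> L.level;
    Rcpp::NumericVector ca((R_xlen_t)net->A[cam_idx].n_elem);
    std::copy(net->A[cam_idx].begin(), net->A[cam_idx].end(), ca.begin());
    ca.attr("dim") = Rcpp::IntegerVector::create(h, w, (int)L.out_ch);
    res["cam_act"] = ca;
    Rcpp::NumericVector cg((R_xlen_t)((size_t)h * w * L.out_ch));
    if (cam_grad.n_elem > 0)
      std::copy(cam_grad.begin(), cam_grad.end(), cg.begin());
    cg.attr("dim") = Rcpp::IntegerVector::create(h, w, (int)L.out_ch);
    res["cam_grad"] = cg;
  }
  return res;
}

// [[Rcpp::export(name = ".unet_get_weights")]]
List unet_get_weights(SEXP ptr) {
  UNet* net = get_net(ptr);
  List res;
  for (auto& L : net->layers) {
    if (L.W.n_elem == 0) continue;
    Rcpp::NumericMatrix W((int)L.W.n_rows, (int)L.W.n_cols);
    std::copy(L.W.begin(), L.W.end(), W.begin());
    Rcpp::NumericVector b((R_xlen_t)L.b.n_elem);
    std::copy(L.b.begin(), L.b.end(), b.begin());
    res[L.name] = List::create(Rcpp::Named("W") = W, Rcpp::Named("b") = b);
  }
  return res;
}

// [[Rcpp::export(name = ".unet_set_weights")]]
void unet_set_weights(SEXP ptr, List weights) {
  UNet* net = get_net(ptr);
  for (auto& L : net->layers) {
    if (L.W.n_elem == 0) continue;
    if (!weights.containsElementNamed(L.name.c_str()))
      stop("missing weights for layer '%s'", L.name.c_str());
    List wl = weights[L.name];
    Rcpp::NumericMatrix W = wl["W"];
    Rcpp::NumericVector b = wl["b"];
    if ((size_t)W.nrow() != L.W.n_rows || (size_t)W.ncol() != L.W.n_cols)
      stop("weight shape mismatch at layer '%s'", L.name.c_str());
    if ((size_t)b.size() != L.b.n_elem)
      stop("bias length mismatch at layer '%s'", L.name.c_str());
    std::copy(W.begin(), W.end(), L.W.begin());
    std::copy(b.begin(), b.end(), L.b.begin());
  }
}

// [[Rcpp::export(name = ".unet_layer_info")]]
Rcpp::DataFrame unet_layer_info(SEXP ptr) {
  UNet* net = get_net(ptr);
  std::vector<std::string> nm;
  std::vector<int> kind, in_ch, out_ch, nW, nb;
  for (auto& L : net->layers) {
    nm.push_back(L.name);
    kind.push_back(L.kind);
    in_ch.push_back(L.in_ch);
    out_ch.push_back(L.out_ch);
    nW.push_back((int)L.W.n_elem);
    nb.push_back((int)L.b.n_elem);
  }
  return Rcpp::DataFrame::create(
      Rcpp::Named("layer") = nm, Rcpp::Named("kind") = kind,
      Rcpp::Named("in_ch") = in_ch, Rcpp::Named("out_ch") = out_ch,
      Rcpp::Named("n_weights") = nW, Rcpp::Named("n_bias") = nb,
      Rcpp::Named("stringsAsFactors") = false);
}
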