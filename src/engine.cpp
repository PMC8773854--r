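// Training/inference engine for the multibranch EEG ConvNets.
//
// All activations and parameters are single precision; the expensive steps
// (temporal convolution, dense layer) are expressed as BLAS sgemm through
// Armadillo. The engine is deliberately specialised to the two branch
// families (EEGNet-style, ShallowConvNet-style) rather than a generic layer
// graph: the first temporal convolution dominates the cost, and writing it
// as a padded im2col + one gemm per trial keeps a 50-epoch run on hundreds
// of trials tractable on one CPU core.
//
// Layout conventions:
//   * a batch is an arma::fcube (T, C, B): slice = trial, column = channel;
//   * temporal conv output per trial is ((C*T) x F); column f reshaped
//     (T, C) column-major recovers the (time, channel) plane of map f;
//   * feature-map tensors after the spatial stage are (T', M, B).
//
// Batch norm follows the usual mini-batch formulation (biased variance,
// eps 1e-3, running stats with momentum 0.99); inference uses running stats.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;
using arma::fcube;

static const float BN_EPS = 1e-3f;
static const float BN_MOMENTUM = 0.99f;
static const float LOG_EPS = 1e-6f;

// ---------------------------------------------------------------- parameters

struct Param {
  std::string name;
  fmat w, g, m, v;   // value, gradient, Adam moments
  void init(const std::string& nm, int r, int c) {
    name = nm;
    w.set_size(r, c);
    g.zeros(r, c);
    m.zeros(r, c);
    v.zeros(r, c);
  }
  void glorot(std::mt19937& rng, double fan_in, double fan_out) {
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> U(-lim, lim);
    for (arma::uword i = 0; i < w.n_elem; ++i) w[i] = (float)U(rng);
  }
};

struct BNLayer {
  std::string name;
  fvec gamma, beta, rmean, rvar;    // trainable scale/shift + running stats
  fvec gg, gb, mg, vg, mb, vb;      // grads + Adam moments
  fvec bmean, bistd;                // cached batch statistics
  long steps = 0;                   // batches folded into the running stats
  void init(const std::string& nm, int n) {
    name = nm;
    gamma.ones(n); beta.zeros(n);
    rmean.zeros(n); rvar.zeros(n);
    gg.zeros(n); gb.zeros(n);
    mg.zeros(n); vg.zeros(n); mb.zeros(n); vb.zeros(n);
    bmean.zeros(n); bistd.zeros(n);
    steps = 0;
  }
  // running statistics are exponential moving averages started at zero;
  // zero-debiasing (divide by 1 - momentum^steps) makes them unbiased even
  // after few updates, so a checkpoint restored from an early epoch still
  // normalises consistently at inference time
  void update_running(int f, float mean, float var) {
    rmean[f] = BN_MOMENTUM * rmean[f] + (1.0f - BN_MOMENTUM) * mean;
    rvar[f]  = BN_MOMENTUM * rvar[f]  + (1.0f - BN_MOMENTUM) * var;
  }
  float corr() const {
    return steps > 0 ? (float)(1.0 - std::pow((double)BN_MOMENTUM, (double)steps))
                     : 1.0f;
  }
  // steps semantics: 0 = untrained (mean 0, var 1); > 0 = debiased EMA;
  // -1 = explicit statistics installed via set_weights, used verbatim
  float infer_mean(int f) const {
    if (steps < 0) return rmean[f];
    return steps > 0 ? rmean[f] / corr() : 0.0f;
  }
  float infer_istd(int f) const {
    float v;
    if (steps < 0) v = rvar[f];
    else v = steps > 0 ? std::max(rvar[f] / corr(), 0.0f) : 1.0f;
    return 1.0f / std::sqrt(v + BN_EPS);
  }
  void begin_training_batch() {
    if (steps < 0) { steps = 0; rmean.zeros(); rvar.zeros(); }
    steps++;
  }
};

// ELU and its derivative expressed from the output value (monotone, f(0)=0)
static inline float elu(float x) { return x > 0.0f ? x : std::expm1(x); }
static inline float elu_grad_from_out(float a) { return a > 0.0f ? 1.0f : a + 1.0f; }

// ------------------------------------------------------------- branch configs

struct EEGBranchCfg {
  int F1, KE, D, F2, sep_len, pool1, pool2;
  double dropout;
};

struct ShallowBranchCfg {
  int n_filters, KE, pool_len, pool_stride;
  double dropout;
};

// --------------------------------------------------------------- EEG branch

struct EEGBranch {
  EEGBranchCfg cfg;
  int T, C, M, T1, T2, pad1, pad_sep;
  Param W1, Wd, Ws, Wp;
  BNLayer bn1, bn2, bn3;

  // caches (sized per batch at forward time). The temporal stage keeps the
  // RAW convolution output per trial (cube slice = contiguous (C*T) x F1
  // matrix); the first batch norm is never materialised — being affine per
  // map, it is folded into the depthwise stage, and its statistics and
  // gradient reductions are fused into the per-trial loops while the data
  // are cache-hot. The im2col matrix lives in a single per-trial scratch
  // buffer so the conv gemms read from cache instead of a batch-sized
  // matrix in main memory.
  fcube y1;             // (C*T, F1, B) raw temporal-conv output
  fcube dy1;            // (C*T, F1, B) gradient at the temporal-conv output
  fmat xcol_scratch;    // (T, KE) one channel's padded im2col (L2-resident)
  fmat xpad_scratch;    // (T+KE-1, C)
  fmat ytmp_scratch;    // (T, F1)
  fcube z2hat, a2;      // (T, M, B)
  fcube mask1;          // (T1, M, B) inverted-dropout mask (if dropout > 0)
  fcube pd1, dc;        // (T1, M, B) pooled+dropped input / depthwise output
  fcube x3hat, a3;      // (T1, F2, B)
  fcube mask2;          // (T2, F2, B)
  fmat feats;           // (T2*F2, B)

  int feat_len() const { return T2 * cfg.F2; }

  void configure(const EEGBranchCfg& c, int T_, int C_, const std::string& tag,
                 std::mt19937& rng) {
    cfg = c; T = T_; C = C_;
    M = cfg.F1 * cfg.D;
    T1 = T / cfg.pool1;
    T2 = T1 / cfg.pool2;
    pad1 = (cfg.KE - 1) / 2;
    pad_sep = (cfg.sep_len - 1) / 2;
    if (T1 < 1 || T2 < 1)
      Rcpp::stop("pooling collapses the time axis to zero length");
    W1.init(tag + "_temporal_conv", cfg.KE, cfg.F1);
    W1.glorot(rng, cfg.KE, (double)cfg.KE * cfg.F1);
    Wd.init(tag + "_depthwise_spatial", C, M);
    Wd.glorot(rng, C, (double)C * cfg.D);
    Ws.init(tag + "_separable_depthwise", cfg.sep_len, M);
    Ws.glorot(rng, cfg.sep_len, cfg.sep_len);
    Wp.init(tag + "_separable_pointwise", M, cfg.F2);
    Wp.glorot(rng, M, cfg.F2);
    bn1.init(tag + "_batchnorm1", cfg.F1);
    bn2.init(tag + "_batchnorm2", M);
    bn3.init(tag + "_batchnorm3", cfg.F2);
  }

  // padded im2col of one channel of the current trial (xpad_scratch must
  // hold the zero-padded trial); the (T x KE) block stays cache-resident
  void im2col_channel(int c) {
    for (int k = 0; k < cfg.KE; ++k)
      std::memcpy(xcol_scratch.colptr(k), xpad_scratch.colptr(c) + k,
                  sizeof(float) * T);
  }
  void pad_trial(const fmat& x) {
    xpad_scratch.zeros();
    xpad_scratch.rows(pad1, pad1 + T - 1) = x;
  }

  // batch norm over the map columns of a (T', nmap, B) cube
  void bn_forward_cube(BNLayer& bn, fcube& x, bool training) {
    const int nmap = x.n_cols, B = x.n_slices, R = x.n_rows;
    const double N = (double)R * B;
    for (int f = 0; f < nmap; ++f) {
      float mean, istd;
      if (training) {
        double s = 0, ss = 0;
        for (int b = 0; b < B; ++b) {
          const float* p = x.slice(b).colptr(f);
          for (int r = 0; r < R; ++r) { s += p[r]; ss += (double)p[r] * p[r]; }
        }
        double mu = s / N, var = ss / N - mu * mu;
        if (var < 0) var = 0;
        mean = (float)mu;
        istd = (float)(1.0 / std::sqrt(var + BN_EPS));
        bn.update_running(f, mean, (float)var);
      } else {
        mean = bn.infer_mean(f);
        istd = bn.infer_istd(f);
      }
      bn.bmean[f] = mean; bn.bistd[f] = istd;
      for (int b = 0; b < B; ++b) {
        float* p = x.slice(b).colptr(f);
        for (int r = 0; r < R; ++r) p[r] = (p[r] - mean) * istd;
      }
    }
    if (training) bn.begin_training_batch();
  }

  void bn_backward_cube(BNLayer& bn, const fcube& xhat, fcube& d, bool training) {
    const int nmap = xhat.n_cols, B = xhat.n_slices, R = xhat.n_rows;
    const double N = (double)R * B;
    for (int f = 0; f < nmap; ++f) {
      double sd = 0, sdx = 0;
      for (int b = 0; b < B; ++b) {
        const float* pd = d.slice(b).colptr(f);
        const float* px = xhat.slice(b).colptr(f);
        for (int r = 0; r < R; ++r) { sd += pd[r]; sdx += (double)pd[r] * px[r]; }
      }
      bn.gb[f] += (float)sd;
      bn.gg[f] += (float)sdx;
      const float g = bn.gamma[f], istd = bn.bistd[f];
      if (training) {
        const float c1 = (float)(sd / N), c2 = (float)(sdx / N);
        for (int b = 0; b < B; ++b) {
          float* pd = d.slice(b).colptr(f);
          const float* px = xhat.slice(b).colptr(f);
          for (int r = 0; r < R; ++r)
            pd[r] = g * istd * (pd[r] - c1 - px[r] * c2);
        }
      } else {
        for (int b = 0; b < B; ++b) {
          float* pd = d.slice(b).colptr(f);
          for (int r = 0; r < R; ++r) pd[r] = g * istd * pd[r];
        }
      }
    }
  }

  void forward(const fcube& X, bool training, std::mt19937& rng) {
    const int B = X.n_slices;
    const int F1 = cfg.F1, F2 = cfg.F2;
    const size_t CT = (size_t)C * T;
    const double N1 = (double)CT * B;

    // temporal convolution, one cache-resident im2col + gemm per channel,
    // with the batch-norm statistics accumulated while the output is hot
    y1.set_size(CT, F1, B);
    xcol_scratch.set_size(T, cfg.KE);
    xpad_scratch.set_size(T + cfg.KE - 1, C);
    ytmp_scratch.set_size(T, F1);
    std::vector<double> s1(F1, 0.0), ss1(F1, 0.0);
    for (int b = 0; b < B; ++b) {
      pad_trial(X.slice(b));
      for (int c = 0; c < C; ++c) {
        im2col_channel(c);
        ytmp_scratch = xcol_scratch * W1.w;
        for (int f = 0; f < F1; ++f) {
          const float* p = ytmp_scratch.colptr(f);
          float* dst = y1.slice(b).colptr(f) + (size_t)c * T;
          if (training) {
            double s = 0, ss = 0;
            for (int r = 0; r < T; ++r) {
              dst[r] = p[r];
              s += p[r]; ss += (double)p[r] * p[r];
            }
            s1[f] += s; ss1[f] += ss;
          } else {
            std::memcpy(dst, p, sizeof(float) * T);
          }
        }
      }
    }
    for (int f = 0; f < F1; ++f) {
      if (training) {
        double mu = s1[f] / N1, var = ss1[f] / N1 - mu * mu;
        if (var < 0) var = 0;
        bn1.bmean[f] = (float)mu;
        bn1.bistd[f] = (float)(1.0 / std::sqrt(var + BN_EPS));
        bn1.update_running(f, (float)mu, (float)var);
      } else {
        bn1.bmean[f] = bn1.infer_mean(f);
        bn1.bistd[f] = bn1.infer_istd(f);
      }
    }
    if (training) bn1.begin_training_batch();

    // depthwise spatial convolution; batch norm 1 enters as the affine map
    // y -> a*y + c with a = gamma*istd, c = beta - gamma*istd*mean
    fcube z(T, M, B);
    fmat tmp(T, C);
    for (int b = 0; b < B; ++b) {
      for (int f = 0; f < F1; ++f) {
        const float a = bn1.gamma[f] * bn1.bistd[f];
        const float cc = bn1.beta[f] - a * bn1.bmean[f];
        const fmat view(const_cast<float*>(y1.slice(b).colptr(f)), T, C, false, true);
        tmp = view * a;
        tmp += cc;
        z.slice(b).cols(f * cfg.D, f * cfg.D + cfg.D - 1) =
          tmp * Wd.w.cols(f * cfg.D, f * cfg.D + cfg.D - 1);
      }
    }
    bn_forward_cube(bn2, z, training);
    z2hat = std::move(z);
    a2.set_size(T, M, B);
    for (int b = 0; b < B; ++b)
      for (int m = 0; m < M; ++m) {
        const float* ph = z2hat.slice(b).colptr(m);
        float* pa = a2.slice(b).colptr(m);
        const float g = bn2.gamma[m], be = bn2.beta[m];
        for (int t = 0; t < T; ++t) pa[t] = elu(g * ph[t] + be);
      }

    // average pool 1 + dropout
    pd1.set_size(T1, M, B);
    const float inv_p1 = 1.0f / cfg.pool1;
    for (int b = 0; b < B; ++b)
      for (int m = 0; m < M; ++m) {
        const float* src = a2.slice(b).colptr(m);
        float* dst = pd1.slice(b).colptr(m);
        for (int t = 0; t < T1; ++t) {
          float s = 0;
          for (int k = 0; k < cfg.pool1; ++k) s += src[t * cfg.pool1 + k];
          dst[t] = s * inv_p1;
        }
      }
    const bool use_drop = training && cfg.dropout > 0;
    if (use_drop) {
      mask1.set_size(T1, M, B);
      const double keep = 1.0 - cfg.dropout;
      std::uniform_real_distribution<double> U(0.0, 1.0);
      for (arma::uword i = 0; i < mask1.n_elem; ++i)
        mask1[i] = U(rng) < keep ? (float)(1.0 / keep) : 0.0f;
      pd1 %= mask1;
    }

    // separable convolution: per-map temporal depthwise, then 1x1 pointwise
    dc.set_size(T1, M, B);
    for (int b = 0; b < B; ++b)
      for (int m = 0; m < M; ++m) {
        const float* src = pd1.slice(b).colptr(m);
        const float* ker = Ws.w.colptr(m);
        float* dst = dc.slice(b).colptr(m);
        for (int t = 0; t < T1; ++t) {
          float s = 0;
          const int k0 = std::max(0, pad_sep - t);
          const int k1 = std::min(cfg.sep_len, T1 + pad_sep - t);
          for (int k = k0; k < k1; ++k) s += ker[k] * src[t + k - pad_sep];
          dst[t] = s;
        }
      }
    x3hat.set_size(T1, F2, B);
    for (int b = 0; b < B; ++b) x3hat.slice(b) = dc.slice(b) * Wp.w;
    bn_forward_cube(bn3, x3hat, training);
    a3.set_size(T1, F2, B);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F2; ++f) {
        const float* ph = x3hat.slice(b).colptr(f);
        float* pa = a3.slice(b).colptr(f);
        const float g = bn3.gamma[f], be = bn3.beta[f];
        for (int t = 0; t < T1; ++t) pa[t] = elu(g * ph[t] + be);
      }

    // average pool 2 + dropout + flatten
    feats.set_size((size_t)T2 * F2, B);
    const float inv_p2 = 1.0f / cfg.pool2;
    fmat q(T2, F2);
    if (use_drop) mask2.set_size(T2, F2, B);
    std::uniform_real_distribution<double> U(0.0, 1.0);
    const double keep = 1.0 - cfg.dropout;
    for (int b = 0; b < B; ++b) {
      for (int f = 0; f < F2; ++f) {
        const float* src = a3.slice(b).colptr(f);
        for (int t = 0; t < T2; ++t) {
          float s = 0;
          for (int k = 0; k < cfg.pool2; ++k) s += src[t * cfg.pool2 + k];
          q(t, f) = s * inv_p2;
        }
      }
      if (use_drop) {
        for (arma::uword i = 0; i < q.n_elem; ++i)
          mask2.slice(b)[i] = U(rng) < keep ? (float)(1.0 / keep) : 0.0f;
        q %= mask2.slice(b);
      }
      std::memcpy(feats.colptr(b), q.memptr(), sizeof(float) * q.n_elem);
    }
  }

  void backward(const fcube& X, const fmat& dfeats, bool training) {
    const int B = X.n_slices;
    const int F1 = cfg.F1, F2 = cfg.F2;
    const size_t CT = (size_t)C * T;
    const double N1 = (double)CT * B;
    const bool use_drop = training && cfg.dropout > 0;

    // unflatten -> pool2 backward -> ELU -> BN3
    fcube d3(T1, F2, B);
    const float inv_p2 = 1.0f / cfg.pool2;
    for (int b = 0; b < B; ++b) {
      fmat dq(const_cast<float*>(dfeats.colptr(b)), T2, F2, false, true);
      for (int f = 0; f < F2; ++f) {
        float* dst = d3.slice(b).colptr(f);
        const float* a = a3.slice(b).colptr(f);
        const float* m2 = use_drop ? mask2.slice(b).colptr(f) : nullptr;
        for (int t = 0; t < T1; ++t) {
          const int t2 = t / cfg.pool2;
          float g = 0;
          if (t2 < T2) {
            g = dq(t2, f) * inv_p2;
            if (use_drop) g *= m2[t2];
          }
          dst[t] = g * elu_grad_from_out(a[t]);
        }
      }
    }
    bn_backward_cube(bn3, x3hat, d3, training);

    // pointwise + separable depthwise backward
    fcube ddc(T1, M, B);
    for (int b = 0; b < B; ++b) {
      Wp.g += dc.slice(b).t() * d3.slice(b);
      ddc.slice(b) = d3.slice(b) * Wp.w.t();
    }
    fcube dp1(T1, M, B, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int m = 0; m < M; ++m) {
        const float* dout = ddc.slice(b).colptr(m);
        const float* src = pd1.slice(b).colptr(m);
        float* gker = Ws.g.colptr(m);
        const float* ker = Ws.w.colptr(m);
        float* din = dp1.slice(b).colptr(m);
        for (int t = 0; t < T1; ++t) {
          const int k0 = std::max(0, pad_sep - t);
          const int k1 = std::min(cfg.sep_len, T1 + pad_sep - t);
          const float d = dout[t];
          for (int k = k0; k < k1; ++k) {
            gker[k] += d * src[t + k - pad_sep];
            din[t + k - pad_sep] += d * ker[k];
          }
        }
      }
    if (use_drop) dp1 %= mask1;

    // pool1 backward -> ELU -> BN2
    fcube d2(T, M, B);
    const float inv_p1 = 1.0f / cfg.pool1;
    for (int b = 0; b < B; ++b)
      for (int m = 0; m < M; ++m) {
        const float* dp = dp1.slice(b).colptr(m);
        const float* a = a2.slice(b).colptr(m);
        float* dst = d2.slice(b).colptr(m);
        for (int t = 0; t < T; ++t) {
          const int t1 = t / cfg.pool1;
          const float g = (t1 < T1) ? dp[t1] * inv_p1 : 0.0f;
          dst[t] = g * elu_grad_from_out(a[t]);
        }
      }
    bn_backward_cube(bn2, z2hat, d2, training);

    // depthwise spatial backward, fused with the batch-norm-1 gradient
    // reductions (xhat recomputed on the fly from the raw conv output)
    dy1.set_size(CT, F1, B);
    std::vector<double> sd1(F1, 0.0), sdx1(F1, 0.0);
    fmat tmp(T, C), dtmp(T, C);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F1; ++f) {
        const float a = bn1.gamma[f] * bn1.bistd[f];
        const float cc = bn1.beta[f] - a * bn1.bmean[f];
        const fmat view(const_cast<float*>(y1.slice(b).colptr(f)), T, C, false, true);
        tmp = view * a;
        tmp += cc;
        const fmat dz = d2.slice(b).cols(f * cfg.D, f * cfg.D + cfg.D - 1);
        Wd.g.cols(f * cfg.D, f * cfg.D + cfg.D - 1) += tmp.t() * dz;
        dtmp = dz * Wd.w.cols(f * cfg.D, f * cfg.D + cfg.D - 1).t();
        float* out = dy1.slice(b).colptr(f);
        const float* pv = view.memptr();
        const float* pdt = dtmp.memptr();
        const float mu = bn1.bmean[f], istd = bn1.bistd[f];
        double sd = 0, sdx = 0;
        for (size_t r = 0; r < CT; ++r) {
          const float d = pdt[r];
          out[r] = d;
          sd += d;
          sdx += (double)d * ((pv[r] - mu) * istd);
        }
        sd1[f] += sd; sdx1[f] += sdx;
      }
    for (int f = 0; f < F1; ++f) {
      bn1.gb[f] += (float)sd1[f];
      bn1.gg[f] += (float)sdx1[f];
    }

    // batch-norm-1 input gradient fused per trial with the temporal-conv
    // weight gradient (per-channel im2col rebuilt into the cache-resident
    // scratch, gradients gathered channel-wise)
    fmat dtmp2(T, F1);
    for (int b = 0; b < B; ++b) {
      for (int f = 0; f < F1; ++f) {
        const float g = bn1.gamma[f], istd = bn1.bistd[f], mu = bn1.bmean[f];
        float* pd = dy1.slice(b).colptr(f);
        const float* pv = y1.slice(b).colptr(f);
        if (training) {
          const float c1 = (float)(sd1[f] / N1), c2 = (float)(sdx1[f] / N1);
          for (size_t r = 0; r < CT; ++r)
            pd[r] = g * istd * (pd[r] - c1 - (pv[r] - mu) * istd * c2);
        } else {
          for (size_t r = 0; r < CT; ++r) pd[r] = g * istd * pd[r];
        }
      }
      pad_trial(X.slice(b));
      for (int c = 0; c < C; ++c) {
        im2col_channel(c);
        for (int f = 0; f < F1; ++f)
          std::memcpy(dtmp2.colptr(f), dy1.slice(b).colptr(f) + (size_t)c * T,
                      sizeof(float) * T);
        W1.g += xcol_scratch.t() * dtmp2;
      }
    }
  }

  void free_caches() {
    y1.reset(); dy1.reset(); xcol_scratch.reset(); xpad_scratch.reset();
    ytmp_scratch.reset();
    z2hat.reset(); a2.reset(); mask1.reset(); pd1.reset(); dc.reset();
    x3hat.reset(); a3.reset(); mask2.reset(); feats.reset();
  }
};

// ------------------------------------------------------------ shallow branch

struct ShallowBranch {
  ShallowBranchCfg cfg;
  int T, C, Tv, T2;
  Param W1, Wspat;
  BNLayer bn;

  fcube y1;            // (C*Tv, F, B) temporal conv output
  fcube zhat;          // (Tv, F, B) normalised spatial output
  fcube pool_out;      // (T2, F, B) pooled squared activations (pre-log)
  fcube mask;          // (T2, F, B)
  fmat feats;          // (T2*F, B)

  int feat_len() const { return T2 * cfg.n_filters; }

  void configure(const ShallowBranchCfg& c, int T_, int C_, const std::string& tag,
                 std::mt19937& rng) {
    cfg = c; T = T_; C = C_;
    Tv = T - cfg.KE + 1;
    if (Tv < cfg.pool_len)
      Rcpp::stop("pooling collapses the time axis to zero length");
    T2 = (Tv - cfg.pool_len) / cfg.pool_stride + 1;
    const int F = cfg.n_filters;
    W1.init(tag + "_temporal_conv", cfg.KE, F);
    W1.glorot(rng, cfg.KE, (double)cfg.KE * F);
    Wspat.init(tag + "_spatial_conv", (size_t)C * F, F);
    Wspat.glorot(rng, (double)C * F, F);
    bn.init(tag + "_batchnorm", F);
  }

  void im2col_valid(const fmat& x, fmat& xcol) const {
    for (int k = 0; k < cfg.KE; ++k) {
      float* dst = xcol.colptr(k);
      for (int c = 0; c < C; ++c)
        std::memcpy(dst + (size_t)c * Tv, x.colptr(c) + k, sizeof(float) * Tv);
    }
  }

  void forward(const fcube& X, bool training, std::mt19937& rng) {
    const int B = X.n_slices, F = cfg.n_filters;
    y1.set_size((size_t)C * Tv, F, B);
    fmat xcol((size_t)C * Tv, cfg.KE);
    for (int b = 0; b < B; ++b) {
      im2col_valid(X.slice(b), xcol);
      y1.slice(b) = xcol * W1.w;
    }
    // spatial convolution mixing all temporal maps
    zhat.set_size(Tv, F, B);
    for (int b = 0; b < B; ++b) {
      zhat.slice(b).zeros();
      for (int f = 0; f < F; ++f) {
        const fmat view(const_cast<float*>(y1.slice(b).colptr(f)), Tv, C, false, true);
        zhat.slice(b) += view * Wspat.w.rows((size_t)f * C, (size_t)f * C + C - 1);
      }
    }
    // batch norm -> square -> overlapping average pool -> log
    bn_forward(zhat, training);
    const int B2 = B;
    pool_out.set_size(T2, F, B2);
    const float inv_p = 1.0f / cfg.pool_len;
    fmat s(Tv, F);
    feats.set_size((size_t)T2 * F, B2);
    const bool use_drop = training && cfg.dropout > 0;
    if (use_drop) mask.set_size(T2, F, B2);
    std::uniform_real_distribution<double> U(0.0, 1.0);
    const double keep = 1.0 - cfg.dropout;
    fmat q(T2, F);
    for (int b = 0; b < B2; ++b) {
      for (int f = 0; f < F; ++f) {
        const float* ph = zhat.slice(b).colptr(f);
        float* ps = s.colptr(f);
        const float g = bn.gamma[f], be = bn.beta[f];
        for (int t = 0; t < Tv; ++t) { const float v = g * ph[t] + be; ps[t] = v * v; }
        float* po = pool_out.slice(b).colptr(f);
        for (int t = 0; t < T2; ++t) {
          float acc = 0;
          const int t0 = t * cfg.pool_stride;
          for (int k = 0; k < cfg.pool_len; ++k) acc += ps[t0 + k];
          po[t] = acc * inv_p;
        }
        for (int t = 0; t < T2; ++t)
          q(t, f) = std::log(std::max(po[t], LOG_EPS));
      }
      if (use_drop) {
        for (arma::uword i = 0; i < q.n_elem; ++i)
          mask.slice(b)[i] = U(rng) < keep ? (float)(1.0 / keep) : 0.0f;
        q %= mask.slice(b);
      }
      std::memcpy(feats.colptr(b), q.memptr(), sizeof(float) * q.n_elem);
    }
  }

  void bn_forward(fcube& x, bool training) {
    const int F = x.n_cols, B = x.n_slices, R = x.n_rows;
    const double N = (double)R * B;
    for (int f = 0; f < F; ++f) {
      float mean, istd;
      if (training) {
        double sAcc = 0, ssAcc = 0;
        for (int b = 0; b < B; ++b) {
          const float* p = x.slice(b).colptr(f);
          for (int r = 0; r < R; ++r) { sAcc += p[r]; ssAcc += (double)p[r] * p[r]; }
        }
        double mu = sAcc / N, var = ssAcc / N - mu * mu;
        if (var < 0) var = 0;
        mean = (float)mu;
        istd = (float)(1.0 / std::sqrt(var + BN_EPS));
        bn.update_running(f, mean, (float)var);
      } else {
        mean = bn.infer_mean(f);
        istd = bn.infer_istd(f);
      }
      bn.bmean[f] = mean; bn.bistd[f] = istd;
      for (int b = 0; b < B; ++b) {
        float* p = x.slice(b).colptr(f);
        for (int r = 0; r < R; ++r) p[r] = (p[r] - mean) * istd;
      }
    }
    if (training) bn.begin_training_batch();
  }

  void backward(const fcube& X, const fmat& dfeats, bool training) {
    const int B = X.n_slices, F = cfg.n_filters;
    const bool use_drop = training && cfg.dropout > 0;
    const float inv_p = 1.0f / cfg.pool_len;
    fcube dz(Tv, F, B);
    fmat s(Tv, F);
    // per-map sums for batch-norm backward accumulated over the whole batch
    std::vector<double> sd(F, 0.0), sdx(F, 0.0);
    // first pass: grad through log, pool, square down to BN output grad (ds)
    fcube ds(Tv, F, B, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      const fmat dq(const_cast<float*>(dfeats.colptr(b)), T2, F, false, true);
      for (int f = 0; f < F; ++f) {
        const float* ph = zhat.slice(b).colptr(f);
        const float g = bn.gamma[f], be = bn.beta[f];
        float* psq = s.colptr(f);
        for (int t = 0; t < Tv; ++t) psq[t] = g * ph[t] + be;  // s (pre-square)
        const float* po = pool_out.slice(b).colptr(f);
        float* pd = ds.slice(b).colptr(f);
        for (int t = 0; t < T2; ++t) {
          float gq = dq(t, f);
          if (use_drop) gq *= mask.slice(b)(t, f);
          const float dpool = po[t] > LOG_EPS ? gq / po[t] : 0.0f;
          const int t0 = t * cfg.pool_stride;
          const float gsq = dpool * inv_p;
          for (int k = 0; k < cfg.pool_len; ++k)
            pd[t0 + k] += gsq * 2.0f * psq[t0 + k];
        }
        const float* px = zhat.slice(b).colptr(f);
        const float* pdv = ds.slice(b).colptr(f);
        double a = 0, c = 0;
        for (int t = 0; t < Tv; ++t) { a += pdv[t]; c += (double)pdv[t] * px[t]; }
        sd[f] += a; sdx[f] += c;
      }
    }
    const double N = (double)Tv * B;
    for (int f = 0; f < F; ++f) { bn.gb[f] += (float)sd[f]; bn.gg[f] += (float)sdx[f]; }
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F; ++f) {
        const float g = bn.gamma[f], istd = bn.bistd[f];
        const float c1 = (float)(sd[f] / N), c2 = (float)(sdx[f] / N);
        const float* px = zhat.slice(b).colptr(f);
        const float* pdv = ds.slice(b).colptr(f);
        float* out = dz.slice(b).colptr(f);
        if (training)
          for (int t = 0; t < Tv; ++t)
            out[t] = g * istd * (pdv[t] - c1 - px[t] * c2);
        else
          for (int t = 0; t < Tv; ++t) out[t] = g * istd * pdv[t];
      }
    // spatial conv backward + temporal conv weight gradient
    fmat dy1((size_t)C * Tv, F);
    fmat xcol((size_t)C * Tv, cfg.KE);
    for (int b = 0; b < B; ++b) {
      for (int f = 0; f < F; ++f) {
        const fmat view(const_cast<float*>(y1.slice(b).colptr(f)), Tv, C, false, true);
        Wspat.g.rows((size_t)f * C, (size_t)f * C + C - 1) += view.t() * dz.slice(b);
        fmat dview = dz.slice(b) * Wspat.w.rows((size_t)f * C, (size_t)f * C + C - 1).t();
        std::memcpy(dy1.colptr(f), dview.memptr(), sizeof(float) * dview.n_elem);
      }
      im2col_valid(X.slice(b), xcol);
      W1.g += xcol.t() * dy1;
    }
  }

  void free_caches() {
    y1.reset(); zhat.reset(); pool_out.reset(); mask.reset(); feats.reset();
  }
};

// -------------------------------------------------------------------- model

struct Model {
  std::string family;           // "eegnet" or "shallow"
  int T, C, K;
  std::vector<EEGBranch> eeg;
  std::vector<ShallowBranch> shallow;
  Param Wfc, bfc;
  std::mt19937 rng;
  long adam_t = 0;

  // snapshot of weights + running stats for best-checkpoint restore
  std::vector<fmat> snap_w;
  std::vector<fvec> snap_bn;
  std::vector<long> snap_bn_steps;
  bool has_snapshot = false;

  int feat_total() const {
    int s = 0;
    for (const auto& b : eeg) s += b.feat_len();
    for (const auto& b : shallow) s += b.feat_len();
    return s;
  }

  std::vector<Param*> params() {
    std::vector<Param*> out;
    for (auto& b : eeg) { out.push_back(&b.W1); out.push_back(&b.Wd);
                          out.push_back(&b.Ws); out.push_back(&b.Wp); }
    for (auto& b : shallow) { out.push_back(&b.W1); out.push_back(&b.Wspat); }
    out.push_back(&Wfc); out.push_back(&bfc);
    return out;
  }
  std::vector<BNLayer*> bns() {
    std::vector<BNLayer*> out;
    for (auto& b : eeg) { out.push_back(&b.bn1); out.push_back(&b.bn2);
                          out.push_back(&b.bn3); }
    for (auto& b : shallow) out.push_back(&b.bn);
    return out;
  }

  void zero_grads() {
    for (auto* p : params()) p->g.zeros();
    for (auto* b : bns()) { b->gg.zeros(); b->gb.zeros(); }
  }

  // forward through all branches; returns softmax probabilities (K x B)
  fmat forward(const fcube& X, bool training) {
    const int B = X.n_slices;
    for (auto& b : eeg) b.forward(X, training, rng);
    for (auto& b : shallow) b.forward(X, training, rng);
    fmat feats(feat_total(), B);
    size_t off = 0;
    for (auto& b : eeg) {
      feats.rows(off, off + b.feat_len() - 1) = b.feats;
      off += b.feat_len();
    }
    for (auto& b : shallow) {
      feats.rows(off, off + b.feat_len() - 1) = b.feats;
      off += b.feat_len();
    }
    fmat logits = Wfc.w.t() * feats;
    logits.each_col() += bfc.w.col(0);
    // row-wise stable softmax over classes (rows = classes here)
    for (int b = 0; b < B; ++b) {
      fvec v = logits.col(b);
      v -= v.max();
      fvec e = arma::exp(v);
      logits.col(b) = e / arma::accu(e);
    }
    last_feats = feats;
    return logits;
  }
  fmat last_feats;

  void backward(const fcube& X, const fmat& probs, const arma::ivec& y, bool training) {
    const int B = X.n_slices;
    fmat dlogits = probs;
    for (int b = 0; b < B; ++b) dlogits(y[b], b) -= 1.0f;
    dlogits /= (float)B;
    Wfc.g += last_feats * dlogits.t();
    bfc.g.col(0) += arma::sum(dlogits, 1);
    fmat dfeats = Wfc.w * dlogits;
    size_t off = 0;
    for (auto& b : eeg) {
      b.backward(X, dfeats.rows(off, off + b.feat_len() - 1), training);
      off += b.feat_len();
    }
    for (auto& b : shallow) {
      b.backward(X, dfeats.rows(off, off + b.feat_len() - 1), training);
      off += b.feat_len();
    }
  }

  void adam_step(double lr) {
    adam_t++;
    const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
    const double bc1 = 1.0 - std::pow(b1, (double)adam_t);
    const double bc2 = 1.0 - std::pow(b2, (double)adam_t);
    const float a = (float)(lr * std::sqrt(bc2) / bc1);
    for (auto* p : params()) {
      p->m = 0.9f * p->m + 0.1f * p->g;
      p->v = 0.999f * p->v + 0.001f * arma::square(p->g);
      p->w -= a * p->m / (arma::sqrt(p->v) + (float)(eps * std::sqrt(bc2)));
    }
    for (auto* b : bns()) {
      b->mg = 0.9f * b->mg + 0.1f * b->gg;
      b->vg = 0.999f * b->vg + 0.001f * arma::square(b->gg);
      b->gamma -= a * b->mg / (arma::sqrt(b->vg) + (float)(eps * std::sqrt(bc2)));
      b->mb = 0.9f * b->mb + 0.1f * b->gb;
      b->vb = 0.999f * b->vb + 0.001f * arma::square(b->gb);
      b->beta -= a * b->mb / (arma::sqrt(b->vb) + (float)(eps * std::sqrt(bc2)));
    }
  }

  void sgd_step(double lr) {
    for (auto* p : params()) p->w -= (float)lr * p->g;
    for (auto* b : bns()) {
      b->gamma -= (float)lr * b->gg;
      b->beta -= (float)lr * b->gb;
    }
  }

  void snapshot() {
    snap_w.clear(); snap_bn.clear(); snap_bn_steps.clear();
    for (auto* p : params()) snap_w.push_back(p->w);
    for (auto* b : bns()) {
      snap_bn.push_back(b->gamma); snap_bn.push_back(b->beta);
      snap_bn.push_back(b->rmean); snap_bn.push_back(b->rvar);
      snap_bn_steps.push_back(b->steps);
    }
    has_snapshot = true;
  }
  void restore() {
    if (!has_snapshot) Rcpp::stop("no snapshot saved");
    size_t i = 0, j = 0;
    for (auto* p : params()) p->w = snap_w[i++];
    i = 0;
    for (auto* b : bns()) {
      b->gamma = snap_bn[i++]; b->beta = snap_bn[i++];
      b->rmean = snap_bn[i++]; b->rvar = snap_bn[i++];
      b->steps = snap_bn_steps[j++];
    }
  }

  void free_caches() {
    for (auto& b : eeg) b.free_caches();
    for (auto& b : shallow) b.free_caches();
    last_feats.reset();
  }
};

struct Dataset {
  fcube X;        // (T, C, N)
  arma::ivec y;   // 0-based labels
};

// ------------------------------------------------------------- R interface

static EEGBranchCfg eeg_cfg_from_list(const Rcpp::List& l) {
  EEGBranchCfg c;
  c.F1 = Rcpp::as<int>(l["n_temporal_filters"]);
  c.KE = Rcpp::as<int>(l["kernel_length"]);
  c.D = Rcpp::as<int>(l["depth_multiplier"]);
  c.F2 = Rcpp::as<int>(l["pointwise_filters"]);
  c.sep_len = Rcpp::as<int>(l["separable_kernel_length"]);
  Rcpp::IntegerVector pools = l["pool_lengths"];
  c.pool1 = pools[0]; c.pool2 = pools[1];
  c.dropout = Rcpp::as<double>(l["dropout_rate"]);
  return c;
}

static ShallowBranchCfg shallow_cfg_from_list(const Rcpp::List& l) {
  ShallowBranchCfg c;
  c.n_filters = Rcpp::as<int>(l["n_filters"]);
  c.KE = Rcpp::as<int>(l["kernel_length"]);
  c.pool_len = Rcpp::as<int>(l["pool_length"]);
  c.pool_stride = Rcpp::as<int>(l["pool_stride"]);
  c.dropout = Rcpp::as<double>(l["dropout_rate"]);
  return c;
}

// [[Rcpp::export]]
SEXP cpp_model_new(Rcpp::List spec, int seed) {
  Rcpp::XPtr<Model> ptr(new Model(), true);
  Model& m = *ptr;
  m.family = Rcpp::as<std::string>(spec["family"]);
  m.C = Rcpp::as<int>(spec["n_channels"]);
  m.T = Rcpp::as<int>(spec["n_samples"]);
  m.K = Rcpp::as<int>(spec["n_classes"]);
  m.rng.seed((unsigned)seed);
  Rcpp::List branches = spec["branches"];
  for (int i = 0; i < branches.size(); ++i) {
    std::string tag = "branch" + std::to_string(i + 1);
    if (m.family == "eegnet") {
      EEGBranch b;
      b.configure(eeg_cfg_from_list(branches[i]), m.T, m.C, tag, m.rng);
      m.eeg.push_back(std::move(b));
    } else {
      ShallowBranch b;
      b.configure(shallow_cfg_from_list(branches[i]), m.T, m.C, tag, m.rng);
      m.shallow.push_back(std::move(b));
    }
  }
  const int ftot = m.feat_total();
  m.Wfc.init("dense", ftot, m.K);
  m.Wfc.glorot(m.rng, ftot, m.K);
  m.bfc.init("dense_bias", m.K, 1);
  m.bfc.w.zeros();
  return ptr;
}

// [[Rcpp::export]]
SEXP cpp_data_new(Rcpp::NumericVector arr, Rcpp::IntegerVector labels) {
  Rcpp::IntegerVector dims = arr.attr("dim");
  const int n = dims[0], C = dims[1], T = dims[2];
  Rcpp::XPtr<Dataset> ptr(new Dataset(), true);
  ptr->X.set_size(T, C, n);
  const double* src = arr.begin();
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < C; ++c) {
      const double* col = src + (size_t)n * c + (size_t)n * C * t;
      for (int i = 0; i < n; ++i)
        ptr->X(t, c, i) = (float)col[i];
    }
  ptr->y.set_size(n);
  for (int i = 0; i < n; ++i) ptr->y[i] = labels[i];
  return ptr;
}

// enumeration of every trainable tensor: the brute-force audit oracle
// [[Rcpp::export]]
Rcpp::DataFrame cpp_param_entries(SEXP model_ptr) {
  Rcpp::XPtr<Model> m(model_ptr);
  std::vector<std::string> names, shapes;
  std::vector<int> counts;
  auto add = [&](const std::string& nm, size_t r, size_t c) {
    names.push_back(nm);
    shapes.push_back(c == 1 ? std::to_string(r)
                            : std::to_string(r) + "x" + std::to_string(c));
    counts.push_back((int)(r * c));
  };
  for (auto* p : m->params()) add(p->name, p->w.n_rows, p->w.n_cols);
  for (auto* b : m->bns()) {
    add(b->name + "_scale", b->gamma.n_elem, 1);
    add(b->name + "_shift", b->beta.n_elem, 1);
  }
  return Rcpp::DataFrame::create(Rcpp::Named("tensor") = names,
                                 Rcpp::Named("shape") = shapes,
                                 Rcpp::Named("count") = counts,
                                 Rcpp::Named("stringsAsFactors") = false);
}

// [[Rcpp::export]]
Rcpp::List cpp_train_epoch(SEXP model_ptr, SEXP data_ptr, int batch_size,
                           double lr, std::string optimizer) {
  Rcpp::XPtr<Model> m(model_ptr);
  Rcpp::XPtr<Dataset> d(data_ptr);
  const int N = d->X.n_slices;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  std::shuffle(idx.begin(), idx.end(), m->rng);
  double loss_sum = 0;
  int correct = 0;
  for (int start = 0; start < N; start += batch_size) {
    const int nb = std::min(batch_size, N - start);
    fcube X(m->T, m->C, nb);
    arma::ivec y(nb);
    for (int j = 0; j < nb; ++j) {
      X.slice(j) = d->X.slice(idx[start + j]);
      y[j] = d->y[idx[start + j]];
    }
    m->zero_grads();
    fmat probs = m->forward(X, true);
    for (int j = 0; j < nb; ++j) {
      const float p = std::max(probs(y[j], j), 1e-12f);
      loss_sum += -std::log((double)p);
      arma::uword am;
      probs.col(j).max(am);
      if ((int)am == y[j]) correct++;
    }
    m->backward(X, probs, y, true);
    if (optimizer == "adam") m->adam_step(lr); else m->sgd_step(lr);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss_sum / N,
                            Rcpp::Named("accuracy") = (double)correct / N);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_predict(SEXP model_ptr, SEXP data_ptr, int batch_size = 64) {
  Rcpp::XPtr<Model> m(model_ptr);
  Rcpp::XPtr<Dataset> d(data_ptr);
  const int N = d->X.n_slices;
  Rcpp::NumericMatrix out(N, m->K);
  for (int start = 0; start < N; start += batch_size) {
    const int nb = std::min(batch_size, N - start);
    fcube X(m->T, m->C, nb);
    for (int j = 0; j < nb; ++j) X.slice(j) = d->X.slice(start + j);
    fmat probs = m->forward(X, false);
    for (int j = 0; j < nb; ++j)
      for (int k = 0; k < m->K; ++k)
        out(start + j, k) = probs(k, j);
  }
  m->free_caches();
  return out;
}

// [[Rcpp::export]]
void cpp_reseed(SEXP model_ptr, int seed) {
  Rcpp::XPtr<Model>(model_ptr)->rng.seed((unsigned)seed);
}

// [[Rcpp::export]]
void cpp_snapshot(SEXP model_ptr) { Rcpp::XPtr<Model>(model_ptr)->snapshot(); }

// [[Rcpp::export]]
void cpp_restore(SEXP model_ptr) { Rcpp::XPtr<Model>(model_ptr)->restore(); }

// [[Rcpp::export]]
void cpp_free_caches(SEXP model_ptr) { Rcpp::XPtr<Model>(model_ptr)->free_caches(); }

// [[Rcpp::export]]
Rcpp::List cpp_get_weights(SEXP model_ptr) {
  Rcpp::XPtr<Model> m(model_ptr);
  Rcpp::List out;
  for (auto* p : m->params()) {
    Rcpp::NumericMatrix w(p->w.n_rows, p->w.n_cols);
    for (arma::uword i = 0; i < p->w.n_elem; ++i) w[i] = p->w[i];
    out[p->name] = w;
  }
  for (auto* b : m->bns()) {
    out[b->name + "_scale"] = Rcpp::NumericVector(b->gamma.begin(), b->gamma.end());
    out[b->name + "_shift"] = Rcpp::NumericVector(b->beta.begin(), b->beta.end());
    Rcpp::NumericVector rm(b->rmean.n_elem), rv(b->rvar.n_elem);
    for (arma::uword i = 0; i < b->rmean.n_elem; ++i) {
      rm[i] = b->infer_mean((int)i);
      if (b->steps < 0) rv[i] = b->rvar[i];
      else rv[i] = b->steps > 0 ? std::max(b->rvar[i] / b->corr(), 0.0f) : 1.0f;
    }
    out[b->name + "_running_mean"] = rm;
    out[b->name + "_running_var"] = rv;
  }
  return out;
}

// [[Rcpp::export]]
void cpp_set_weights(SEXP model_ptr, Rcpp::List weights) {
  Rcpp::XPtr<Model> m(model_ptr);
  for (auto* p : m->params()) {
    if (!weights.containsElementNamed(p->name.c_str())) continue;
    Rcpp::NumericMatrix w = weights[p->name];
    if ((arma::uword)w.nrow() != p->w.n_rows || (arma::uword)w.ncol() != p->w.n_cols)
      Rcpp::stop("weight shape mismatch for tensor '%s'", p->name);
    for (arma::uword i = 0; i < p->w.n_elem; ++i) p->w[i] = (float)w[i];
  }
  for (auto* b : m->bns()) {
    auto set_vec = [&](const std::string& nm, fvec& dst) {
      if (!weights.containsElementNamed(nm.c_str())) return;
      Rcpp::NumericVector v = weights[nm];
      if ((arma::uword)v.size() != dst.n_elem)
        Rcpp::stop("weight shape mismatch for tensor '%s'", nm);
      for (arma::uword i = 0; i < dst.n_elem; ++i) dst[i] = (float)v[i];
    };
    set_vec(b->name + "_scale", b->gamma);
    set_vec(b->name + "_shift", b->beta);
    // running stats are supplied already debiased: store with a converged
    // correction factor so inference uses them verbatim
    if (weights.containsElementNamed((b->name + "_running_mean").c_str())) {
      fvec rm(b->rmean.n_elem), rv(b->rvar.n_elem);
      set_vec(b->name + "_running_mean", rm);
      set_vec(b->name + "_running_var", rv);
      b->rmean = rm; b->rvar = rv;
      b->steps = -1;  // explicit statistics: use verbatim at inference
    }
  }
}
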