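// Fast single-precision training engine for the convolutional MPRA model.
//
// The R side owns the canonical (double) parameters and all inference and
// attribution paths; this engine holds a float32 mirror for the training
// loop only, where single precision is ample and roughly doubles GEMM
// throughput on one core.  Sequences are passed once as base codes
// (0=A,1=C,2=G,3=T,4=N) and one-hot expanded per batch in C.  Dropout and
// shuffling draw from R's RNG, so runs are reproducible under set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct ConvLayer {
  fmat W;  fvec b;      // W: filters x (C_in * k)
  int k, C_in, filters;
  fmat mW, vW; fvec mb, vb;           // Adam state
};
struct BNLayer {
  fvec gamma, beta, run_mean, run_var;
  float eps, momentum;
  fvec mg, vg, mb, vb;
};
struct DenseLayer {
  fmat W; fvec b;
  fmat mW, vW; fvec mb, vb;
};

struct Engine {
  int L, n_tasks, n_conv;
  bool batchnorm;
  float p_dropout;
  std::vector<ConvLayer> conv;
  std::vector<BNLayer> bn;
  DenseLayer dense;
  // Polyak (exponential moving) averages of the trainable parameters;
  // validation and the returned model use these for a smoother optimum.
  std::vector<fmat> ema_cW; std::vector<fvec> ema_cb;
  std::vector<fvec> ema_g, ema_be;
  fmat ema_dW; fvec ema_db;
  float ema_decay = 0.998f;
  long step = 0;
};

static void onehot_batch(const RawVector &codes, int L,
                         const std::vector<int> &idx, fmat &X) {
  // X: (4*L) x B, column-major; zero then set
  X.zeros();
  for (size_t b = 0; b < idx.size(); ++b) {
    const Rbyte *src = &codes[(R_xlen_t)idx[b] * L];
    float *col = X.colptr(b);
    for (int p = 0; p < L; ++p) {
      if (src[p] < 4) col[p * 4 + src[p]] = 1.0f;
    }
  }
}

// im2col on a channel-fastest (C, P_in) x B activation held as (C*P_in) x B
static void im2col_f(const fmat &Z, int C, int Lin, int k, fmat &out) {
  const int P = Lin - k + 1;
  const int B = Z.n_cols;
  // out: (C*k) x (P*B)
  for (int b = 0; b < B; ++b) {
    const float *zb = Z.colptr(b);
    for (int p = 0; p < P; ++p) {
      float *dst = out.colptr((size_t)b * P + p);
      std::memcpy(dst, zb + (size_t)p * C, (size_t)C * k * sizeof(float));
    }
  }
}

static void col2im_f(const fmat &dXcol, int C, int Lin, int k, fmat &dZ) {
  const int P = Lin - k + 1;
  const int B = dZ.n_cols;
  dZ.zeros();
  const size_t collen = (size_t)C * k;
  for (int b = 0; b < B; ++b) {
    float *zb = dZ.colptr(b);
    for (int p = 0; p < P; ++p) {
      const float *src = dXcol.colptr((size_t)b * P + p);
      float *dst = zb + (size_t)p * C;
      for (size_t j = 0; j < collen; ++j) dst[j] += src[j];
    }
  }
}

static void adam_update(fmat &w, fmat &m, fmat &v, const fmat &g,
                        float lr, float c1, float c2, float eps) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * (g % g);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}
static void adam_update_v(fvec &w, fvec &m, fvec &v, const fvec &g,
                          float lr, float c1, float c2, float eps) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * (g % g);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}

// [[Rcpp::export]]
SEXP engine_create(List spec, List conv_W, List conv_b, List bn_par,
                   NumericMatrix dense_W, NumericVector dense_b) {
  Engine *e = new Engine();
  e->L = as<int>(spec["fragment_length"]);
  e->n_tasks = as<int>(spec["n_tasks"]);
  e->n_conv = as<int>(spec["n_conv_layers"]);
  e->batchnorm = as<bool>(spec["batchnorm"]);
  e->p_dropout = as<double>(spec["p_dropout"]);
  int C = 4;
  for (int i = 0; i < e->n_conv; ++i) {
    ConvLayer cl;
    NumericMatrix W = conv_W[i];
    cl.W = arma::conv_to<fmat>::from(as<arma::mat>(W));
    cl.b = arma::conv_to<fvec>::from(as<arma::vec>(conv_b[i]));
    cl.filters = cl.W.n_rows;
    cl.k = as<int>(spec["filter_length"]);
    cl.C_in = C;
    cl.mW.zeros(cl.W.n_rows, cl.W.n_cols); cl.vW.zeros(cl.W.n_rows, cl.W.n_cols);
    cl.mb.zeros(cl.b.n_elem); cl.vb.zeros(cl.b.n_elem);
    e->conv.push_back(cl);
    if (e->batchnorm) {
      List bp = bn_par[i];
      BNLayer bl;
      bl.gamma = arma::conv_to<fvec>::from(as<arma::vec>(bp["gamma"]));
      bl.beta = arma::conv_to<fvec>::from(as<arma::vec>(bp["beta"]));
      bl.run_mean = arma::conv_to<fvec>::from(as<arma::vec>(bp["run_mean"]));
      bl.run_var = arma::conv_to<fvec>::from(as<arma::vec>(bp["run_var"]));
      bl.eps = as<double>(bp["eps"]);
      bl.momentum = as<double>(bp["momentum"]);
      bl.mg.zeros(bl.gamma.n_elem); bl.vg.zeros(bl.gamma.n_elem);
      bl.mb.zeros(bl.beta.n_elem); bl.vb.zeros(bl.beta.n_elem);
      e->bn.push_back(bl);
    }
    C = cl.filters;
  }
  e->dense.W = arma::conv_to<fmat>::from(as<arma::mat>(dense_W));
  e->dense.b = arma::conv_to<fvec>::from(as<arma::vec>(dense_b));
  e->dense.mW.zeros(e->dense.W.n_rows, e->dense.W.n_cols);
  e->dense.vW.zeros(e->dense.W.n_rows, e->dense.W.n_cols);
  e->dense.mb.zeros(e->dense.b.n_elem); e->dense.vb.zeros(e->dense.b.n_elem);
  for (int i = 0; i < e->n_conv; ++i) {
    e->ema_cW.push_back(e->conv[i].W);
    e->ema_cb.push_back(e->conv[i].b);
    if (e->batchnorm) {
      e->ema_g.push_back(e->bn[i].gamma);
      e->ema_be.push_back(e->bn[i].beta);
    }
  }
  e->ema_dW = e->dense.W;
  e->ema_db = e->dense.b;
  XPtr<Engine> ptr(e, true);
  return ptr;
}

static void ema_blend(Engine *e) {
  // warm-up schedule so the average tracks the weights closely at first
  const float d = std::min(e->ema_decay,
                           (float)e->step / (float)(e->step + 1));
  const float o = 1.0f - d;
  for (int i = 0; i < e->n_conv; ++i) {
    e->ema_cW[i] = d * e->ema_cW[i] + o * e->conv[i].W;
    e->ema_cb[i] = d * e->ema_cb[i] + o * e->conv[i].b;
    if (e->batchnorm) {
      e->ema_g[i] = d * e->ema_g[i] + o * e->bn[i].gamma;
      e->ema_be[i] = d * e->ema_be[i] + o * e->bn[i].beta;
    }
  }
  e->ema_dW = d * e->ema_dW + o * e->dense.W;
  e->ema_db = d * e->ema_db + o * e->dense.b;
}

// One epoch of minibatch Adam on MSE.  order is a 0-based permutation of
// the training examples; returns the mean training loss.
// [[Rcpp::export]]
double engine_train_epoch(SEXP eptr, RawVector codes, NumericMatrix Y,
                          IntegerVector order, int batch_size, double lr,
                          double weight_decay = 0.0,
                          double clip_norm = 5.0) {
  XPtr<Engine> e(eptr);
  const int L = e->L;
  const int n = order.size();
  const int T = e->n_tasks;
  const int nc = e->n_conv;
  fmat Yf = arma::conv_to<fmat>::from(as<arma::mat>(Y));  // T x N(total)
  double total_loss = 0.0;

  std::vector<fmat> act(nc + 1), xcol(nc), bn_y(nc), bn_istd(nc), rd_g(nc);
  std::vector<int> Lv(nc + 1);
  Lv[0] = L;
  for (int i = 0; i < nc; ++i) Lv[i + 1] = Lv[i] - e->conv[i].k + 1;

  const float p = e->p_dropout;
  const float scale = p > 0 ? 1.0f / (1.0f - p) : 1.0f;
  const double il1p = p > 0 ? 1.0 / std::log1p(-(double)p) : 0.0;

  for (int s = 0; s < n; s += batch_size) {
    const int B = std::min(batch_size, n - s);
    std::vector<int> idx(B);
    for (int b = 0; b < B; ++b) idx[b] = order[s + b];

    // ---- forward ----
    fmat X((size_t)4 * L, B);
    onehot_batch(codes, L, idx, X);
    fmat cur = X;
    int C = 4;
    for (int i = 0; i < nc; ++i) {
      ConvLayer &cl = e->conv[i];
      const int P = Lv[i + 1];
      xcol[i].set_size((size_t)C * cl.k, (size_t)P * B);
      im2col_f(cur, C, Lv[i], cl.k, xcol[i]);
      fmat O = cl.W * xcol[i];
      O.each_col() += cl.b;                     // filters x (P*B)
      if (e->batchnorm) {
        BNLayer &bl = e->bn[i];
        fvec mu = arma::mean(O, 1);
        fvec var = arma::mean(O % O, 1) - mu % mu;
        bl.run_mean = bl.momentum * bl.run_mean + (1 - bl.momentum) * mu;
        bl.run_var = bl.momentum * bl.run_var + (1 - bl.momentum) * var;
        fvec istd = 1.0f / arma::sqrt(var + bl.eps);
        O.each_col() -= mu;
        O.each_col() %= istd;
        bn_istd[i] = istd;
        O.each_col() %= bl.gamma;
        O.each_col() += bl.beta;
        bn_y[i] = O;                            // y (xhat recoverable)
      }
      // fused relu + dropout; g holds the local gradient
      rd_g[i].set_size(O.n_rows, O.n_cols);
      {
        float *op = O.memptr(); float *gp = rd_g[i].memptr();
        const size_t tot = O.n_elem;
        for (size_t j = 0; j < tot; ++j) {
          float gi = op[j] > 0 ? scale : 0.0f;
          gp[j] = p > 0 ? gi : (op[j] > 0 ? 1.0f : 0.0f);
        }
        if (p > 0) {
          size_t j = (size_t)std::floor(std::log(unif_rand()) * il1p);
          while (j < tot) {
            gp[j] = 0.0f;
            j += 1 + (size_t)std::floor(std::log(unif_rand()) * il1p);
          }
        }
        for (size_t j = 0; j < tot; ++j) op[j] *= gp[j];
      }
      // reshape filters x (P*B) -> (filters*P) x B
      O.reshape((size_t)cl.filters * P, B);
      act[i + 1] = O;
      cur = act[i + 1];
      C = cl.filters;
    }
    fmat out = e->dense.W * cur;                // T x B
    out.each_col() += e->dense.b;

    fmat Yb(T, B);
    for (int b = 0; b < B; ++b) Yb.col(b) = Yf.col(idx[b]);
    fmat resid = out - Yb;
    const double loss = arma::accu(arma::square(resid)) / resid.n_elem;
    if (!std::isfinite(loss))
      stop("non-finite training loss (float engine)");
    total_loss += loss * B;

    // ---- backward (gradients buffered for global-norm clipping) ----
    const float c1 = 1.0f - std::pow(0.9f, (float)(e->step + 1));
    const float c2 = 1.0f - std::pow(0.999f, (float)(e->step + 1));
    e->step += 1;
    const float lrf = lr;
    fmat dOut = resid * (2.0f / resid.n_elem);
    fmat dW_dense = dOut * cur.t();
    fvec db_dense = arma::sum(dOut, 1);
    fmat dcur = e->dense.W.t() * dOut;          // (filters*P) x B
    double gss = arma::accu(arma::square(dW_dense)) +
                 arma::accu(arma::square(db_dense));
    std::vector<fmat> g_cW(nc); std::vector<fvec> g_cb(nc);
    std::vector<fvec> g_gamma(nc), g_beta(nc);

    for (int i = nc - 1; i >= 0; --i) {
      ConvLayer &cl = e->conv[i];
      const int P = Lv[i + 1];
      fmat dO = dcur;
      dO.reshape(cl.filters, (size_t)P * B);
      dO %= rd_g[i];                            // relu+dropout backward
      if (e->batchnorm) {
        BNLayer &bl = e->bn[i];
        const float m = (float)dO.n_cols;
        fmat xhat = bn_y[i];
        xhat.each_col() -= bl.beta;
        for (arma::uword r = 0; r < xhat.n_rows; ++r) {
          float g = bl.gamma(r) == 0.0f ? 1e-12f : bl.gamma(r);
          xhat.row(r) /= g;
        }
        fvec dgamma = arma::sum(dO % xhat, 1);
        fvec dbeta = arma::sum(dO, 1);
        fmat dX = m * dO;
        dX.each_col() -= dbeta;
        dX -= xhat.each_col() % dgamma;
        fvec sc = (bl.gamma % bn_istd[i]) / m;
        dX.each_col() %= sc;
        g_gamma[i] = dgamma; g_beta[i] = dbeta;
        gss += arma::accu(arma::square(dgamma)) +
               arma::accu(arma::square(dbeta));
        dO = dX;
      }
      g_cW[i] = dO * xcol[i].t();
      g_cb[i] = arma::sum(dO, 1);
      gss += arma::accu(arma::square(g_cW[i])) +
             arma::accu(arma::square(g_cb[i]));
      if (i > 0) {
        fmat dXcol = cl.W.t() * dO;             // (C_in*k) x (P*B)
        fmat dZ((size_t)cl.C_in * Lv[i], B);
        col2im_f(dXcol, cl.C_in, Lv[i], cl.k, dZ);
        dcur = dZ;                              // already (C*L) x B layout
      }
    }

    // global-norm clip, then apply all updates
    float gscale = 1.0f;
    if (clip_norm > 0) {
      double gnorm = std::sqrt(gss);
      if (gnorm > clip_norm) gscale = (float)(clip_norm / gnorm);
    }
    if (gscale != 1.0f) {
      dW_dense *= gscale; db_dense *= gscale;
      for (int i = 0; i < nc; ++i) {
        g_cW[i] *= gscale; g_cb[i] *= gscale;
        if (e->batchnorm) { g_gamma[i] *= gscale; g_beta[i] *= gscale; }
      }
    }
    adam_update(e->dense.W, e->dense.mW, e->dense.vW, dW_dense,
                lrf, c1, c2, 1e-8f);
    if (weight_decay > 0) e->dense.W *= (1.0f - lrf * (float)weight_decay);
    adam_update_v(e->dense.b, e->dense.mb, e->dense.vb, db_dense,
                  lrf, c1, c2, 1e-8f);
    for (int i = 0; i < nc; ++i) {
      ConvLayer &cl = e->conv[i];
      adam_update(cl.W, cl.mW, cl.vW, g_cW[i], lrf, c1, c2, 1e-8f);
      // no decay on pre-batchnorm weights: BN cancels their scale and
      // shrinking them only degrades the normalization numerics
      adam_update_v(cl.b, cl.mb, cl.vb, g_cb[i], lrf, c1, c2, 1e-8f);
      if (e->batchnorm) {
        BNLayer &bl = e->bn[i];
        adam_update_v(bl.gamma, bl.mg, bl.vg, g_gamma[i], lrf, c1, c2, 1e-8f);
        adam_update_v(bl.beta, bl.mb, bl.vb, g_beta[i], lrf, c1, c2, 1e-8f);
      }
    }
    ema_blend(e);
  }
  return total_loss / n;
}

// Reset batchnorm running statistics to the exact moments of a calibration
// batch (dropout off).
// [[Rcpp::export]]
void engine_recalibrate(SEXP eptr, RawVector codes, IntegerVector idx0) {
  XPtr<Engine> e(eptr);
  if (!e->batchnorm) return;
  const int L = e->L;
  const int B = idx0.size();
  std::vector<int> idx(B);
  for (int b = 0; b < B; ++b) idx[b] = idx0[b];
  fmat X((size_t)4 * L, B);
  onehot_batch(codes, L, idx, X);
  fmat cur = X;
  int C = 4, Lin = L;
  for (int i = 0; i < e->n_conv; ++i) {
    ConvLayer &cl = e->conv[i];
    const int P = Lin - cl.k + 1;
    fmat xcol((size_t)C * cl.k, (size_t)P * B);
    im2col_f(cur, C, Lin, cl.k, xcol);
    fmat O = cl.W * xcol;
    O.each_col() += cl.b;
    BNLayer &bl = e->bn[i];
    fvec mu = arma::mean(O, 1);
    fvec var = arma::mean(O % O, 1) - mu % mu;
    bl.run_mean = mu;
    bl.run_var = var;
    fvec istd = 1.0f / arma::sqrt(var + bl.eps);
    O.each_col() -= mu;
    O.each_col() %= istd;
    O.each_col() %= bl.gamma;
    O.each_col() += bl.beta;
    O.transform([](float x) { return x > 0 ? x : 0.0f; });
    O.reshape((size_t)cl.filters * P, B);
    cur = O;
    C = cl.filters;
    Lin = P;
  }
}

// Extract the current (or Polyak-averaged) parameters as double-precision
// R objects.  Batchnorm running statistics are returned as held; callers
// should recalibrate them against the extracted weights.
// [[Rcpp::export]]
List engine_params(SEXP eptr, bool use_ema = false) {
  XPtr<Engine> e(eptr);
  List conv_W(e->n_conv), conv_b(e->n_conv), bn(e->n_conv);
  for (int i = 0; i < e->n_conv; ++i) {
    const fmat &W = use_ema ? e->ema_cW[i] : e->conv[i].W;
    const fvec &b = use_ema ? e->ema_cb[i] : e->conv[i].b;
    conv_W[i] = wrap(arma::conv_to<arma::mat>::from(W));
    conv_b[i] = wrap(arma::conv_to<arma::vec>::from(b));
    if (e->batchnorm) {
      const fvec &g = use_ema ? e->ema_g[i] : e->bn[i].gamma;
      const fvec &be = use_ema ? e->ema_be[i] : e->bn[i].beta;
      bn[i] = List::create(
        _["gamma"] = wrap(arma::conv_to<arma::vec>::from(g)),
        _["beta"] = wrap(arma::conv_to<arma::vec>::from(be)),
        _["run_mean"] = wrap(arma::conv_to<arma::vec>::from(e->bn[i].run_mean)),
        _["run_var"] = wrap(arma::conv_to<arma::vec>::from(e->bn[i].run_var)));
    }
  }
  const fmat &dW = use_ema ? e->ema_dW : e->dense.W;
  const fvec &db = use_ema ? e->ema_db : e->dense.b;
  return List::create(_["conv_W"] = conv_W, _["conv_b"] = conv_b,
                      _["bn"] = bn,
                      _["dense_W"] = wrap(arma::conv_to<arma::mat>::from(dW)),
                      _["dense_b"] = wrap(arma::conv_to<arma::vec>::from(db)));
}
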