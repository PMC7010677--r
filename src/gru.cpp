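// GRU stack core: double-precision inference, and a persistent
// single-precision trainer (fused BPTT + ADAM) for the model fit.
//
// One "path" is a stack of L unidirectional GRU layers followed by an
// affine (linear) head mapping the top hidden state to a scalar per
// timestep.  The bidirectional model runs two fully independent paths,
// the second on the time-reversed input; that orchestration lives in R.
//
// Gate equations per cell (logistic sigmoid gates, configurable
// candidate activation):
//   r  = sigmoid(Ur x + Wr h_prev + br)
//   z  = sigmoid(Uz x + Wz h_prev + bz)
//   hc = act(U x + W (r .* h_prev) + bh)
//   h  = (1 - z) .* h_prev + z .* hc
//
// Layout: a window batch is a T x B matrix (time down the rows).  All
// per-timestep quantities live in H x (T*B) matrices whose column block
// t*B .. t*B+B-1 holds timestep t; input-side projections and
// weight-gradient accumulations then collapse into single large GEMMs
// (the three gates stacked into one 3H-row operand), and only the
// hidden-to-hidden recurrence is sequential in t.  Per-timestep
// elementwise updates are fused pointer loops writing straight into
// preallocated caches.
//
// The trainer keeps weights, ADAM state and workspaces alive across
// minibatches behind an external pointer, evaluating in single
// precision: ample for stochastic-gradient training and roughly twice
// the arithmetic/memory throughput of double.  Inference
// (cpp_path_forward) and the gradient checker (cpp_path_grad) run in
// double precision.

#include <RcppArmadillo.h>
#include <cmath>
#include <vector>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#define TREMORNET_HAVE_MXCSR 1
#endif
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::fmat;
using arma::fvec;

namespace {

const int ACT_RELU = 0;
const int ACT_TANH = 1;

template <typename eT>
inline eT sigmoid1(eT a) { return eT(1) / (eT(1) + std::exp(-a)); }

template <typename eT>
inline eT act1(eT a, int act) {
  return (act == ACT_RELU) ? (a > eT(0) ? a : eT(0)) : std::tanh(a);
}

// X (T x B) -> column-blocked 1 x (T*B)
template <typename eT>
arma::Mat<eT> row_blocked(const arma::Mat<eT>& X) {
  arma::Mat<eT> Xt = X.t();  // B x T
  return arma::reshape(Xt, 1, Xt.n_elem);
}

template <typename eT>
arma::Mat<eT> blocked_to_TB(const arma::Mat<eT>& yrow, int T, int B) {
  arma::Mat<eT> Y = arma::reshape(yrow, B, T);
  return arma::Mat<eT>(Y.t());
}

// ---------------------------------------------------------------------------
// Double-precision reference path (inference and gradient checks), with
// weights in the user-facing unstacked naming (Ur, Wr, Uz, Wz, U, W).
// ---------------------------------------------------------------------------

struct LayerW {
  mat Ur, Wr, Uz, Wz, U, W;
  vec br, bz, bh;
};

LayerW unpack_layer(const List& lay) {
  LayerW w;
  w.Ur = as<mat>(lay["Ur"]); w.Wr = as<mat>(lay["Wr"]);
  w.Uz = as<mat>(lay["Uz"]); w.Wz = as<mat>(lay["Wz"]);
  w.U  = as<mat>(lay["U"]);  w.W  = as<mat>(lay["W"]);
  w.br = as<vec>(lay["br"]); w.bz = as<vec>(lay["bz"]);
  w.bh = as<vec>(lay["bh"]);
  return w;
}

struct LayerCache {
  mat Hseq;       // H x (T+1)*B, block 0 is the initial state
  mat R, Z, HC;   // H x T*B
};

LayerCache run_layer_d(const mat& Xmat, const LayerW& w, const mat& h0,
                       int T, int B, int act) {
  const int H = w.W.n_rows;
  const int n = H * B;
  LayerCache c;
  c.Hseq.set_size(H, (T + 1) * B);
  c.R.set_size(H, T * B);
  c.Z.set_size(H, T * B);
  c.HC.set_size(H, T * B);

  mat Gr = w.Ur * Xmat; Gr.each_col() += w.br;
  mat Gz = w.Uz * Xmat; Gz.each_col() += w.bz;
  mat Gc = w.U  * Xmat; Gc.each_col() += w.bh;
  mat Wrz = arma::join_cols(w.Wr, w.Wz);
  mat arz(2 * H, B), rh(H, B), wrh(H, B);

  c.Hseq.cols(0, B - 1) = h0;
  for (int t = 0; t < T; ++t) {
    const int c0 = t * B;
    const double* ph = c.Hseq.colptr(c0);
    arz = Wrz * c.Hseq.cols(c0, c0 + B - 1);
    double* pr = c.R.colptr(c0);
    double* pz = c.Z.colptr(c0);
    double* prh = rh.memptr();
    const double* pgr = Gr.colptr(c0);
    const double* pgz = Gz.colptr(c0);
    for (int j = 0; j < B; ++j) {
      const double* pa = arz.colptr(j);
      const int o = j * H;
      for (int i = 0; i < H; ++i) {
        const double r = sigmoid1(pgr[o + i] + pa[i]);
        const double z = sigmoid1(pgz[o + i] + pa[H + i]);
        pr[o + i] = r; pz[o + i] = z; prh[o + i] = r * ph[o + i];
      }
    }
    wrh = w.W * rh;
    double* phc = c.HC.colptr(c0);
    double* phn = c.Hseq.colptr(c0 + B);
    const double* pgc = Gc.colptr(c0);
    const double* pw = wrh.memptr();
    for (int i = 0; i < n; ++i) {
      const double hc = act1(pgc[i] + pw[i], act);
      phc[i] = hc;
      phn[i] = (1.0 - pz[i]) * ph[i] + pz[i] * hc;
    }
  }
  return c;
}

}  // namespace

// [[Rcpp::depends(RcppArmadillo)]]

// Forward pass of one path in double precision.  X: T x B.  h0: H x
// (B*L) initial hidden states (empty matrix means zeros).  Returns the
// per-timestep scalar outputs (T x B) and the final hidden state of
// every layer (for streaming use); optionally the full hidden sequence
// of every layer (H x T*B, column-blocked by timestep).
// [[Rcpp::export]]
List cpp_path_forward(const arma::mat& X, const List& layers,
                      const arma::vec& V, double cbias,
                      const arma::mat& h0, int act,
                      bool return_hidden_seq = false) {
  const int T = X.n_rows, B = X.n_cols, L = layers.size();
  List hseqs(L);
  arma::mat Hfinal;
  arma::mat cur = row_blocked<double>(X);
  for (int l = 0; l < L; ++l) {
    LayerW w = unpack_layer(layers[l]);
    const int H = w.W.n_rows;
    arma::mat h0l = h0.is_empty()
        ? arma::mat(H, B, arma::fill::zeros)
        : arma::mat(h0.cols(l * B, l * B + B - 1));
    LayerCache c = run_layer_d(cur, w, h0l, T, B, act);
    cur = c.Hseq.cols(B, (T + 1) * B - 1);  // outputs, blocks 1..T
    if (Hfinal.is_empty()) Hfinal.set_size(H, B * L);
    Hfinal.cols(l * B, l * B + B - 1) = c.Hseq.cols(T * B, (T + 1) * B - 1);
    if (return_hidden_seq) hseqs[l] = cur;
  }
  arma::mat yrow = V.t() * cur;
  yrow += cbias;
  List out = List::create(_["y"] = blocked_to_TB<double>(yrow, T, B),
                          _["h_final"] = Hfinal);
  if (return_hidden_seq) out["hidden"] = hseqs;
  return out;
}

// Double-precision forward + BPTT against a per-timestep target with
// mean-squared-error loss over all T*B output entries and zero initial
// states.  Used by the finite-difference gradient checks; the training
// loop itself goes through the single-precision trainer below.
// [[Rcpp::export]]
List cpp_path_grad(const arma::mat& X, const arma::mat& Ytarget,
                   const List& layers, const arma::vec& V, double cbias,
                   int act) {
  const int T = X.n_rows, B = X.n_cols, L = layers.size();
  const double N = static_cast<double>(T) * B;

  std::vector<LayerW> W(L);
  std::vector<LayerCache> C(L);
  std::vector<mat> Xins(L);

  mat cur = row_blocked<double>(X);
  for (int l = 0; l < L; ++l) {
    W[l] = unpack_layer(layers[l]);
    Xins[l] = cur;
    const int H = W[l].W.n_rows;
    C[l] = run_layer_d(cur, W[l], mat(H, B, arma::fill::zeros), T, B, act);
    cur = C[l].Hseq.cols(B, (T + 1) * B - 1);
  }

  mat yrow = V.t() * cur;
  yrow += cbias;
  mat Y = blocked_to_TB<double>(yrow, T, B);
  mat resid = Y - Ytarget;
  double loss = arma::accu(arma::square(resid)) / N;

  mat dyrow = row_blocked<double>(mat(2.0 * resid / N));
  vec dV = cur * dyrow.t();
  double dc = arma::accu(dyrow);
  mat dHext = V * dyrow;

  List lgrads(L);
  for (int l = L - 1; l >= 0; --l) {
    const LayerW& w = W[l];
    const LayerCache& c = C[l];
    const int H = w.W.n_rows;
    mat dAr(H, T * B), dAz(H, T * B), dAc(H, T * B);
    mat WrzT = arma::join_cols(w.Wr, w.Wz).t();
    mat WT = w.W.t();
    mat carry(H, B, arma::fill::zeros);
    mat darz(2 * H, B), tmp(H, B);
    for (int t = T - 1; t >= 0; --t) {
      const int c0 = t * B, c1 = t * B + B - 1;
      mat hprev = c.Hseq.cols(c0, c1);
      mat r = c.R.cols(c0, c1), z = c.Z.cols(c0, c1), hc = c.HC.cols(c0, c1);
      mat dh = dHext.cols(c0, c1) + carry;
      mat actg = (act == ACT_RELU)
          ? mat(arma::conv_to<mat>::from(hc > 0.0))
          : mat(1.0 - arma::square(hc));
      mat dac = (dh % z) % actg;
      tmp = WT * dac;
      darz.rows(0, H - 1) = (tmp % hprev) % r % (1.0 - r);
      darz.rows(H, 2 * H - 1) = (dh % (hc - hprev)) % z % (1.0 - z);
      carry = dh % (1.0 - z) + tmp % r + WrzT * darz;
      dAr.cols(c0, c1) = darz.rows(0, H - 1);
      dAz.cols(c0, c1) = darz.rows(H, 2 * H - 1);
      dAc.cols(c0, c1) = dac;
    }
    const mat& Xin = Xins[l];
    mat Hprev = c.Hseq.cols(0, T * B - 1);
    mat RH = c.R % Hprev;
    lgrads[l] = List::create(
      _["Ur"] = mat(dAr * Xin.t()), _["Wr"] = mat(dAr * Hprev.t()),
      _["Uz"] = mat(dAz * Xin.t()), _["Wz"] = mat(dAz * Hprev.t()),
      _["U"]  = mat(dAc * Xin.t()), _["W"]  = mat(dAc * RH.t()),
      _["br"] = vec(arma::sum(dAr, 1)),
      _["bz"] = vec(arma::sum(dAz, 1)),
      _["bh"] = vec(arma::sum(dAc, 1)));
    if (l > 0)
      dHext = w.Ur.t() * dAr + w.Uz.t() * dAz + w.U.t() * dAc;
  }

  return List::create(_["loss"] = loss, _["y"] = Y,
                      _["layers"] = lgrads, _["V"] = dV, _["c"] = dc);
}


// ---------------------------------------------------------------------------
// Single-precision trainer with persistent state (weights, ADAM moments,
// workspaces) behind an external pointer.
// ---------------------------------------------------------------------------

namespace {

struct TLayer {
  int in = 0, H = 0;
  // weights, gates stacked: rows [0,H) reset, [H,2H) update, [2H,3H) candidate
  fmat Us;    // 3H x in
  fmat Wrz;   // 2H x H
  fmat W;     // H x H
  fvec bs;    // 3H
  // gradients
  fmat dUs, dWrz, dW; fvec dbs;
  // ADAM moments
  fmat mUs, vUs, mWrz, vWrz, mW, vW; fvec mbs, vbs;
  // workspaces/caches (persist across minibatches)
  fmat Xin;            // in x T*B
  fmat G;              // 3H x T*B
  fmat Hseq;           // H x (T+1)*B
  fmat R, Z, HC;       // H x T*B
  fmat dA;             // 3H x T*B
};

struct Trainer {
  int L = 0, act = ACT_RELU;
  long step_n = 0;
  float lr, b1, b2, eps, clip;
  std::vector<TLayer> lay;
  fvec V; float c = 0;
  fvec dV, mV, vV;
  float dc = 0, mc = 0, vc = 0;
};

// The BPTT carry decays geometrically through the update gate, so
// single-precision gradient buffers contain many subnormal values;
// x86 resolves subnormal arithmetic in microcode, which cripples GEMM
// throughput.  Training runs with flush-to-zero / denormals-are-zero
// set (scoped; restored on exit) — flushed magnitudes are < 1e-38 and
// irrelevant to the update.
struct FlushDenormals {
#ifdef TREMORNET_HAVE_MXCSR
  unsigned int old_csr;
  FlushDenormals() : old_csr(_mm_getcsr()) { _mm_setcsr(old_csr | 0x8040); }
  ~FlushDenormals() { _mm_setcsr(old_csr); }
#endif
};

void trainer_forward(Trainer& tr, const arma::mat& X, bool keep) {
  const int T = X.n_rows, B = X.n_cols;
  tr.lay[0].Xin = row_blocked<float>(arma::conv_to<fmat>::from(X));
  for (int l = 0; l < tr.L; ++l) {
    TLayer& y = tr.lay[l];
    const int H = y.H;
    y.G = y.Us * y.Xin;
    y.G.each_col() += y.bs;
    y.Hseq.set_size(H, (T + 1) * B);
    y.Hseq.cols(0, B - 1).zeros();
    if (keep) {
      y.R.set_size(H, T * B);
      y.Z.set_size(H, T * B);
      y.HC.set_size(H, T * B);
    }
    fmat rh(H, B), wrh(H, B), arz(2 * H, B), rloc(H, B), zloc(H, B);
    for (int t = 0; t < T; ++t) {
      const int c0 = t * B;
      const float* ph = y.Hseq.colptr(c0);
      arz = y.Wrz * y.Hseq.cols(c0, c0 + B - 1);
      float* pr = keep ? y.R.colptr(c0) : rloc.memptr();
      float* pz = keep ? y.Z.colptr(c0) : zloc.memptr();
      float* prh = rh.memptr();
      for (int j = 0; j < B; ++j) {
        const float* pg = y.G.colptr(c0 + j);
        const float* pa = arz.colptr(j);
        const int o = j * H;
        for (int i = 0; i < H; ++i) {
          const float r = sigmoid1(pg[i] + pa[i]);
          const float z = sigmoid1(pg[H + i] + pa[H + i]);
          pr[o + i] = r; pz[o + i] = z; prh[o + i] = r * ph[o + i];
        }
      }
      wrh = y.W * rh;
      float* phn = y.Hseq.colptr(c0 + B);
      float* phc = keep ? y.HC.colptr(c0) : wrh.memptr();
      const float* pw = wrh.memptr();
      for (int j = 0; j < B; ++j) {
        const float* pg = y.G.colptr(c0 + j);
        const int o = j * H;
        for (int i = 0; i < H; ++i) {
          const int k = o + i;
          const float hc = act1(pg[2 * H + i] + pw[k], tr.act);
          phc[k] = hc;
          phn[k] = (1.0f - pz[k]) * ph[k] + pz[k] * hc;
        }
      }
    }
    if (l + 1 < tr.L)
      tr.lay[l + 1].Xin = y.Hseq.cols(B, (T + 1) * B - 1);
  }
}

// y and residual staging shared by step and eval
double trainer_loss_and_dy(Trainer& tr, const arma::mat& X,
                           const arma::mat& Yt, bool want_grad,
                           fmat& dyrow, fmat& topH) {
  const int T = X.n_rows, B = X.n_cols;
  TLayer& top = tr.lay[tr.L - 1];
  topH = top.Hseq.cols(B, (T + 1) * B - 1);
  fmat yrow = tr.V.t() * topH;
  yrow += tr.c;
  fmat ytrow = row_blocked<float>(arma::conv_to<fmat>::from(Yt));
  fmat resid = yrow - ytrow;
  const float N = static_cast<float>(T) * B;
  double loss = arma::accu(arma::square(arma::conv_to<arma::mat>::from(resid))) / N;
  if (want_grad) dyrow = 2.0f * resid / N;
  return loss;
}

void adam_update(fmat& w, const fmat& g, fmat& m, fmat& v,
                 float a_t, float b1, float b2, float eps, float scale) {
  const int n = w.n_elem;
  float* pw = w.memptr(); float* pm = m.memptr(); float* pv = v.memptr();
  const float* pg = g.memptr();
  for (int i = 0; i < n; ++i) {
    const float gi = pg[i] * scale;
    pm[i] = b1 * pm[i] + (1.0f - b1) * gi;
    pv[i] = b2 * pv[i] + (1.0f - b2) * gi * gi;
    pw[i] -= a_t * pm[i] / (std::sqrt(pv[i]) + eps);
  }
}

void adam_update_vec(fvec& w, const fvec& g, fvec& m, fvec& v,
                     float a_t, float b1, float b2, float eps, float scale) {
  fmat wm(w.memptr(), w.n_elem, 1, false, true);
  fmat gm(const_cast<float*>(g.memptr()), g.n_elem, 1, false, true);
  fmat mm(m.memptr(), m.n_elem, 1, false, true);
  fmat vm(v.memptr(), v.n_elem, 1, false, true);
  adam_update(wm, gm, mm, vm, a_t, b1, b2, eps, scale);
}

}  // namespace

// Create a trainer.  `layers` uses the unstacked naming (Ur, Wr, Uz,
// Wz, U, W, br, bz, bh); weights are converted to the stacked
// single-precision layout internally.
// [[Rcpp::export]]
SEXP cpp_trainer_create(const List& layers, const arma::vec& V, double cbias,
                        double lr, double beta1, double beta2, double eps,
                        double clip, int act) {
  Trainer* tr = new Trainer();
  tr->L = layers.size();
  tr->act = act;
  tr->lr = lr; tr->b1 = beta1; tr->b2 = beta2; tr->eps = eps;
  tr->clip = clip;
  tr->lay.resize(tr->L);
  for (int l = 0; l < tr->L; ++l) {
    LayerW w = unpack_layer(layers[l]);
    TLayer& y = tr->lay[l];
    y.H = w.W.n_rows; y.in = w.Ur.n_cols;
    y.Us = arma::conv_to<fmat>::from(
        mat(arma::join_cols(w.Ur, w.Uz, w.U)));
    y.Wrz = arma::conv_to<fmat>::from(mat(arma::join_cols(w.Wr, w.Wz)));
    y.W = arma::conv_to<fmat>::from(w.W);
    y.bs = arma::conv_to<fvec>::from(vec(arma::join_cols(w.br, w.bz, w.bh)));
    y.mUs.zeros(3 * y.H, y.in); y.vUs.zeros(3 * y.H, y.in);
    y.mWrz.zeros(2 * y.H, y.H); y.vWrz.zeros(2 * y.H, y.H);
    y.mW.zeros(y.H, y.H); y.vW.zeros(y.H, y.H);
    y.mbs.zeros(3 * y.H); y.vbs.zeros(3 * y.H);
  }
  tr->V = arma::conv_to<fvec>::from(V);
  tr->c = cbias;
  tr->mV.zeros(V.n_elem); tr->vV.zeros(V.n_elem);
  XPtr<Trainer> p(tr, true);
  return p;
}

// One minibatch: forward, BPTT, global-norm gradient clipping, ADAM
// update.  X, Ytarget: T x B.  Returns the (pre-update) batch loss.
// [[Rcpp::export]]
double cpp_trainer_step(SEXP ptr, const arma::mat& X,
                        const arma::mat& Ytarget) {
  XPtr<Trainer> tp(ptr);
  Trainer& tr = *tp;
  const int T = X.n_rows, B = X.n_cols;
  FlushDenormals ftz;

  trainer_forward(tr, X, true);
  fmat dyrow, topH;
  double loss = trainer_loss_and_dy(tr, X, Ytarget, true, dyrow, topH);
  if (!std::isfinite(loss)) return loss;  // caller aborts; no update

  tr.dV = topH * dyrow.t();
  tr.dc = arma::accu(dyrow);
  fmat dHext = tr.V * dyrow;  // H x T*B

  for (int l = tr.L - 1; l >= 0; --l) {
    TLayer& y = tr.lay[l];
    const int H = y.H;
    y.dA.set_size(3 * H, T * B);
    fmat WrzT = y.Wrz.t();  // H x 2H
    fmat WT = y.W.t();
    fmat carry(H, B, arma::fill::zeros), carry_new(H, B);
    fmat darz(2 * H, B), dac(H, B), tmp(H, B);
    for (int t = T - 1; t >= 0; --t) {
      const int c0 = t * B;
      const float* ph = y.Hseq.colptr(c0);   // h_{t-1}
      const float* pz = y.Z.colptr(c0);
      const float* phc = y.HC.colptr(c0);
      const float* pdx = dHext.colptr(c0);
      const float* pca = carry.memptr();
      float* pdac = dac.memptr();
      for (int k = 0; k < H * B; ++k) {
        const float dh = pdx[k] + pca[k];
        const float g = (tr.act == ACT_RELU)
                            ? (phc[k] > 0.0f ? 1.0f : 0.0f)
                            : (1.0f - phc[k] * phc[k]);
        pdac[k] = dh * pz[k] * g;
      }
      tmp = WT * dac;
      const float* pr = y.R.colptr(c0);
      const float* pt = tmp.memptr();
      float* pcn = carry_new.memptr();
      for (int j = 0; j < B; ++j) {
        float* pda = darz.colptr(j);
        float* pa3 = y.dA.colptr(c0 + j);
        const float* pdc = dac.colptr(j);
        const int o = j * H;
        for (int i = 0; i < H; ++i) {
          const int k = o + i;
          const float dh = pdx[k] + pca[k];
          const float r = pr[k], z = pz[k];
          const float dar = (pt[k] * ph[k]) * r * (1.0f - r);
          const float daz = (dh * (phc[k] - ph[k])) * z * (1.0f - z);
          pda[i] = dar; pda[H + i] = daz;
          pa3[i] = dar; pa3[H + i] = daz; pa3[2 * H + i] = pdc[i];
          pcn[k] = dh * (1.0f - z) + pt[k] * r;
        }
      }
      carry = carry_new + WrzT * darz;
    }
    auto Hprev = y.Hseq.cols(0, T * B - 1);
    fmat RH = y.R % Hprev;
    y.dUs = y.dA * y.Xin.t();
    y.dWrz = y.dA.rows(0, 2 * H - 1) * Hprev.t();
    y.dW = y.dA.rows(2 * H, 3 * H - 1) * RH.t();
    y.dbs = arma::sum(y.dA, 1);
    if (l > 0) dHext = y.Us.t() * y.dA;
  }

  // global-norm gradient clipping
  double sq = arma::dot(tr.dV, tr.dV) + tr.dc * tr.dc;
  for (const TLayer& y : tr.lay)
    sq += arma::dot(y.dUs, y.dUs) + arma::dot(y.dWrz, y.dWrz) +
          arma::dot(y.dW, y.dW) + arma::dot(y.dbs, y.dbs);
  const double gnorm = std::sqrt(sq);
  float scale = 1.0f;
  if (tr.clip > 0 && gnorm > tr.clip) scale = tr.clip / gnorm;

  // ADAM with bias correction
  tr.step_n++;
  const float a_t = tr.lr *
      std::sqrt(1.0f - std::pow(tr.b2, (float)tr.step_n)) /
      (1.0f - std::pow(tr.b1, (float)tr.step_n));
  for (TLayer& y : tr.lay) {
    adam_update(y.Us, y.dUs, y.mUs, y.vUs, a_t, tr.b1, tr.b2, tr.eps, scale);
    adam_update(y.Wrz, y.dWrz, y.mWrz, y.vWrz, a_t, tr.b1, tr.b2, tr.eps, scale);
    adam_update(y.W, y.dW, y.mW, y.vW, a_t, tr.b1, tr.b2, tr.eps, scale);
    adam_update_vec(y.bs, y.dbs, y.mbs, y.vbs, a_t, tr.b1, tr.b2, tr.eps, scale);
  }
  adam_update_vec(tr.V, tr.dV, tr.mV, tr.vV, a_t, tr.b1, tr.b2, tr.eps, scale);
  {
    const float gi = tr.dc * scale;
    tr.mc = tr.b1 * tr.mc + (1.0f - tr.b1) * gi;
    tr.vc = tr.b2 * tr.vc + (1.0f - tr.b2) * gi * gi;
    tr.c -= a_t * tr.mc / (std::sqrt(tr.vc) + tr.eps);
  }
  return loss;
}

// Forward-only batch loss (no caches beyond layer staging, no update).
// [[Rcpp::export]]
double cpp_trainer_eval(SEXP ptr, const arma::mat& X,
                        const arma::mat& Ytarget) {
  XPtr<Trainer> tp(ptr);
  Trainer& tr = *tp;
  FlushDenormals ftz;
  trainer_forward(tr, X, false);
  fmat dyrow, topH;
  return trainer_loss_and_dy(tr, X, Ytarget, false, dyrow, topH);
}

// Current weights in the unstacked, double-precision naming.
// [[Rcpp::export]]
List cpp_trainer_params(SEXP ptr) {
  XPtr<Trainer> tp(ptr);
  Trainer& tr = *tp;
  List layers(tr.L);
  for (int l = 0; l < tr.L; ++l) {
    const TLayer& y = tr.lay[l];
    const int H = y.H;
    mat Us = arma::conv_to<mat>::from(y.Us);
    mat Wrz = arma::conv_to<mat>::from(y.Wrz);
    vec bs = arma::conv_to<vec>::from(y.bs);
    layers[l] = List::create(
      _["Ur"] = mat(Us.rows(0, H - 1)),
      _["Uz"] = mat(Us.rows(H, 2 * H - 1)),
      _["U"]  = mat(Us.rows(2 * H, 3 * H - 1)),
      _["Wr"] = mat(Wrz.rows(0, H - 1)),
      _["Wz"] = mat(Wrz.rows(H, 2 * H - 1)),
      _["W"]  = arma::conv_to<mat>::from(y.W),
      _["br"] = vec(bs.subvec(0, H - 1)),
      _["bz"] = vec(bs.subvec(H, 2 * H - 1)),
      _["bh"] = vec(bs.subvec(2 * H, 3 * H - 1)));
  }
  return List::create(_["layers"] = layers,
                      _["V"] = arma::conv_to<vec>::from(tr.V),
                      _["c"] = static_cast<double>(tr.c));
}
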