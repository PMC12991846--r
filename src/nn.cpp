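// Minimal single-precision conv-net engine (im2col + GEMM) used by the
// no-reference quality regressors: conv (stride 1, zero same-padding),
// 2x2 max-pool, ReLU, dense, inverted dropout, MAE loss, Adam, and
// activation capture for Grad-CAM. Batches are matrices (C*H*W) x N
// with per-sample layout index(c,h,w) = c*H*W + w*H + h.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::fmat as_fmat(SEXP x) {
  NumericVector v(x);
  int nr, nc;
  if (Rf_isMatrix(x)) {
    IntegerVector d = as<IntegerVector>(Rf_getAttrib(x, R_DimSymbol));
    nr = d[0]; nc = d[1];
  } else { nr = v.size(); nc = 1; }
  arma::fmat out(nr, nc);
  for (int i = 0; i < nr * nc; ++i) out[i] = (float)v[i];
  return out;
}

static void im2col(const float* x, int C, int H, int W, int k, int pad,
                   arma::fmat& col) {
  // col is (k*k*C) x (H*W); row r = c*k*k + dj*k + di, col q = w*H + h
  const int HW = H * W;
  const int kk = k * k;
  float* cp = col.memptr();
  const int R = col.n_rows;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      float* dst = cp + (size_t)(w * H + h) * R;
      for (int c = 0; c < C; ++c) {
        const float* plane = x + c * HW;
        float* d = dst + c * kk;
        for (int dj = 0; dj < k; ++dj) {
          const int sw = w + dj - pad;
          if (sw < 0 || sw >= W) {
            for (int di = 0; di < k; ++di) d[dj * k + di] = 0.0f;
            continue;
          }
          const float* pc = plane + sw * H;
          for (int di = 0; di < k; ++di) {
            const int sh = h + di - pad;
            d[dj * k + di] = (sh >= 0 && sh < H) ? pc[sh] : 0.0f;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::fmat& col, int C, int H, int W, int k,
                       int pad, float* dx) {
  const int HW = H * W;
  const int kk = k * k;
  const float* cp = col.memptr();
  const int R = col.n_rows;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const float* src = cp + (size_t)(w * H + h) * R;
      for (int c = 0; c < C; ++c) {
        float* plane = dx + c * HW;
        const float* s = src + c * kk;
        for (int dj = 0; dj < k; ++dj) {
          const int sw = w + dj - pad;
          if (sw < 0 || sw >= W) continue;
          float* pc = plane + sw * H;
          for (int di = 0; di < k; ++di) {
            const int sh = h + di - pad;
            if (sh >= 0 && sh < H) pc[sh] += s[dj * k + di];
          }
        }
      }
    }
  }
}

enum LType { CONV, POOL, RELU, FLATTEN, DROPOUT, DENSE };

struct LayerSpec {
  LType type;
  int k = 0, C = 0, H = 0, W = 0, out = 0, in = 0;
  float rate = 0.0f;
  int widx = -1; // index into weight arrays, -1 if none
};

struct Net {
  std::vector<LayerSpec> ls;
  std::vector<arma::fmat> Wf; // conv: (k*k*C) x F; dense: in x out
  std::vector<arma::fvec> bf;

  void parse(List layers, List weights) {
    int wi = 0;
    for (int l = 0; l < layers.size(); ++l) {
      List ly = layers[l];
      std::string t = as<std::string>(ly["type"]);
      LayerSpec s;
      if (t == "conv") {
        s.type = CONV; s.k = ly["k"]; s.C = ly["C"]; s.H = ly["H"];
        s.W = ly["Wd"]; s.out = ly["out"];
        List wl = weights[wi];
        arma::fmat Wm = as_fmat(wl["W"]);
        Wm.reshape(s.k * s.k * s.C, s.out);
        Wf.push_back(Wm);
        bf.push_back(as_fmat(wl["b"]).col(0));
        s.widx = wi++;
      } else if (t == "dense") {
        s.type = DENSE;
        List wl = weights[wi];
        Wf.push_back(as_fmat(wl["W"]));
        bf.push_back(as_fmat(wl["b"]).col(0));
        s.in = Wf.back().n_rows; s.out = Wf.back().n_cols;
        s.widx = wi++;
      } else if (t == "pool") {
        s.type = POOL; s.C = ly["C"]; s.H = ly["H"]; s.W = ly["Wd"];
      } else if (t == "relu") {
        s.type = RELU;
      } else if (t == "flatten") {
        s.type = FLATTEN;
      } else if (t == "dropout") {
        s.type = DROPOUT; s.rate = (float)as<double>(ly["rate"]);
      } else stop("unknown layer type");
      ls.push_back(s);
    }
  }
};

struct Cache {
  std::vector<arma::fmat> acts;       // acts[l] = input to layer l
  std::vector<arma::umat> poolidx;
  std::vector<arma::fmat> dropmask;
};

static arma::fmat net_forward(Net& net, const arma::fmat& X, Cache& cc,
                              bool training, std::mt19937& rng) {
  const int L = net.ls.size();
  const int N = X.n_cols;
  cc.acts.assign(L + 1, arma::fmat());
  cc.poolidx.assign(L, arma::umat());
  cc.dropmask.assign(L, arma::fmat());
  cc.acts[0] = X;
  for (int l = 0; l < L; ++l) {
    const LayerSpec& s = net.ls[l];
    const arma::fmat& A = cc.acts[l];
    switch (s.type) {
    case CONV: {
      const int HW = s.H * s.W;
      arma::fmat out(s.out * HW, N);
      arma::fmat col(s.k * s.k * s.C, HW);
      const int pad = (s.k - 1) / 2;
      for (int n = 0; n < N; ++n) {
        im2col(A.colptr(n), s.C, s.H, s.W, s.k, pad, col);
        arma::fmat Y = col.t() * net.Wf[s.widx]; // HW x F
        Y.each_row() += net.bf[s.widx].t();
        std::memcpy(out.colptr(n), Y.memptr(), sizeof(float) * s.out * HW);
      }
      cc.acts[l + 1] = std::move(out);
      break;
    }
    case POOL: {
      const int H2 = s.H / 2, W2 = s.W / 2;
      arma::fmat out(s.C * H2 * W2, N);
      arma::umat idx(s.C * H2 * W2, N);
      for (int n = 0; n < N; ++n) {
        const float* x = A.colptr(n);
        float* o = out.colptr(n);
        arma::uword* id = idx.colptr(n);
        for (int c = 0; c < s.C; ++c) {
          const float* plane = x + c * s.H * s.W;
          for (int w = 0; w < W2; ++w)
            for (int h = 0; h < H2; ++h) {
              int base = (2 * w) * s.H + 2 * h;
              int cand[4] = {base, base + 1, base + s.H, base + s.H + 1};
              int best = cand[0];
              float bv = plane[cand[0]];
              for (int t = 1; t < 4; ++t)
                if (plane[cand[t]] > bv) { bv = plane[cand[t]]; best = cand[t]; }
              o[c * H2 * W2 + w * H2 + h] = bv;
              id[c * H2 * W2 + w * H2 + h] = c * s.H * s.W + best;
            }
        }
      }
      cc.acts[l + 1] = std::move(out);
      cc.poolidx[l] = std::move(idx);
      break;
    }
    case RELU:
      cc.acts[l + 1] = arma::clamp(A, 0.0f,
                                   std::numeric_limits<float>::max());
      break;
    case FLATTEN:
      cc.acts[l + 1] = A;
      break;
    case DROPOUT: {
      if (training && s.rate > 0) {
        std::uniform_real_distribution<float> U(0.0f, 1.0f);
        arma::fmat m(A.n_rows, A.n_cols);
        const float keep = 1.0f - s.rate;
        for (arma::uword i = 0; i < m.n_elem; ++i)
          m[i] = (U(rng) < keep) ? 1.0f / keep : 0.0f;
        cc.acts[l + 1] = A % m;
        cc.dropmask[l] = std::move(m);
      } else cc.acts[l + 1] = A;
      break;
    }
    case DENSE: {
      arma::fmat out = net.Wf[s.widx].t() * A;
      out.each_col() += net.bf[s.widx];
      cc.acts[l + 1] = std::move(out);
      break;
    }
    }
  }
  return cc.acts[L];
}

// backward pass; if gW/gb non-null accumulate gradients; capture_layer
// records the gradient at that layer's output into cap_grad
static void net_backward(Net& net, Cache& cc, arma::fmat dA,
                         std::vector<arma::fmat>* gW,
                         std::vector<arma::fvec>* gb,
                         int capture_layer, arma::fmat* cap_grad) {
  const int L = net.ls.size();
  const int N = dA.n_cols;
  for (int l = L - 1; l >= 0; --l) {
    const LayerSpec& s = net.ls[l];
    const arma::fmat& A = cc.acts[l];
    if (capture_layer == l && cap_grad) *cap_grad = dA;
    arma::fmat dPrev;
    switch (s.type) {
    case DENSE:
      if (gW) {
        (*gW)[s.widx] = A * dA.t();
        (*gb)[s.widx] = arma::sum(dA, 1);
      }
      dPrev = net.Wf[s.widx] * dA;
      break;
    case RELU:
      dPrev = dA % arma::conv_to<arma::fmat>::from(cc.acts[l + 1] > 0);
      break;
    case FLATTEN:
      dPrev = std::move(dA);
      break;
    case DROPOUT:
      dPrev = (cc.dropmask[l].n_elem > 0) ? arma::fmat(dA % cc.dropmask[l])
                                          : std::move(dA);
      break;
    case POOL: {
      dPrev.zeros(s.C * s.H * s.W, N);
      const arma::umat& idx = cc.poolidx[l];
      for (int n = 0; n < N; ++n) {
        float* dst = dPrev.colptr(n);
        const float* src = dA.colptr(n);
        const arma::uword* id = idx.colptr(n);
        for (arma::uword i = 0; i < idx.n_rows; ++i) dst[id[i]] += src[i];
      }
      break;
    }
    case CONV: {
      const int HW = s.H * s.W;
      const int pad = (s.k - 1) / 2;
      arma::fmat dWm;
      arma::fvec db;
      if (gW) { dWm.zeros(s.k * s.k * s.C, s.out); db.zeros(s.out); }
      dPrev.zeros(s.C * HW, N);
      arma::fmat col(s.k * s.k * s.C, HW);
      for (int n = 0; n < N; ++n) {
        arma::fmat dY(const_cast<float*>(dA.colptr(n)), HW, s.out, false,
                      true);
        if (gW) {
          im2col(A.colptr(n), s.C, s.H, s.W, s.k, pad, col);
          dWm += col * dY;
          db += arma::sum(dY, 0).t();
        }
        arma::fmat dcol = net.Wf[s.widx] * dY.t(); // (k*k*C) x HW
        col2im_add(dcol, s.C, s.H, s.W, s.k, pad, dPrev.colptr(n));
      }
      if (gW) { (*gW)[s.widx] = std::move(dWm); (*gb)[s.widx] = std::move(db); }
      break;
    }
    }
    dA = std::move(dPrev);
  }
}

static SEXP weights_to_r(Net& net, List layers) {
  List out;
  for (size_t l = 0; l < net.ls.size(); ++l) {
    const LayerSpec& s = net.ls[l];
    if (s.widx < 0) continue;
    if (s.type == CONV) {
      NumericVector W(net.Wf[s.widx].begin(), net.Wf[s.widx].end());
      W.attr("dim") = IntegerVector::create(s.k, s.k, s.C, s.out);
      out.push_back(List::create(_["W"] = W,
          _["b"] = NumericVector(net.bf[s.widx].begin(),
                                 net.bf[s.widx].end())));
    } else {
      NumericVector W(net.Wf[s.widx].begin(), net.Wf[s.widx].end());
      W.attr("dim") = IntegerVector::create(s.in, s.out);
      out.push_back(List::create(_["W"] = W,
          _["b"] = NumericVector(net.bf[s.widx].begin(),
                                 net.bf[s.widx].end())));
    }
  }
  return out;
}

// [[Rcpp::export(name = ".nn_run")]]
List nn_run(List layers, List weights, SEXP Xs, SEXP ys,
            bool training, bool want_grads, int dropout_seed,
            int capture_layer, int gradcam_output) {
  Net net;
  net.parse(layers, weights);
  arma::fmat X = as_fmat(Xs);
  std::mt19937 rng((unsigned)dropout_seed);
  Cache cc;
  arma::fmat pred = net_forward(net, X, cc, training, rng);
  double loss = NA_REAL;
  arma::fmat dA;
  if (gradcam_output >= 0) {
    dA.zeros(pred.n_rows, pred.n_cols);
    dA.row(gradcam_output).fill(1.0f);
  } else if (!Rf_isNull(ys)) {
    arma::fmat y = as_fmat(ys);
    arma::fmat diff = pred - y;
    loss = arma::accu(arma::abs(diff)) / diff.n_elem;
    if (want_grads) dA = arma::sign(diff) / (float)diff.n_elem;
  }
  List out = List::create(
      _["pred"] = wrap(arma::conv_to<arma::mat>::from(pred)),
      _["loss"] = loss);
  if (dA.n_elem > 0) {
    std::vector<arma::fmat> gW(net.Wf.size());
    std::vector<arma::fvec> gb(net.bf.size());
    arma::fmat cap_act, cap_grad;
    if (capture_layer >= 0) cap_act = cc.acts[capture_layer + 1];
    bool needW = want_grads && gradcam_output < 0;
    net_backward(net, cc, dA, needW ? &gW : nullptr, needW ? &gb : nullptr,
                 capture_layer, &cap_grad);
    if (needW) {
      List g;
      for (size_t l = 0; l < net.ls.size(); ++l) {
        const LayerSpec& s = net.ls[l];
        if (s.widx < 0) continue;
        NumericVector W(gW[s.widx].begin(), gW[s.widx].end());
        if (s.type == CONV)
          W.attr("dim") = IntegerVector::create(s.k, s.k, s.C, s.out);
        else
          W.attr("dim") = IntegerVector::create(s.in, s.out);
        g.push_back(List::create(_["W"] = W,
            _["b"] = NumericVector(gb[s.widx].begin(), gb[s.widx].end())));
      }
      out["grads"] = g;
    }
    if (capture_layer >= 0) {
      out["capture_act"] = wrap(arma::conv_to<arma::mat>::from(cap_act));
      if (cap_grad.n_elem > 0)
        out["capture_grad"] = wrap(arma::conv_to<arma::mat>::from(cap_grad));
    }
  } else if (capture_layer >= 0) {
    out["capture_act"] =
        wrap(arma::conv_to<arma::mat>::from(cc.acts[capture_layer + 1]));
  }
  return out;
}

// Full training loop: MAE loss, Adam, shuffled minibatches, early
// stopping on validation MAE; returns the best-validation weights.
// [[Rcpp::export(name = ".nn_train")]]
List nn_train(List layers, List weights, SEXP Xs, SEXP Ys, SEXP Xvs,
              SEXP Yvs, double lr, int batch, int max_epochs, int patience,
              int seed) {
  Net net;
  net.parse(layers, weights);
  arma::fmat X = as_fmat(Xs), Y = as_fmat(Ys);
  arma::fmat Xv = as_fmat(Xvs), Yv = as_fmat(Yvs);
  const int n = X.n_cols;
  std::mt19937 rng((unsigned)seed);

  std::vector<arma::fmat> mW(net.Wf.size()), vW(net.Wf.size());
  std::vector<arma::fvec> mb(net.bf.size()), vb(net.bf.size());
  for (size_t i = 0; i < net.Wf.size(); ++i) {
    mW[i].zeros(arma::size(net.Wf[i])); vW[i].zeros(arma::size(net.Wf[i]));
    mb[i].zeros(net.bf[i].n_elem); vb[i].zeros(net.bf[i].n_elem);
  }
  std::vector<arma::fmat> gW(net.Wf.size());
  std::vector<arma::fvec> gb(net.bf.size());
  std::vector<arma::fmat> bestW = net.Wf;
  std::vector<arma::fvec> bestb = net.bf;
  double bestLoss = std::numeric_limits<double>::infinity();
  int bestEpoch = 0, bad = 0, t = 0;
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  std::vector<double> trainHist, valHist;
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  Cache cc;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double tl = 0; int nb = 0;
    for (int start = 0; start < n; start += batch) {
      int bs = std::min(batch, n - start);
      arma::fmat Xb(X.n_rows, bs), Yb(Y.n_rows, bs);
      for (int i = 0; i < bs; ++i) {
        Xb.col(i) = X.col(perm[start + i]);
        Yb.col(i) = Y.col(perm[start + i]);
      }
      arma::fmat pred = net_forward(net, Xb, cc, true, rng);
      arma::fmat diff = pred - Yb;
      tl += arma::accu(arma::abs(diff)) / diff.n_elem;
      nb++;
      arma::fmat dA = arma::sign(diff) / (float)diff.n_elem;
      net_backward(net, cc, dA, &gW, &gb, -1, nullptr);
      t++;
      const float bc1 = 1.0f - std::pow(b1, (float)t);
      const float bc2 = 1.0f - std::pow(b2, (float)t);
      for (size_t i = 0; i < net.Wf.size(); ++i) {
        mW[i] = b1 * mW[i] + (1 - b1) * gW[i];
        vW[i] = b2 * vW[i] + (1 - b2) * arma::square(gW[i]);
        net.Wf[i] -= lr * (mW[i] / bc1) / (arma::sqrt(vW[i] / bc2) + eps);
        mb[i] = b1 * mb[i] + (1 - b1) * gb[i];
        vb[i] = b2 * vb[i] + (1 - b2) * arma::square(gb[i]);
        net.bf[i] -= lr * (mb[i] / bc1) / (arma::sqrt(vb[i] / bc2) + eps);
      }
    }
    // validation in chunks to bound memory
    double vl = 0; long vcount = 0;
    for (int start = 0; start < (int)Xv.n_cols; start += 256) {
      int bs = std::min(256, (int)Xv.n_cols - start);
      arma::fmat pred = net_forward(net, Xv.cols(start, start + bs - 1), cc,
                                    false, rng);
      vl += arma::accu(arma::abs(pred - Yv.cols(start, start + bs - 1)));
      vcount += (long)pred.n_elem;
    }
    vl /= vcount;
    trainHist.push_back(tl / nb);
    valHist.push_back(vl);
    Rcpp::checkUserInterrupt();
    if (vl < bestLoss) {
      bestLoss = vl; bestW = net.Wf; bestb = net.bf; bestEpoch = epoch;
      bad = 0;
    } else if (++bad > patience) break;
  }
  net.Wf = bestW; net.bf = bestb;
  return List::create(
      _["weights"] = weights_to_r(net, layers),
      _["train_mae"] = trainHist, _["val_mae"] = valHist,
      _["best_epoch"] = bestEpoch, _["best_val_mae"] = bestLoss);
}
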