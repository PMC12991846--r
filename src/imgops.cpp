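// Low-level image kernels: 2-D cross-correlation with explicit boundary
// handling, bilinear resize, Radon forward projection and filtered
// backprojection. Boundary conventions matter for the metric definitions
// (valid-region windows for SSIM, symmetric padding for MSCN), so these
// are implemented here rather than borrowed from FFT-based filters.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat pad_matrix(const arma::mat& A, int pt, int pb, int pl, int pr,
                            const std::string& boundary) {
  const int H = A.n_rows, W = A.n_cols;
  arma::mat P(H + pt + pb, W + pl + pr, arma::fill::zeros);
  P.submat(pt, pl, pt + H - 1, pl + W - 1) = A;
  if (boundary == "zero") return P;
  // symmetric (reflect including edge pixel), clamped for pads >= dim
  auto refl = [](int i, int n) {
    if (n == 1) return 0;
    int p = 2 * n;
    i = ((i % p) + p) % p;
    return (i < n) ? i : (p - 1 - i);
  };
  for (int r = 0; r < (int)P.n_rows; ++r) {
    int sr = refl(r - pt, H);
    for (int c = 0; c < (int)P.n_cols; ++c) {
      if (r >= pt && r < pt + H && c >= pl && c < pl + W) continue;
      int sc = refl(c - pl, W);
      P(r, c) = A(sr, sc);
    }
  }
  return P;
}

static arma::mat xcorr_valid(const arma::mat& A, const arma::mat& K) {
  const int H = A.n_rows, W = A.n_cols, kh = K.n_rows, kw = K.n_cols;
  const int oh = H - kh + 1, ow = W - kw + 1;
  arma::mat out(oh, ow, arma::fill::zeros);
  for (int dj = 0; dj < kw; ++dj)
    for (int di = 0; di < kh; ++di) {
      const double k = K(di, dj);
      if (k == 0.0) continue;
      out += k * A.submat(di, dj, di + oh - 1, dj + ow - 1);
    }
  return out;
}

// [[Rcpp::export(name = ".cc_filter2")]]
arma::mat cc_filter2(const arma::mat& A, const arma::mat& K,
                     const std::string& mode, const std::string& boundary) {
  // cross-correlation (no kernel flip); mode "valid" or "same"
  if (mode == "valid") return xcorr_valid(A, K);
  const int kh = K.n_rows, kw = K.n_cols;
  const int pt = (kh - 1) / 2, pb = kh - 1 - pt;
  const int pl = (kw - 1) / 2, pr = kw - 1 - pl;
  return xcorr_valid(pad_matrix(A, pt, pb, pl, pr, boundary), K);
}

// [[Rcpp::export(name = ".cc_pad")]]
arma::mat cc_pad(const arma::mat& A, int pt, int pb, int pl, int pr,
                 const std::string& boundary) {
  return pad_matrix(A, pt, pb, pl, pr, boundary);
}

// 2x2 mean pooling (truncates odd trailing row/col)
// [[Rcpp::export(name = ".cc_meanpool2")]]
arma::mat cc_meanpool2(const arma::mat& A) {
  const int H = A.n_rows / 2, W = A.n_cols / 2;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = 0.25 * (A(2 * i, 2 * j) + A(2 * i + 1, 2 * j) +
                          A(2 * i, 2 * j + 1) + A(2 * i + 1, 2 * j + 1));
  return out;
}

// [[Rcpp::export(name = ".cc_resize_bilinear")]]
arma::mat cc_resize_bilinear(const arma::mat& A, int oh, int ow) {
  const int H = A.n_rows, W = A.n_cols;
  arma::mat out(oh, ow);
  const double sr = (double)H / oh, sc = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    double y = (j + 0.5) * sc - 0.5;
    int j0 = (int)std::floor(y);
    double fy = y - j0;
    int j1 = std::min(std::max(j0 + 1, 0), W - 1);
    j0 = std::min(std::max(j0, 0), W - 1);
    for (int i = 0; i < oh; ++i) {
      double x = (i + 0.5) * sr - 0.5;
      int i0 = (int)std::floor(x);
      double fx = x - i0;
      int i1 = std::min(std::max(i0 + 1, 0), H - 1);
      int i0c = std::min(std::max(i0, 0), H - 1);
      out(i, j) = (1 - fx) * ((1 - fy) * A(i0c, j0) + fy * A(i0c, j1)) +
                  fx * ((1 - fy) * A(i1, j0) + fy * A(i1, j1));
    }
  }
  return out;
}

// Radon forward projection by bilinear splatting onto the detector.
// angles in radians; detector has nd bins spanning the image diagonal.
// [[Rcpp::export(name = ".cc_radon")]]
arma::mat cc_radon(const arma::mat& A, const arma::vec& angles, int nd) {
  const int H = A.n_rows, W = A.n_cols, na = angles.n_elem;
  arma::mat sino(nd, na, arma::fill::zeros);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0, c0 = (nd - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < W; ++j) {
      const double xr = (j - cx);
      for (int i = 0; i < H; ++i) {
        const double v = A(i, j);
        if (v == 0.0) continue;
        const double s = xr * ct + (i - cy) * st + c0;
        int s0 = (int)std::floor(s);
        double f = s - s0;
        if (s0 >= 0 && s0 < nd) sino(s0, a) += v * (1 - f);
        if (s0 + 1 >= 0 && s0 + 1 < nd) sino(s0 + 1, a) += v * f;
      }
    }
  }
  return sino;
}

// Backprojection (adjoint with bilinear detector interpolation).
// [[Rcpp::export(name = ".cc_backproject")]]
arma::mat cc_backproject(const arma::mat& sino, const arma::vec& angles,
                         int H, int W) {
  const int nd = sino.n_rows, na = angles.n_elem;
  arma::mat out(H, W, arma::fill::zeros);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0, c0 = (nd - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < W; ++j) {
      const double xc = (j - cx) * ct + c0;
      for (int i = 0; i < H; ++i) {
        const double s = xc + (i - cy) * st;
        int s0 = (int)std::floor(s);
        double f = s - s0;
        double v = 0.0;
        if (s0 >= 0 && s0 < nd) v += sino(s0, a) * (1 - f);
        if (s0 + 1 >= 0 && s0 + 1 < nd) v += sino(s0 + 1, a) * f;
        out(i, j) += v;
      }
    }
  }
  return out * (M_PI / (2.0 * na));
}
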