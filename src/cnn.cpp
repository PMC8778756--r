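// Compact convolutional network kernels: 3x3 same-padding convolution,
// ReLU, 2x2 max-pooling blocks, a dense head and softmax cross-entropy,
// with full backpropagation. All randomness (weight init, shuffling,
// augmentation draws) lives on the R side so the C++ stays deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::umat;

// Activations between blocks are stored as an F x (H*W*B) matrix:
// rows = channels, columns = spatial position p = i + H*j of image b at
// column p + H*W*b. Spatial positions use R's column-major convention so
// an R array img[i, j, c] flattens to p + H*W*c per image.

static mat im2col3(const mat& A, int H, int W, int B) {
  const int C = A.n_rows, HW = H * W;
  mat cols(9 * C, (arma::uword)HW * B, arma::fill::zeros);
  for (int b = 0; b < B; b++) {
    for (int j = 0; j < W; j++) {
      for (int i = 0; i < H; i++) {
        const int p = i + H * j + HW * b;
        for (int dj = -1; dj <= 1; dj++) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          for (int di = -1; di <= 1; di++) {
            const int ii = i + di;
            if (ii < 0 || ii >= H) continue;
            const int q = ii + H * jj + HW * b;
            const int roff = (dj + 1) * 3 + (di + 1);
            for (int c = 0; c < C; c++) cols(c * 9 + roff, p) = A(c, q);
          }
        }
      }
    }
  }
  return cols;
}

static mat col2im3(const mat& dcols, int C, int H, int W, int B) {
  const int HW = H * W;
  mat dA(C, (arma::uword)HW * B, arma::fill::zeros);
  for (int b = 0; b < B; b++) {
    for (int j = 0; j < W; j++) {
      for (int i = 0; i < H; i++) {
        const int p = i + H * j + HW * b;
        for (int dj = -1; dj <= 1; dj++) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          for (int di = -1; di <= 1; di++) {
            const int ii = i + di;
            if (ii < 0 || ii >= H) continue;
            const int q = ii + H * jj + HW * b;
            const int roff = (dj + 1) * 3 + (di + 1);
            for (int c = 0; c < C; c++) dA(c, q) += dcols(c * 9 + roff, p);
          }
        }
      }
    }
  }
  return dA;
}

// 2x2 max-pool, stride 2. Returns pooled activations and the linear column
// index (into the input) of each argmax for the backward pass.
static void maxpool2(const mat& A, int H, int W, int B, mat& out, umat& idx) {
  const int F = A.n_rows, Ho = H / 2, Wo = W / 2;
  const int HW = H * W, HWo = Ho * Wo;
  out.set_size(F, (arma::uword)HWo * B);
  idx.set_size(F, (arma::uword)HWo * B);
  for (int b = 0; b < B; b++) {
    for (int jo = 0; jo < Wo; jo++) {
      for (int io = 0; io < Ho; io++) {
        const int po = io + Ho * jo + HWo * b;
        const int q00 = (2 * io) + H * (2 * jo) + HW * b;
        const int qs[4] = {q00, q00 + 1, q00 + H, q00 + H + 1};
        for (int f = 0; f < F; f++) {
          double best = A(f, qs[0]);
          int bi = 0;
          for (int k = 1; k < 4; k++) {
            if (A(f, qs[k]) > best) { best = A(f, qs[k]); bi = k; }
          }
          out(f, po) = best;
          idx(f, po) = qs[bi];
        }
      }
    }
  }
}

// Forward (and optionally backward) pass over a batch.
// X: (3*side*side) x B, values in [0,1]; y: 0-based labels (length 0 to skip
// the loss); weights: list(Wc=list, bc=list, Wd, bd, Wo, bo).
// [[Rcpp::export]]
List cpp_cnn_batch(List weights, const arma::mat& X, IntegerVector y,
                   int side, bool want_grad) {
  List WcL = weights["Wc"], bcL = weights["bc"];
  mat Wd = weights["Wd"], Wo = weights["Wo"];
  vec bd = weights["bd"], bo = weights["bo"];
  const int L = WcL.size();
  const int B = X.n_cols;
  const int HW0 = side * side;
  if ((int)X.n_rows != 3 * HW0) stop("input size does not match model side");

  // unpack input into channel-rows layout
  mat A(3, (arma::uword)HW0 * B);
  for (int b = 0; b < B; b++)
    for (int c = 0; c < 3; c++)
      for (int p = 0; p < HW0; p++)
        A(c, p + (arma::uword)HW0 * b) = X(p + HW0 * c, b);

  std::vector<mat> colsv(L), Zv(L);    // caches for backward
  std::vector<umat> idxv(L);
  std::vector<int> Hs(L + 1);
  Hs[0] = side;
  int H = side, W = side;
  for (int l = 0; l < L; l++) {
    if (H % 2 != 0) stop("side must halve cleanly through every block");
    mat Wl = WcL[l];
    vec bl = bcL[l];
    mat cols = im2col3(A, H, W, B);
    mat Z = Wl * cols;
    Z.each_col() += bl;
    mat Zr = arma::clamp(Z, 0.0, arma::datum::inf);
    mat P; umat idx;
    maxpool2(Zr, H, W, B, P, idx);
    if (want_grad) { colsv[l] = cols; Zv[l] = Z; idxv[l] = idx; }
    A = P;
    H /= 2; W /= 2;
    Hs[l + 1] = H;
  }
  const int FL = A.n_rows, hw = H * W, flat = FL * hw;

  // flatten: Xf(f*hw + p, b) = A(f, p + hw*b)
  mat Xf(flat, B);
  for (int b = 0; b < B; b++)
    for (int f = 0; f < FL; f++)
      for (int p = 0; p < hw; p++)
        Xf(f * hw + p, b) = A(f, p + (arma::uword)hw * b);

  mat Zd = Wd * Xf;
  Zd.each_col() += bd;
  mat Hd = arma::clamp(Zd, 0.0, arma::datum::inf);
  mat Zo = Wo * Hd;
  Zo.each_col() += bo;

  // softmax per column
  mat P = Zo;
  for (int b = 0; b < B; b++) {
    vec z = P.col(b);
    z -= z.max();
    vec e = arma::exp(z);
    P.col(b) = e / arma::accu(e);
  }

  double loss = NA_REAL;
  const bool have_y = y.size() == B;
  if (have_y) {
    loss = 0.0;
    for (int b = 0; b < B; b++)
      loss -= std::log(std::max(P(y[b], b), 1e-12));
    loss /= B;
  }

  List out = List::create(Named("loss") = loss,
                          Named("probs") = P);
  if (!want_grad) return out;
  if (!have_y) stop("gradients need labels");

  mat dZo = P;
  for (int b = 0; b < B; b++) dZo(y[b], b) -= 1.0;
  dZo /= B;
  mat dWo = dZo * Hd.t();
  vec dbo = arma::sum(dZo, 1);
  mat dHd = Wo.t() * dZo;
  mat dZd = dHd % arma::conv_to<mat>::from(Zd > 0);
  mat dWd = dZd * Xf.t();
  vec dbd = arma::sum(dZd, 1);
  mat dXf = Wd.t() * dZd;

  // unflatten
  mat dA(FL, (arma::uword)hw * B);
  for (int b = 0; b < B; b++)
    for (int f = 0; f < FL; f++)
      for (int p = 0; p < hw; p++)
        dA(f, p + (arma::uword)hw * b) = dXf(f * hw + p, b);

  List dWcL(L), dbcL(L);
  for (int l = L - 1; l >= 0; l--) {
    int Hl = Hs[l];                       // input side of block l
    int Ho = Hl / 2;
    mat Wl = WcL[l];
    // pool backward: scatter dA into pre-pool grid
    const int F = dA.n_rows;
    mat dZr(F, (arma::uword)Hl * Hl * B, arma::fill::zeros);
    for (arma::uword col = 0; col < dA.n_cols; col++)
      for (int f = 0; f < F; f++)
        dZr(f, idxv[l](f, col)) += dA(f, col);
    (void)Ho;
    // relu backward
    dZr %= arma::conv_to<mat>::from(Zv[l] > 0);
    mat dWl = dZr * colsv[l].t();
    vec dbl = arma::sum(dZr, 1);
    dWcL[l] = dWl;
    dbcL[l] = dbl;
    if (l > 0) {
      mat dcols = Wl.t() * dZr;
      const int Cin = ((mat)WcL[l - 1]).n_rows;  // filters of previous block
      dA = col2im3(dcols, Cin, Hl, Hl, B);
    }
  }

  out["grads"] = List::create(Named("Wc") = dWcL, Named("bc") = dbcL,
                              Named("Wd") = dWd, Named("bd") = dbd,
                              Named("Wo") = dWo, Named("bo") = dbo);
  return out;
}

// Bilinear rotation of an H x W x 3 raster (values in [0,1]) about its
// centre; pixels mapped from outside the source take `fill`.
// [[Rcpp::export]]
NumericVector cpp_rotate_bilinear(NumericVector img, double angle_deg,
                                  NumericVector fill) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1];
  NumericVector out(img.size());
  out.attr("dim") = d;
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int j = 0; j < W; j++) {
    for (int i = 0; i < H; i++) {
      // inverse map: rotate output coords by -angle
      const double yr = i - cy, xr = j - cx;
      const double ys = ct * yr + st * xr + cy;
      const double xs = -st * yr + ct * xr + cx;
      const int i0 = (int)std::floor(ys), j0 = (int)std::floor(xs);
      const double fy = ys - i0, fx = xs - j0;
      for (int c = 0; c < 3; c++) {
        double v;
        if (i0 < -1 || i0 > H - 1 || j0 < -1 || j0 > W - 1) {
          v = fill[c];
        } else {
          auto px = [&](int ii, int jj) -> double {
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) return fill[c];
            return img[ii + H * jj + H * W * c];
          };
          v = (1 - fy) * (1 - fx) * px(i0, j0) +
              (1 - fy) * fx * px(i0, j0 + 1) +
              fy * (1 - fx) * px(i0 + 1, j0) +
              fy * fx * px(i0 + 1, j0 + 1);
        }
        out[i + H * j + H * W * c] = v;
      }
    }
  }
  return out;
}

// Bilinear resize of an H x W x 3 raster (values in [0,1]) to out_h x
// out_w, pixel-centre aligned.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector img, int out_h, int out_w) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1];
  NumericVector out((R_xlen_t)out_h * out_w * 3);
  out.attr("dim") = IntegerVector::create(out_h, out_w, 3);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int j = 0; j < out_w; j++) {
    const double xs = (j + 0.5) * sx - 0.5;
    int j0 = (int)std::floor(xs);
    double fx = xs - j0;
    if (j0 < 0) { j0 = 0; fx = 0; }
    if (j0 >= W - 1) { j0 = W - 2 < 0 ? 0 : W - 2; fx = W > 1 ? 1 : 0; }
    for (int i = 0; i < out_h; i++) {
      const double ys = (i + 0.5) * sy - 0.5;
      int i0 = (int)std::floor(ys);
      double fy = ys - i0;
      if (i0 < 0) { i0 = 0; fy = 0; }
      if (i0 >= H - 1) { i0 = H - 2 < 0 ? 0 : H - 2; fy = H > 1 ? 1 : 0; }
      const int i1 = H > 1 ? i0 + 1 : i0, j1 = W > 1 ? j0 + 1 : j0;
      for (int c = 0; c < 3; c++) {
        const double* p = &img[(R_xlen_t)H * W * c];
        const double v =
            (1 - fy) * (1 - fx) * p[i0 + H * j0] +
            (1 - fy) * fx * p[i0 + H * j1] +
            fy * (1 - fx) * p[i1 + H * j0] +
            fy * fx * p[i1 + H * j1];
        out[i + out_h * j + (R_xlen_t)out_h * out_w * c] = v;
      }
    }
  }
  return out;
}
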