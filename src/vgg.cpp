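// Forward pass of a VGG-style convolutional stack (3x3 kernels, stride 1,
// zero padding 1, ReLU, 2x2 max pooling) up to an arbitrary tap layer,
// followed by global average pooling. Single precision: the GEMM dominates
// and float halves time and memory relative to double.
//
// Layout conventions (must match the R-side weight builder):
//  - a feature map is an arma::fmat of shape [C x S*S], spatial position
//    p = x*S + y (column-major image, y = row, x = column);
//  - a conv weight is [C_out x C_in*9], column index c*9 + k with kernel
//    offset k = (dx+1)*3 + (dy+1), dx/dy in {-1,0,1}.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col3x3(const arma::fmat& X, int S, arma::fmat& cols) {
  const int C = X.n_rows;
  cols.set_size(C * 9, S * S);
  cols.zeros();
  for (int x = 0; x < S; ++x) {
    for (int y = 0; y < S; ++y) {
      const int p = x * S + y;
      float* dst = cols.colptr(p);
      for (int dx = -1; dx <= 1; ++dx) {
        const int xx = x + dx;
        if (xx < 0 || xx >= S) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= S) continue;
          const int k = (dx + 1) * 3 + (dy + 1);
          const float* src = X.colptr(xx * S + yy);
          for (int c = 0; c < C; ++c) dst[c * 9 + k] = src[c];
        }
      }
    }
  }
}

static void maxpool2x2(const arma::fmat& X, int S, arma::fmat& out) {
  const int C = X.n_rows, S2 = S / 2;
  out.set_size(C, S2 * S2);
  for (int x2 = 0; x2 < S2; ++x2) {
    for (int y2 = 0; y2 < S2; ++y2) {
      const int x = 2 * x2, y = 2 * y2;
      arma::fvec m = X.col(x * S + y);
      m = arma::max(m, arma::fvec(X.col((x + 1) * S + y)));
      m = arma::max(m, arma::fvec(X.col(x * S + y + 1)));
      m = arma::max(m, arma::fvec(X.col((x + 1) * S + y + 1)));
      out.col(x2 * S2 + y2) = m;
    }
  }
}

// imgs: [C0*side*side x N] doubles, each column one image, value (c, p) at
// index p*C0 + c. layers: list of list(W, b, pool). Returns pooled features
// [C_tap x N] and, if return_maps, the tap feature maps [C_tap x S_tap^2 x N].
// [[Rcpp::export]]
List vgg_forward_cpp(const NumericMatrix& imgs, const List& layers,
                     int side, int in_channels, bool return_maps) {
  const int N = imgs.ncol();
  const int L = layers.size();

  // stage weights once as float
  std::vector<arma::fmat> Ws(L);
  std::vector<arma::fvec> bs(L);
  std::vector<bool> pools(L);
  for (int l = 0; l < L; ++l) {
    List lay = layers[l];
    Ws[l] = arma::conv_to<arma::fmat>::from(
        as<arma::mat>(lay["W"]));
    bs[l] = arma::conv_to<arma::fvec>::from(
        as<arma::vec>(lay["b"]));
    pools[l] = as<bool>(lay["pool"]);
  }

  const int C_tap = Ws[L - 1].n_rows;
  int S_tap = side;
  for (int l = 0; l < L; ++l) if (pools[l]) S_tap /= 2;

  arma::mat feats(C_tap, N);
  NumericVector maps;
  if (return_maps) {
    maps = NumericVector(Dimension(C_tap, S_tap * S_tap, N));
  }

  arma::fmat X, cols, pooled;
  for (int n = 0; n < N; ++n) {
    X.set_size(in_channels, side * side);
    {
      const double* src = &imgs(0, n);
      for (arma::uword i = 0; i < X.n_elem; ++i) X(i) = (float)src[i];
    }
    int S = side;
    for (int l = 0; l < L; ++l) {
      if (pools[l]) {
        maxpool2x2(X, S, pooled);
        S /= 2;
        X = pooled;
      }
      im2col3x3(X, S, cols);
      X = Ws[l] * cols;
      X.each_col() += bs[l];
      X.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    }
    feats.col(n) = arma::conv_to<arma::vec>::from(arma::mean(X, 1));
    if (return_maps) {
      double* dst = &maps[0] + (R_xlen_t)n * C_tap * S_tap * S_tap;
      for (arma::uword i = 0; i < X.n_elem; ++i) dst[i] = X(i);
    }
    if (n % 64 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["features"] = feats);
  if (return_maps) out["maps"] = maps;
  return out;
}
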