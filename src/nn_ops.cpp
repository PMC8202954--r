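// Compact CPU conv-net primitives: im2col + BLAS GEMM convolutions with
// hand-derived backward passes, 2x2 max pooling, nearest-neighbour resizing,
// 8-connected component labelling and masked GLCM pair counting.
//
// Array layout convention (column-major, as R stores them):
//   activations x : dim c(H, W, C, N)
//   weights     w : dim c(kh, kw, Cin, Cout)

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix (K x L, K = kh*kw*Cin, L = Ho*Wo) for one sample.
// Row index r = i + kh*(j + kw*cin); column index l = ho + Ho*wo.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int cin = 0; cin < C; ++cin) {
    const double* xc = x + (size_t)cin * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * cin);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + j - pad;
          double* dst = col.colptr(0) + r; // element (r, l): col(r, ho + Ho*wo)
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) col(r, ho + (size_t)Ho * wo) = 0.0;
            continue;
          }
          const double* xcw = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + i - pad;
            col(r, ho + (size_t)Ho * wo) =
              (hi < 0 || hi >= H) ? 0.0 : xcw[hi];
          }
          (void)dst;
        }
      }
    }
  }
}

// Scatter-add of a col-matrix gradient back onto the input image.
static void col2im(const arma::mat& dcol, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int cin = 0; cin < C; ++cin) {
    double* xc = dx + (size_t)cin * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * cin);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + j - pad;
          if (wi < 0 || wi >= W) continue;
          double* xcw = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + i - pad;
            if (hi >= 0 && hi < H) xcw[hi] += dcol(r, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_forward(NumericVector x, NumericVector w,
                              NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv forward");
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv output would be empty");
  int K = kh * kw * Cin, L = Ho * Wo;

  NumericVector y((R_xlen_t)((size_t)Ho*(size_t)Wo*(size_t)Cout*(size_t)N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, L);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat Y = Wmat.t() * col; // Cout x L
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double bb = b[co];
      double* yc = yn + (size_t)co * L;
      for (int l = 0; l < L; ++l) yc[l] = Y(co, l) + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_backward(NumericVector x, NumericVector w, NumericVector dy,
                      int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  int K = kh * kw * Cin, L = Ho * Wo;

  NumericVector dx((R_xlen_t)((size_t)H*(size_t)W*(size_t)C*(size_t)N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)((size_t)kh*(size_t)kw*(size_t)Cin*(size_t)Cout));
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector db(Cout);
  arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWmat(dw.begin(), K, Cout, false, true);
  arma::mat col(K, L);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat dY(Cout, L);
    const double* dyn = dy.begin() + (size_t)n * L * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + (size_t)co * L;
      for (int l = 0; l < L; ++l) dY(co, l) = dyc[l];
      db[co] += arma::accu(dY.row(co));
    }
    dWmat += col * dY.t();              // K x Cout
    arma::mat dcol = Wmat * dY;         // K x L
    col2im(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
           dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even.
// [[Rcpp::export]]
List nn_maxpool_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool requires even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)((size_t)Ho*(size_t)Wo*(size_t)C*(size_t)N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector amax((R_xlen_t)((size_t)Ho*(size_t)Wo*(size_t)C*(size_t)N));
  amax.attr("dim") = IntegerVector::create(Ho, Wo, C, N); // 0..3: (dh, dw) = (k%2, k/2)
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xp = x.begin() + p * H * W;
    double* yp = y.begin() + p * Ho * Wo;
    int* ap = amax.begin() + p * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int best = 0;
        double bv = xp[(2 * ho) + (size_t)(2 * wo) * H];
        for (int k = 1; k < 4; ++k) {
          double v = xp[(2 * ho + k % 2) + (size_t)(2 * wo + k / 2) * H];
          if (v > bv) { bv = v; best = k; }
        }
        yp[ho + (size_t)wo * Ho] = bv;
        ap[ho + (size_t)wo * Ho] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_backward(NumericVector dy, IntegerVector amax,
                                  int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((R_xlen_t)((size_t)H*(size_t)W*(size_t)C*(size_t)N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* dyp = dy.begin() + p * Ho * Wo;
    const int* ap = amax.begin() + p * Ho * Wo;
    double* dxp = dx.begin() + p * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        int k = ap[ho + (size_t)wo * Ho];
        dxp[(2 * ho + k % 2) + (size_t)(2 * wo + k / 2) * H] +=
          dyp[ho + (size_t)wo * Ho];
      }
  }
  return dx;
}

// Nearest-neighbour resize to (Ho, Wo); source index floor(i * H / Ho).
// [[Rcpp::export]]
NumericVector nn_resize_nearest(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)((size_t)Ho*(size_t)Wo*(size_t)C*(size_t)N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> ri(Ho), ci(Wo);
  for (int i = 0; i < Ho; ++i) ri[i] = std::min((int)((long long)i * H / Ho), H - 1);
  for (int j = 0; j < Wo; ++j) ci[j] = std::min((int)((long long)j * W / Wo), W - 1);
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xp = x.begin() + p * H * W;
    double* yp = y.begin() + p * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        yp[i + (size_t)j * Ho] = xp[ri[i] + (size_t)ci[j] * H];
  }
  return y;
}

// Adjoint of nn_resize_nearest: accumulate output gradients onto sources.
// [[Rcpp::export]]
NumericVector nn_resize_nearest_backward(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((R_xlen_t)((size_t)H*(size_t)W*(size_t)C*(size_t)N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> ri(Ho), ci(Wo);
  for (int i = 0; i < Ho; ++i) ri[i] = std::min((int)((long long)i * H / Ho), H - 1);
  for (int j = 0; j < Wo; ++j) ci[j] = std::min((int)((long long)j * W / Wo), W - 1);
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* dyp = dy.begin() + p * Ho * Wo;
    double* dxp = dx.begin() + p * H * W;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dxp[ri[i] + (size_t)ci[j] * H] += dyp[i + (size_t)j * Ho];
  }
  return dx;
}

// 8-connected component labelling of a logical/0-1 matrix (BFS flood fill).
// Labels are assigned in raster (column-major) discovery order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cc_label8(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int> > queue;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      queue.clear();
      queue.push_back(std::make_pair(i, j));
      while (!queue.empty()) {
        std::pair<int,int> p = queue.back();
        queue.pop_back();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              queue.push_back(std::make_pair(ni, nj));
            }
          }
      }
    }
  }
  return lab;
}

// Raw GLCM pair counts for one set of offsets; both pixels must lie in the
// mask. g holds levels 0..G-1. Counts are NOT symmetrized or normalized here.
// [[Rcpp::export]]
NumericMatrix glcm_pair_counts(IntegerMatrix g, LogicalMatrix mask, int G,
                               IntegerVector drow, IntegerVector dcol) {
  int H = g.nrow(), W = g.ncol(), nOff = drow.size();
  NumericMatrix P(G, G);
  for (int o = 0; o < nOff; ++o) {
    int dr = drow[o], dc = dcol[o];
    for (int j = 0; j < W; ++j) {
      int nj = j + dc;
      if (nj < 0 || nj >= W) continue;
      for (int i = 0; i < H; ++i) {
        int ni = i + dr;
        if (ni < 0 || ni >= H) continue;
        if (mask(i, j) && mask(ni, nj)) {
          int a = g(i, j), b = g(ni, nj);
          if (a < 0 || a >= G || b < 0 || b >= G)
            stop("gray level outside [0, levels)");
          P(a, b) += 1.0;
        }
      }
    }
  }
  return P;
}
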