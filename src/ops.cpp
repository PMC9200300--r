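// Numeric kernels for the encoder-decoder segmenter and component labeling.
// Tensor layout throughout: column-major R arrays [h, w, c, n].

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int dim4(const IntegerVector& d, int k) {
  return k < d.size() ? d[k] : 1;
}

// im2col for same-padding k x k convolution, stride 1.
// Returns (h*w) x (k*k*ci) matrix for image l of x.
static void im2col(const double* x, int h, int w, int ci, int l, int k,
                   arma::mat& A) {
  const int pad = k / 2;
  const long planeImg = (long)h * w * ci;
  int col = 0;
  for (int c = 0; c < ci; ++c) {
    const double* xc = x + (long)l * planeImg + (long)c * h * w;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di, ++col) {
        double* Acol = A.colptr(col);
        for (int j = 0; j < w; ++j) {
          int sj = j + dj - pad;
          if (sj < 0 || sj >= w) {
            std::fill(Acol + (long)j * h, Acol + (long)(j + 1) * h, 0.0);
            continue;
          }
          const double* src = xc + (long)sj * h;
          double* dst = Acol + (long)j * h;
          for (int i = 0; i < h; ++i) {
            int si = i + di - pad;
            dst[i] = (si < 0 || si >= h) ? 0.0 : src[si];
          }
        }
      }
    }
  }
}

// scatter-add of column matrix dA back onto the input gradient (col2im)
static void col2im_add(double* dx, int h, int w, int ci, int l, int k,
                       const arma::mat& dA) {
  const int pad = k / 2;
  const long planeImg = (long)h * w * ci;
  int col = 0;
  for (int c = 0; c < ci; ++c) {
    double* xc = dx + (long)l * planeImg + (long)c * h * w;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di, ++col) {
        const double* Acol = dA.colptr(col);
        for (int j = 0; j < w; ++j) {
          int sj = j + dj - pad;
          if (sj < 0 || sj >= w) continue;
          double* dst = xc + (long)sj * h;
          const double* src = Acol + (long)j * h;
          for (int i = 0; i < h; ++i) {
            int si = i + di - pad;
            if (si >= 0 && si < h) dst[si] += src[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector Wt, NumericVector b) {
  IntegerVector dx = x.attr("dim"), dw = Wt.attr("dim");
  int h = dx[0], w = dx[1], ci = dim4(dx, 2), n = dim4(dx, 3);
  int k = dw[0], co = dim4(dw, 3);
  if (dw[1] != k || dim4(dw, 2) != ci)
    stop("weight dims incompatible with input");
  arma::mat Wm(const_cast<double*>(Wt.begin()), (long)k * k * ci, co, false);
  NumericVector y((long)h * w * co * n);
  y.attr("dim") = IntegerVector::create(h, w, co, n);
  arma::mat A(h * (long)w, (long)k * k * ci);
  for (int l = 0; l < n; ++l) {
    im2col(x.begin(), h, w, ci, l, k, A);
    arma::mat Y(y.begin() + (long)l * h * w * co, h * (long)w, co, false, true);
    Y = A * Wm;
    for (int c = 0; c < co; ++c) Y.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector Wt, NumericVector dy) {
  IntegerVector dxd = x.attr("dim"), dw = Wt.attr("dim");
  int h = dxd[0], w = dxd[1], ci = dim4(dxd, 2), n = dim4(dxd, 3);
  int k = dw[0], co = dim4(dw, 3);
  arma::mat Wm(const_cast<double*>(Wt.begin()), (long)k * k * ci, co, false);
  NumericVector dx((long)h * w * ci * n);
  dx.attr("dim") = IntegerVector::create(h, w, ci, n);
  NumericVector dW((long)k * k * ci * co);
  dW.attr("dim") = IntegerVector::create(k, k, ci, co);
  NumericVector db(co);
  arma::mat dWm(dW.begin(), (long)k * k * ci, co, false, true);
  arma::mat A(h * (long)w, (long)k * k * ci);
  for (int l = 0; l < n; ++l) {
    arma::mat dY(const_cast<double*>(dy.begin()) + (long)l * h * w * co,
                 h * (long)w, co, false);
    im2col(x.begin(), h, w, ci, l, k, A);
    dWm += A.t() * dY;
    arma::mat dA = dY * Wm.t();
    col2im_add(dx.begin(), h, w, ci, l, k, dA);
    for (int c = 0; c < co; ++c) db[c] += arma::accu(dY.col(c));
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2. Input spatial dims must be even.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], c = dim4(d, 2), n = dim4(d, 3);
  if (h % 2 || w % 2) stop("maxpool2 requires even spatial dims");
  int ho = h / 2, wo = w / 2;
  NumericVector y((long)ho * wo * c * n);
  IntegerVector arg((long)ho * wo * c * n); // linear index into x
  y.attr("dim") = IntegerVector::create(ho, wo, c, n);
  const double* xp = x.begin();
  long o = 0;
  for (long p = 0; p < (long)c * n; ++p) {
    const long base = p * h * w;
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < ho; ++i, ++o) {
        long i0 = base + (long)(2 * j) * h + 2 * i;
        long cand[4] = {i0, i0 + 1, i0 + h, i0 + h + 1};
        long best = cand[0];
        for (int t = 1; t < 4; ++t)
          if (xp[cand[t]] > xp[best]) best = cand[t];
        y[o] = xp[best];
        arg[o] = (int)best;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector argmax,
                           IntegerVector xdim) {
  long nx = 1;
  for (int i = 0; i < xdim.size(); ++i) nx *= xdim[i];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (long o = 0; o < dy.size(); ++o) dx[argmax[o]] += dy[o];
  return dx;
}

// 8-connected component labeling, labels 1..K in row-major raster order of
// each component's first pixel (matching the particle-analyzer convention).
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(IntegerMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  std::vector<int> parent(1, 0);
  IntegerMatrix lab(h, w);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  // first pass, row-major
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (!mask(i, j)) continue;
      int neigh[4][2] = {{i - 1, j - 1}, {i - 1, j}, {i - 1, j + 1}, {i, j - 1}};
      int cur = 0;
      for (auto& nb : neigh) {
        int ni = nb[0], nj = nb[1];
        if (ni < 0 || nj < 0 || nj >= w) continue;
        int l = lab(ni, nj);
        if (l) cur = cur ? std::min(cur, find(l)) : find(l);
      }
      if (!cur) {
        cur = (int)parent.size();
        parent.push_back(cur);
      } else {
        for (auto& nb : neigh) {
          int ni = nb[0], nj = nb[1];
          if (ni < 0 || nj < 0 || nj >= w) continue;
          if (lab(ni, nj)) unite(cur, lab(ni, nj));
        }
      }
      lab(i, j) = cur;
    }
  }
  // second pass: relabel roots in raster order of first appearance
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (!lab(i, j)) continue;
      int r = find(lab(i, j));
      if (!newlab[r]) newlab[r] = ++next;
      lab(i, j) = newlab[r];
    }
  }
  return lab;
}
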