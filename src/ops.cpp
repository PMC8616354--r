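// Low-level image and network kernels.
// Images are numeric matrices (rows = y, cols = x); activation tensors are
// H x W x C cubes. Everything here is deterministic and single-threaded.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// convolution (same padding, odd kernel) via im2col
// ---------------------------------------------------------------------------

static arma::mat im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, r = k / 2;
  arma::mat cols(k * k * C, (size_t)H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -r; dj <= r; ++dj) {
      for (int di = -r; di <= r; ++di) {
        const int rowIdx = c * k * k + (dj + r) * k + (di + r);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + di;
            if (is < 0 || is >= H) continue;
            cols(rowIdx, (size_t)j * H + i) = x(is, js, c);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add(arma::cube& dx, const arma::mat& cols, int k) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices, r = k / 2;
  for (int c = 0; c < C; ++c) {
    for (int dj = -r; dj <= r; ++dj) {
      for (int di = -r; di <= r; ++di) {
        const int rowIdx = c * k * k + (dj + r) * k + (di + r);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + di;
            if (is < 0 || is >= H) continue;
            dx(is, js, c) += cols(rowIdx, (size_t)j * H + i);
          }
        }
      }
    }
  }
}

// W: (k*k*Cin) x Cout, b: Cout
// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, int k) {
  const int H = x.n_rows, Wd = x.n_cols, Cout = W.n_cols;
  arma::mat cols = im2col(x, k);
  arma::mat out = W.t() * cols;        // Cout x (H*W)
  out.each_col() += b;
  arma::cube y(H, Wd, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = arma::reshape(out.row(c), H, Wd);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(const arma::cube& x, const arma::mat& W,
                         const arma::cube& dout, int k) {
  const int H = x.n_rows, Wd = x.n_cols, Cout = W.n_cols;
  arma::mat G(Cout, (size_t)H * Wd);
  for (int c = 0; c < Cout; ++c)
    G.row(c) = arma::vectorise(dout.slice(c)).t();
  arma::mat cols = im2col(x, k);
  arma::mat dW = cols * G.t();
  arma::vec db = arma::sum(G, 1);
  arma::mat dcols = W * G;             // (k*k*Cin) x (H*W)
  arma::cube dx(H, Wd, x.n_slices, arma::fill::zeros);
  col2im_add(dx, dcols, k);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---------------------------------------------------------------------------
// 2x2 max-pool / nearest-neighbour upsample
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2(const arma::cube& x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  arma::cube out(H, W, C), idx(H, W, C);  // idx in 0..3: (di, dj) = (idx%2, idx/2)
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bi = 0;
        for (int q = 1; q < 4; ++q) {
          double v = x(2 * i + q % 2, 2 * j + q / 2, c);
          if (v > best) { best = v; bi = q; }
        }
        out(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_backward(const arma::cube& dout, const arma::cube& idx) {
  const int H = dout.n_rows, W = dout.n_cols, C = dout.n_slices;
  arma::cube dx(2 * H, 2 * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        int q = (int)idx(i, j, c);
        dx(2 * i + q % 2, 2 * j + q / 2, c) = dout(i, j, c);
      }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_backward(const arma::cube& dout) {
  const int H = dout.n_rows / 2, W = dout.n_cols / 2, C = dout.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dout(2 * i, 2 * j, c) + dout(2 * i + 1, 2 * j, c) +
                      dout(2 * i, 2 * j + 1, c) + dout(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// ---------------------------------------------------------------------------
// separable Gaussian blur, symmetric (mirror) boundary
// ---------------------------------------------------------------------------

static int reflect_idx(int i, int n) {
  // symmetric reflection without edge repetition fallback: -1 -> 0, n -> n-1
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
arma::mat cpp_gauss_blur(const arma::mat& img, double sigma) {
  if (sigma <= 0) return img;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec kern(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    kern(i + r) = std::exp(-0.5 * i * i / (sigma * sigma));
  kern /= arma::accu(kern);
  const int H = img.n_rows, W = img.n_cols;
  arma::mat tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int d = -r; d <= r; ++d) s += kern(d + r) * img(reflect_idx(i + d, H), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int d = -r; d <= r; ++d) s += kern(d + r) * tmp(i, reflect_idx(j + d, W));
      out(i, j) = s;
    }
  return out;
}

// ---------------------------------------------------------------------------
// grayscale morphology with an arbitrary structuring element (offsets+heights)
// out-of-image offsets are ignored so a constant image is a fixed point of
// the opening -- required for rolling-ball background subtraction
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_grey_erode(const arma::mat& img, const arma::imat& off,
                         const arma::vec& h) {
  const int H = img.n_rows, W = img.n_cols, n = off.n_rows;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double m = R_PosInf;
      for (int q = 0; q < n; ++q) {
        int ii = i + off(q, 0), jj = j + off(q, 1);
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        double v = img(ii, jj) - h(q);
        if (v < m) m = v;
      }
      out(i, j) = m;
    }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_grey_dilate(const arma::mat& img, const arma::imat& off,
                          const arma::vec& h) {
  const int H = img.n_rows, W = img.n_cols, n = off.n_rows;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double m = R_NegInf;
      for (int q = 0; q < n; ++q) {
        int ii = i + off(q, 0), jj = j + off(q, 1);
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        double v = img(ii, jj) + h(q);
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  return out;
}

// ---------------------------------------------------------------------------
// connected components (BFS), hole filling, contour tracing
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int d = 0; d < nn; ++d) {
          int ii = p.first + dr[d], jj = p.second + dc[d];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (mask(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  return lab;
}

// fill background regions not 4-connected to the border
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix reach(H, W);
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if ((i == 0 || i == H - 1 || j == 0 || j == W - 1) && !mask(i, j) &&
          !reach(i, j)) {
        reach(i, j) = true;
        q.push(std::make_pair(i, j));
      }
    }
  }
  const int dr[] = {-1, 1, 0, 0}, dc[] = {0, 0, -1, 1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int d = 0; d < 4; ++d) {
      int ii = p.first + dr[d], jj = p.second + dc[d];
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      if (!mask(ii, jj) && !reach(ii, jj)) {
        reach(ii, jj) = true;
        q.push(std::make_pair(ii, jj));
      }
    }
  }
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) out(i, j) = mask(i, j) || !reach(i, j);
  return out;
}

// Moore-neighbour boundary tracing of a single 8-connected component with
// the (pixel, backtrack)-state stopping criterion. Returns an n x 2 matrix
// of 0-based (x = col, y = row) boundary pixel centres, ordered; the caller
// fixes orientation.
// [[Rcpp::export]]
NumericMatrix cpp_trace_contour(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  // clockwise Moore neighbourhood starting at W
  const int dr[] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[] = {-1, -1, 0, 1, 1, 1, 0, -1};
  int si = -1, sj = -1;
  for (int i = 0; i < H && si < 0; ++i)
    for (int j = 0; j < W; ++j)
      if (mask(i, j)) { si = i; sj = j; break; }
  if (si < 0) return NumericMatrix(0, 2);
  std::vector<std::pair<int, int> > pts;
  pts.push_back(std::make_pair(si, sj));
  int ci = si, cj = sj;
  int bdir = 0;  // direction from current pixel to its backtrack (starts west)
  const int p0i = si, p0j = sj, b0 = bdir;
  long guard = 0;
  const long maxit = 8L * (long)H * W + 16;
  while (guard++ < maxit) {
    int found = -1;
    for (int s = 1; s <= 8; ++s) {
      int d = (bdir + s) % 8;
      int ii = ci + dr[d], jj = cj + dc[d];
      if (ii >= 0 && ii < H && jj >= 0 && jj < W && mask(ii, jj)) {
        found = d;
        // backtrack of the next pixel: the neighbour examined just before
        // the hit, expressed as a direction from the next pixel
        int li = ci + dr[(d + 7) % 8], lj = cj + dc[(d + 7) % 8];
        if (s == 1) { li = ci + dr[bdir]; lj = cj + dc[bdir]; }
        int ndir = 0;
        for (int t = 0; t < 8; ++t)
          if (ii + dr[t] == li && jj + dc[t] == lj) { ndir = t; break; }
        ci = ii; cj = jj; bdir = ndir;
        break;
      }
    }
    if (found < 0) break;  // isolated pixel
    if (ci == p0i && cj == p0j && bdir == b0) break;
    pts.push_back(std::make_pair(ci, cj));
  }
  NumericMatrix out(pts.size(), 2);
  for (size_t k = 0; k < pts.size(); ++k) {
    out(k, 0) = pts[k].second;  // x = col
    out(k, 1) = pts[k].first;   // y = row
  }
  return out;
}

// ---------------------------------------------------------------------------
// resize (bilinear for intensities, nearest for masks)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_resize_bilinear(const arma::mat& img, int nh, int nw) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat out(nh, nw);
  const double sy = (double)H / nh, sx = (double)W / nw;
  for (int j = 0; j < nw; ++j)
    for (int i = 0; i < nh; ++i) {
      double y = (i + 0.5) * sy - 0.5, x = (j + 0.5) * sx - 0.5;
      int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
      double fy = y - y0, fx = x - x0;
      int y1 = y0 + 1, x1 = x0 + 1;
      y0 = std::min(std::max(y0, 0), H - 1);
      y1 = std::min(std::max(y1, 0), H - 1);
      x0 = std::min(std::max(x0, 0), W - 1);
      x1 = std::min(std::max(x1, 0), W - 1);
      out(i, j) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_resize_nearest(const LogicalMatrix& img, int nh, int nw) {
  const int H = img.nrow(), W = img.ncol();
  LogicalMatrix out(nh, nw);
  const double sy = (double)H / nh, sx = (double)W / nw;
  for (int j = 0; j < nw; ++j)
    for (int i = 0; i < nh; ++i) {
      int y = std::min((int)((i + 0.5) * sy), H - 1);
      int x = std::min((int)((j + 0.5) * sx), W - 1);
      out(i, j) = img(y, x);
    }
  return out;
}
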