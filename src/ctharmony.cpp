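#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are column-major arrays of dim (H, W, C).
// im2col rows index output positions p = h + H_out * w (h fastest, matching R
// array flattening); columns index (kh, kw, c) with kh fastest.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  int H_out = (H + 2 * pad - k) / stride + 1;
  int W_out = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(H_out * W_out, C * k * k);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * kw + k * k * c;
        for (int w = 0; w < W_out; ++w) {
          int iw = w * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H_out; ++h) {
            int ih = h * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            out(h + H_out * w, col) = x[ih + H * iw + H * W * c];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col (scatter-add).
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  int H_out = (H + 2 * pad - k) / stride + 1;
  int W_out = (W + 2 * pad - k) / stride + 1;
  NumericVector out(H * W * C);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * kw + k * k * c;
        for (int w = 0; w < W_out; ++w) {
          int iw = w * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H_out; ++h) {
            int ih = h * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            out[ih + H * iw + H * W * c] += cols(h + H_out * w, col);
          }
        }
      }
    }
  }
  return out;
}

// Resample a 3D array to new dimensions. mode 0 = trilinear, 1 = nearest.
// Coordinate mapping follows the pixel-center convention
//   x_in = (i_out + 0.5) * (n_in / n_out) - 0.5
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector x, IntegerVector din,
                             IntegerVector dout, int mode) {
  int H = din[0], W = din[1], D = din[2];
  int h2 = dout[0], w2 = dout[1], d2 = dout[2];
  NumericVector out(static_cast<R_xlen_t>(h2) * w2 * d2);
  double sh = static_cast<double>(H) / h2;
  double sw = static_cast<double>(W) / w2;
  double sd = static_cast<double>(D) / d2;
  for (int k = 0; k < d2; ++k) {
    double z = (k + 0.5) * sd - 0.5;
    for (int j = 0; j < w2; ++j) {
      double y = (j + 0.5) * sw - 0.5;
      for (int i = 0; i < h2; ++i) {
        double xx = (i + 0.5) * sh - 0.5;
        double val;
        if (mode == 1) {
          int ii = std::min(std::max(static_cast<int>(std::lround(xx)), 0), H - 1);
          int jj = std::min(std::max(static_cast<int>(std::lround(y)), 0), W - 1);
          int kk = std::min(std::max(static_cast<int>(std::lround(z)), 0), D - 1);
          val = x[ii + H * jj + H * W * kk];
        } else {
          double cx = std::min(std::max(xx, 0.0), H - 1.0);
          double cy = std::min(std::max(y, 0.0), W - 1.0);
          double cz = std::min(std::max(z, 0.0), D - 1.0);
          int x0 = static_cast<int>(std::floor(cx)), x1 = std::min(x0 + 1, H - 1);
          int y0 = static_cast<int>(std::floor(cy)), y1 = std::min(y0 + 1, W - 1);
          int z0 = static_cast<int>(std::floor(cz)), z1 = std::min(z0 + 1, D - 1);
          double fx = cx - x0, fy = cy - y0, fz = cz - z0;
          double c00 = x[x0 + H * y0 + H * W * z0] * (1 - fx) + x[x1 + H * y0 + H * W * z0] * fx;
          double c10 = x[x0 + H * y1 + H * W * z0] * (1 - fx) + x[x1 + H * y1 + H * W * z0] * fx;
          double c01 = x[x0 + H * y0 + H * W * z1] * (1 - fx) + x[x1 + H * y0 + H * W * z1] * fx;
          double c11 = x[x0 + H * y1 + H * W * z1] * (1 - fx) + x[x1 + H * y1 + H * W * z1] * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          val = c0 * (1 - fz) + c1 * fz;
        }
        out[i + static_cast<R_xlen_t>(h2) * j + static_cast<R_xlen_t>(h2) * w2 * k] = val;
      }
    }
  }
  return out;
}

static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// Co-occurrence counts for the 13 unique 3D directions at a given distance.
// lv: discretized levels (1..Ng), 0 outside the ROI. Returns Ng x Ng x 13
// symmetric count arrays.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector lv, IntegerVector dim, int Ng, int dist) {
  int H = dim[0], W = dim[1], D = dim[2];
  NumericVector out(static_cast<R_xlen_t>(Ng) * Ng * 13);
  for (int d = 0; d < 13; ++d) {
    int dh = DIRS[d][0] * dist, dw = DIRS[d][1] * dist, dz = DIRS[d][2] * dist;
    for (int z = 0; z < D; ++z) {
      int z2 = z + dz;
      if (z2 < 0 || z2 >= D) continue;
      for (int w = 0; w < W; ++w) {
        int w2 = w + dw;
        if (w2 < 0 || w2 >= W) continue;
        for (int h = 0; h < H; ++h) {
          int h2 = h + dh;
          if (h2 < 0 || h2 >= H) continue;
          int a = lv[h + H * w + H * W * z];
          int b = lv[h2 + H * w2 + H * W * z2];
          if (a > 0 && b > 0) {
            out[(a - 1) + Ng * (b - 1) + static_cast<R_xlen_t>(Ng) * Ng * d] += 1;
            out[(b - 1) + Ng * (a - 1) + static_cast<R_xlen_t>(Ng) * Ng * d] += 1;
          }
        }
      }
    }
  }
  return out;
}

// Run-length counts per direction: list of 13 (Ng x max_len) matrices.
// A run is a maximal same-level in-ROI segment along the direction.
// [[Rcpp::export]]
List cpp_glrlm(IntegerVector lv, IntegerVector dim, int Ng) {
  int H = dim[0], W = dim[1], D = dim[2];
  int Lmax = std::max(H, std::max(W, D));
  List res(13);
  for (int d = 0; d < 13; ++d) {
    int dh = DIRS[d][0], dw = DIRS[d][1], dz = DIRS[d][2];
    NumericMatrix m(Ng, Lmax);
    for (int z = 0; z < D; ++z) {
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          int a = lv[h + H * w + H * W * z];
          if (a == 0) continue;
          // run start: predecessor out of bounds, outside ROI, or different level
          int ph = h - dh, pw = w - dw, pz = z - dz;
          bool start = ph < 0 || ph >= H || pw < 0 || pw >= W || pz < 0 || pz >= D;
          if (!start) {
            int p = lv[ph + H * pw + H * W * pz];
            start = (p != a);
          }
          if (!start) continue;
          int len = 1;
          int ch = h + dh, cw = w + dw, cz = z + dz;
          while (ch >= 0 && ch < H && cw >= 0 && cw < W && cz >= 0 && cz < D &&
                 lv[ch + H * cw + H * W * cz] == a) {
            ++len;
            ch += dh; cw += dw; cz += dz;
          }
          m(a - 1, len - 1) += 1;
        }
      }
    }
    res[d] = m;
  }
  return res;
}

// Connected zones (26-connectivity) of equal level: matrix of (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector lv, IntegerVector dim) {
  int H = dim[0], W = dim[1], D = dim[2];
  R_xlen_t n = static_cast<R_xlen_t>(H) * W * D;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (lv[s] == 0 || seen[s]) continue;
    int level = lv[s];
    int size = 0;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      ++size;
      int h = cur % H;
      int w = (cur / H) % W;
      int z = cur / (static_cast<R_xlen_t>(H) * W);
      for (int dz = -1; dz <= 1; ++dz) {
        int z2 = z + dz;
        if (z2 < 0 || z2 >= D) continue;
        for (int dw = -1; dw <= 1; ++dw) {
          int w2 = w + dw;
          if (w2 < 0 || w2 >= W) continue;
          for (int dh = -1; dh <= 1; ++dh) {
            if (dh == 0 && dw == 0 && dz == 0) continue;
            int h2 = h + dh;
            if (h2 < 0 || h2 >= H) continue;
            R_xlen_t idx = h2 + static_cast<R_xlen_t>(H) * w2 +
                           static_cast<R_xlen_t>(H) * W * z2;
            if (!seen[idx] && lv[idx] == level) {
              seen[idx] = 1;
              stack.push_back(idx);
            }
          }
        }
      }
    }
    zl.push_back(level);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) {
    out(i, 0) = zl[i];
    out(i, 1) = zs[i];
  }
  return out;
}
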