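// Low-level tensor kernels for the 3D networks.
// Layout convention for all 4D tensors: dim = (C, X, Y, Z), column-major
// (channel fastest), i.e. linear index c + C*(x + X*(y + Y*z)).
#include <Rcpp.h>
using namespace Rcpp;

// im2col for a 3D convolution with odd kernel k, stride 1, zero padding
// (k-1)/2. Output matrix: (Cin*k^3) x (X*Y*Z); row index c + Cin*t with
// tap index t = dx + k*(dy + k*dz), offsets dx,dy,dz in 0..k-1.
// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], X = d[1], Y = d[2], Z = d[3];
  const int pad = (k - 1) / 2, K3 = k * k * k;
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  NumericMatrix cols((R_xlen_t)C * K3, N);
  const double* px = x.begin();
  double* pc = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)C * K3;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xx = 0; xx < X; ++xx) {
        const R_xlen_t col = (R_xlen_t)xx + (R_xlen_t)X * (y + (R_xlen_t)Y * z);
        double* out = pc + col * nrow;
        for (int dz = 0; dz < k; ++dz) {
          const int sz = z + dz - pad;
          for (int dy = 0; dy < k; ++dy) {
            const int sy = y + dy - pad;
            for (int dx = 0; dx < k; ++dx) {
              const int sx = xx + dx - pad;
              const int t = dx + k * (dy + k * dz);
              double* dst = out + (R_xlen_t)C * t;
              if (sx < 0 || sx >= X || sy < 0 || sy >= Y || sz < 0 || sz >= Z) {
                for (int c = 0; c < C; ++c) dst[c] = 0.0;
              } else {
                const double* src = px + (R_xlen_t)C * (sx + (R_xlen_t)X * (sy + (R_xlen_t)Y * sz));
                for (int c = 0; c < C; ++c) dst[c] = src[c];
              }
            }
          }
        }
      }
  return cols;
}

// Adjoint of im2col3: scatter-add columns back into a (C,X,Y,Z) tensor.
// [[Rcpp::export(name = ".col2im3")]]
NumericVector col2im3(NumericMatrix cols, IntegerVector dims, int k) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int pad = (k - 1) / 2, K3 = k * k * k;
  NumericVector x((R_xlen_t)C * X * Y * Z);
  x.attr("dim") = dims;
  double* px = x.begin();
  const double* pc = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)C * K3;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xx = 0; xx < X; ++xx) {
        const R_xlen_t col = (R_xlen_t)xx + (R_xlen_t)X * (y + (R_xlen_t)Y * z);
        const double* in = pc + col * nrow;
        for (int dz = 0; dz < k; ++dz) {
          const int sz = z + dz - pad;
          if (sz < 0 || sz >= Z) continue;
          for (int dy = 0; dy < k; ++dy) {
            const int sy = y + dy - pad;
            if (sy < 0 || sy >= Y) continue;
            for (int dx = 0; dx < k; ++dx) {
              const int sx = xx + dx - pad;
              if (sx < 0 || sx >= X) continue;
              const int t = dx + k * (dy + k * dz);
              const double* src = in + (R_xlen_t)C * t;
              double* dst = px + (R_xlen_t)C * (sx + (R_xlen_t)X * (sy + (R_xlen_t)Y * sz));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
  return x;
}

// 2x2x2 max pooling, stride 2. Returns pooled tensor and 1-based linear
// argmax indices into the input.
// [[Rcpp::export(name = ".maxpool3_fw")]]
List maxpool3_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], X = d[1], Y = d[2], Z = d[3];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector out((R_xlen_t)C * Xo * Yo * Zo);
  IntegerVector idx((R_xlen_t)C * Xo * Yo * Zo);
  out.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  idx.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  const double* px = x.begin();
  for (int z = 0; z < Zo; ++z)
    for (int y = 0; y < Yo; ++y)
      for (int xx = 0; xx < Xo; ++xx) {
        const R_xlen_t o = (R_xlen_t)C * (xx + (R_xlen_t)Xo * (y + (R_xlen_t)Yo * z));
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; R_xlen_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const R_xlen_t i = c + (R_xlen_t)C * ((2 * xx + dx) +
                    (R_xlen_t)X * ((2 * y + dy) + (R_xlen_t)Y * (2 * z + dz)));
                if (px[i] > best) { best = px[i]; bi = i; }
              }
          out[o + c] = best;
          idx[o + c] = (int)(bi + 1);
        }
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3_bw")]]
NumericVector maxpool3_bw(NumericVector g, IntegerVector idx, IntegerVector dims) {
  NumericVector dx((R_xlen_t)dims[0] * dims[1] * dims[2] * dims[3]);
  dx.attr("dim") = dims;
  for (R_xlen_t i = 0; i < g.size(); ++i) dx[idx[i] - 1] += g[i];
  return dx;
}

// Rearrange (Cout*8) x N matrix into (Cout, 2X, 2Y, 2Z): transpose
// convolution kernel 2, stride 2. Row index of m: cout + Cout*t with
// t = dx + 2*(dy + 2*dz); column index: input voxel x + X*(y + Y*z).
// [[Rcpp::export(name = ".block_expand2")]]
NumericVector block_expand2(NumericMatrix m, int Cout, IntegerVector in_sp) {
  const int X = in_sp[0], Y = in_sp[1], Z = in_sp[2];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector out((R_xlen_t)Cout * Xo * Yo * Zo);
  out.attr("dim") = IntegerVector::create(Cout, Xo, Yo, Zo);
  const double* pm = m.begin();
  double* po = out.begin();
  const R_xlen_t nrow = (R_xlen_t)Cout * 8;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xx = 0; xx < X; ++xx) {
        const double* colp = pm + nrow * ((R_xlen_t)xx + (R_xlen_t)X * (y + (R_xlen_t)Y * z));
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const int t = dx + 2 * (dy + 2 * dz);
              double* dst = po + (R_xlen_t)Cout * ((2 * xx + dx) +
                  (R_xlen_t)Xo * ((2 * y + dy) + (R_xlen_t)Yo * (2 * z + dz)));
              const double* src = colp + (R_xlen_t)Cout * t;
              for (int c = 0; c < Cout; ++c) dst[c] = src[c];
            }
      }
  return out;
}

// Adjoint of block_expand2: gather a (Cout, 2X, 2Y, 2Z) tensor back into
// the (Cout*8) x N matrix.
// [[Rcpp::export(name = ".block_collapse2")]]
NumericMatrix block_collapse2(NumericVector g, IntegerVector in_sp) {
  IntegerVector d = g.attr("dim");
  const int Cout = d[0];
  const int X = in_sp[0], Y = in_sp[1], Z = in_sp[2];
  const int Xo = 2 * X, Yo = 2 * Y;
  NumericMatrix m((R_xlen_t)Cout * 8, (R_xlen_t)X * Y * Z);
  const double* pg = g.begin();
  double* pm = m.begin();
  const R_xlen_t nrow = (R_xlen_t)Cout * 8;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xx = 0; xx < X; ++xx) {
        double* colp = pm + nrow * ((R_xlen_t)xx + (R_xlen_t)X * (y + (R_xlen_t)Y * z));
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const int t = dx + 2 * (dy + 2 * dz);
              const double* src = pg + (R_xlen_t)Cout * ((2 * xx + dx) +
                  (R_xlen_t)Xo * ((2 * y + dy) + (R_xlen_t)Yo * (2 * z + dz)));
              double* dst = colp + (R_xlen_t)Cout * t;
              for (int c = 0; c < Cout; ++c) dst[c] = src[c];
            }
      }
  return m;
}
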