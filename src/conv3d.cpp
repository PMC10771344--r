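// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// 3-D convolution primitives for volumetric feature maps.
//
// Layout (R column-major):
//   feature maps: dim (X, Y, Z, C)
//   weights:      dim (K, K, K, Cin, Cout), K odd, 'same' zero padding
//
// The correlation convention of deep-learning frameworks is used:
//   y[x,y,z,o] = b[o] + sum_{c,dx,dy,dz} w[dx+h,dy+h,dz+h,c,o] * in[x+dx,y+dy,z+dz,c]
//
// All three passes route through an im2col patch matrix so the heavy
// contraction is a single BLAS GEMM; the gather/scatter copies run over
// contiguous x-segments.

// Build P (n_vox x K^3*Cin): column (dx,dy,dz,c) holds the input shifted
// by (dx,dy,dz), zero-padded; column order matches the weight layout.
static arma::mat im2col3(const double* in, int X, int Y, int Z, int Cin,
                         int K) {
  const int h = K / 2;
  const arma::uword nvox = (arma::uword)X * Y * Z;
  arma::mat P(nvox, (arma::uword)K * K * K * Cin, arma::fill::zeros);
  arma::uword col = 0;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = in + (size_t)X * Y * Z * c;
    for (int dz = -h; dz <= h; ++dz) {
      for (int dy = -h; dy <= h; ++dy) {
        for (int dx = -h; dx <= h; ++dx, ++col) {
          double* pc = P.colptr(col);
          const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
          const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
          const int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
          if (x1 <= x0) continue;
          for (int z = z0; z < z1; ++z) {
            for (int yy = y0; yy < y1; ++yy) {
              double* dst = pc + (size_t)x0 + (size_t)X * (yy + (size_t)Y * z);
              const double* src = xc + (size_t)(x0 + dx) +
                (size_t)X * ((yy + dy) + (size_t)Y * (z + dz));
              std::memcpy(dst, src, sizeof(double) * (x1 - x0));
            }
          }
        }
      }
    }
  }
  // column order built above is (dx, dy, dz) fastest then c, matching
  // the (K, K, K, Cin) leading dimensions of the weight array
  return P;
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector input, NumericVector weights,
                         NumericVector bias, IntegerVector in_dim,
                         IntegerVector w_dim) {
  const int X = in_dim[0], Y = in_dim[1], Z = in_dim[2], Cin = in_dim[3];
  const int K = w_dim[0], Cout = w_dim[4];
  arma::mat P = im2col3(input.begin(), X, Y, Z, Cin, K);
  arma::mat W(weights.begin(), (arma::uword)K * K * K * Cin, Cout, false);
  arma::mat Ymat = P * W;
  Ymat.each_row() += arma::rowvec(bias.begin(), Cout);
  NumericVector out(Ymat.begin(), Ymat.end());
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  return out;
}

// Gradient w.r.t. the input: scatter-add of gY * W^T back onto the grid
// [[Rcpp::export]]
NumericVector conv3d_bwd_input(NumericVector gout, NumericVector weights,
                               IntegerVector in_dim, IntegerVector w_dim) {
  const int X = in_dim[0], Y = in_dim[1], Z = in_dim[2], Cin = in_dim[3];
  const int K = w_dim[0], Cout = w_dim[4];
  const int h = K / 2;
  const arma::uword nvox = (arma::uword)X * Y * Z;
  arma::mat GY(gout.begin(), nvox, Cout, false);
  arma::mat W(weights.begin(), (arma::uword)K * K * K * Cin, Cout, false);
  arma::mat GP = GY * W.t();  // n_vox x K^3*Cin
  NumericVector gin((R_xlen_t)nvox * Cin);
  double* gx = gin.begin();
  arma::uword col = 0;
  for (int c = 0; c < Cin; ++c) {
    double* gxc = gx + (size_t)nvox * c;
    for (int dz = -h; dz <= h; ++dz) {
      for (int dy = -h; dy <= h; ++dy) {
        for (int dx = -h; dx <= h; ++dx, ++col) {
          const double* pc = GP.colptr(col);
          const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
          const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
          const int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
          if (x1 <= x0) continue;
          for (int z = z0; z < z1; ++z) {
            for (int yy = y0; yy < y1; ++yy) {
              double* dst = gxc + (size_t)(x0 + dx) +
                (size_t)X * ((yy + dy) + (size_t)Y * (z + dz));
              const double* src = pc + (size_t)x0 +
                (size_t)X * (yy + (size_t)Y * z);
              const int n = x1 - x0;
              for (int i = 0; i < n; ++i) dst[i] += src[i];
            }
          }
        }
      }
    }
  }
  gin.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  return gin;
}

// Gradients w.r.t. weights and bias: gW = P^T gY, gb = colsums(gY)
// [[Rcpp::export]]
List conv3d_bwd_weight(NumericVector input, NumericVector gout,
                       IntegerVector in_dim, IntegerVector w_dim) {
  const int X = in_dim[0], Y = in_dim[1], Z = in_dim[2], Cin = in_dim[3];
  const int K = w_dim[0], Cout = w_dim[4];
  const arma::uword nvox = (arma::uword)X * Y * Z;
  arma::mat P = im2col3(input.begin(), X, Y, Z, Cin, K);
  arma::mat GY(gout.begin(), nvox, Cout, false);
  arma::mat GW = P.t() * GY;
  arma::rowvec gb = arma::sum(GY, 0);
  NumericVector gw(GW.begin(), GW.end());
  return List::create(Named("weights") = gw,
                      Named("bias") = NumericVector(gb.begin(), gb.end()));
}

// Single-volume 'valid' correlation: out dims shrink by (k - 1) per axis.
// Used for the Laplacian-of-Gaussian filter after explicit boundary padding.
// [[Rcpp::export]]
NumericVector filt3_valid(NumericVector input, NumericVector kernel,
                          IntegerVector in_dim, IntegerVector k_dim) {
  const int X = in_dim[0], Y = in_dim[1], Z = in_dim[2];
  const int K1 = k_dim[0], K2 = k_dim[1], K3 = k_dim[2];
  const int OX = X - K1 + 1, OY = Y - K2 + 1, OZ = Z - K3 + 1;
  if (OX < 1 || OY < 1 || OZ < 1) stop("kernel larger than input");
  NumericVector out((R_xlen_t)OX * OY * OZ);
  const double* in = input.begin();
  const double* kv = kernel.begin();
  double* y = out.begin();

  for (int dz = 0; dz < K3; ++dz) {
    for (int dy = 0; dy < K2; ++dy) {
      for (int dx = 0; dx < K1; ++dx) {
        const double wv = kv[(size_t)dx + (size_t)K1 * (dy + (size_t)K2 * dz)];
        if (wv == 0.0) continue;
        for (int z = 0; z < OZ; ++z) {
          for (int yy = 0; yy < OY; ++yy) {
            double* yp = y + (size_t)OX * (yy + (size_t)OY * z);
            const double* xp = in + (size_t)dx +
              (size_t)X * ((yy + dy) + (size_t)Y * (z + dz));
            for (int i = 0; i < OX; ++i) yp[i] += wv * xp[i];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ);
  return out;
}
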