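// Voxel-level kernels: the 3D conv-net layer operations (forward/backward),
// trilinear rotation, parallel-beam projection and back-projection.
//
// Network activations are single-precision matrices (Npad x C) held in C++
// and passed around R as external pointers, where Npad enumerates the voxels
// of the volume padded by one voxel of zeros on every face, z fastest
// (column-major R array order).  With that layout a spatial offset
// (dz, dy, dx) is a single shift of the linear index, so a 3x3x3 convolution
// is 27 GEMMs on contiguous row ranges with no im2col buffer; padding rows
// absorb the out-of-field reads and are re-zeroed after every operation.
// Weights and gradients cross the R boundary as doubles (R's only numeric),
// while the heavy activation arithmetic runs in float, the customary
// precision for volumetric network fitting.

#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::mat;
using arma::uword;

typedef Rcpp::XPtr<fmat> act_ptr;

// single-precision GEMM; R's BLAS header only declares the double routines
// but the linked BLAS provides the full set
extern "C" void sgemm_(const char *, const char *, const int *, const int *,
                       const int *, const float *, const float *,
                       const int *, const float *, const int *,
                       const float *, float *, const int *);

static void sgemm_acc(const char *ta, const char *tb, int m, int n, int k,
                      const float *A, int lda, const float *B, int ldb,
                      float *C, int ldc) {
  const float one = 1.0f;
  sgemm_(ta, tb, &m, &n, &k, &one, A, &lda, B, &ldb, &one, C, &ldc);
}

static inline int pad_n(int nz, int ny, int nx) {
  return (nz + 2) * (ny + 2) * (nx + 2);
}

template <typename M> static void zero_pads(M &A, int nz, int ny, int nx) {
  const int pz = nz + 2, py = ny + 2, px = nx + 2;
  for (int ix = 0; ix < px; ix++) {
    for (int iy = 0; iy < py; iy++) {
      const bool edge_xy = (ix == 0 || ix == px - 1 || iy == 0 || iy == py - 1);
      const int off = pz * (iy + py * ix);
      if (edge_xy) {
        A.rows(off, off + pz - 1).zeros();
      } else {
        A.row(off).zeros();
        A.row(off + pz - 1).zeros();
      }
    }
  }
}

static act_ptr make_act(fmat *m) { return act_ptr(m, true); }

// ---- activation transport --------------------------------------------------

// [[Rcpp::export]]
SEXP nn_from_vol(const arma::vec &v, int nz, int ny, int nx) {
  fmat *A = new fmat(pad_n(nz, ny, nx), 1, arma::fill::zeros);
  int k = 0;
  const int pz = nz + 2, py = ny + 2;
  for (int ix = 0; ix < nx; ix++)
    for (int iy = 0; iy < ny; iy++)
      for (int iz = 0; iz < nz; iz++)
        (*A)((iz + 1) + pz * ((iy + 1) + py * (ix + 1)), 0) =
            static_cast<float>(v(k++));
  return make_act(A);
}

// [[Rcpp::export]]
arma::vec nn_to_vol(SEXP Ap, int nz, int ny, int nx, int col = 0) {
  act_ptr A(Ap);
  arma::vec v(static_cast<uword>(nz) * ny * nx);
  int k = 0;
  const int pz = nz + 2, py = ny + 2;
  for (int ix = 0; ix < nx; ix++)
    for (int iy = 0; iy < ny; iy++)
      for (int iz = 0; iz < nz; iz++)
        v(k++) = (*A)((iz + 1) + pz * ((iy + 1) + py * (ix + 1)), col);
  return v;
}

// [[Rcpp::export]]
int nn_ncols(SEXP Ap) {
  act_ptr A(Ap);
  return A->n_cols;
}

// ---- convolution -----------------------------------------------------------

// W has rows grouped by offset j = (dz+1) + 3*(dy+1) + 9*(dx+1): rows
// [j*Cin, (j+1)*Cin) give the (Cin x Cout) kernel slab for that offset.
// [[Rcpp::export]]
SEXP nn_conv(SEXP Ap, int nz, int ny, int nx, const arma::mat &W,
             const arma::rowvec &b, bool relu) {
  act_ptr A(Ap);
  const int Cin = A->n_cols, Np = pad_n(nz, ny, nx);
  const int Cout = W.n_cols, ldw = 27 * Cin;
  const int pz = nz + 2, py = ny + 2;
  const fmat Wf = arma::conv_to<fmat>::from(W);
  fmat *out = new fmat(Np, Cout, arma::fill::zeros);
  for (int j = 0; j < 27; j++) {
    const int dz = j % 3 - 1, dy = (j / 3) % 3 - 1, dx = j / 9 - 1;
    const int s = dz + pz * (dy + py * dx);
    const int lo = std::max(0, -s), hi = Np - 1 - std::max(0, s);
    sgemm_acc("N", "N", hi - lo + 1, Cout, Cin, A->memptr() + lo + s, Np,
              Wf.memptr() + j * Cin, ldw, out->memptr() + lo, Np);
  }
  out->each_row() += arma::conv_to<arma::frowvec>::from(b);
  if (relu) out->transform([](float x) { return x > 0.0f ? x : 0.0f; });
  zero_pads(*out, nz, ny, nx);
  return make_act(out);
}

// backward through conv (+ optional ReLU whose post-activation is `outp`).
// `Gp` is consumed (masked in place).
// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(SEXP Ap, SEXP outp, int nz, int ny, int nx,
                       const arma::mat &W, SEXP Gp, bool relu) {
  act_ptr A(Ap), G(Gp);
  const int Cin = A->n_cols, Np = pad_n(nz, ny, nx);
  const int Cout = W.n_cols, ldw = 27 * Cin;
  const int pz = nz + 2, py = ny + 2;
  if (relu) {
    act_ptr out(outp);
    const float *o = out->memptr();
    float *g = G->memptr();
    for (uword i = 0; i < G->n_elem; i++) {
      if (o[i] <= 0.0f) g[i] = 0.0f;
    }
  }
  zero_pads(*G, nz, ny, nx);
  const fmat Wf = arma::conv_to<fmat>::from(W);
  fmat *dA = new fmat(Np, Cin, arma::fill::zeros);
  fmat dW(27 * Cin, Cout, arma::fill::zeros);
  for (int j = 0; j < 27; j++) {
    const int dz = j % 3 - 1, dy = (j / 3) % 3 - 1, dx = j / 9 - 1;
    const int s = dz + pz * (dy + py * dx);
    const int lo = std::max(0, -s), hi = Np - 1 - std::max(0, s);
    const int m = hi - lo + 1;
    // dA[v+s] += G[v] * Wj^T
    sgemm_acc("N", "T", m, Cin, Cout, G->memptr() + lo, Np,
              Wf.memptr() + j * Cin, ldw, dA->memptr() + lo + s, Np);
    // dWj += A[v+s]^T * G[v]
    sgemm_acc("T", "N", Cin, Cout, m, A->memptr() + lo + s, Np,
              G->memptr() + lo, Np, dW.memptr() + j * Cin, ldw);
  }
  zero_pads(*dA, nz, ny, nx);
  arma::frowvec db = arma::sum(*G, 0);
  return List::create(Named("dA") = make_act(dA),
                      Named("dW") = arma::conv_to<mat>::from(dW),
                      Named("db") = arma::conv_to<arma::rowvec>::from(db));
}

// 1x1x1 convolution (plain GEMM over channels)
// [[Rcpp::export]]
SEXP nn_conv1(SEXP Ap, int nz, int ny, int nx, const arma::mat &W,
              const arma::rowvec &b) {
  act_ptr A(Ap);
  const fmat Wf = arma::conv_to<fmat>::from(W);
  fmat *out = new fmat((*A) * Wf);
  out->each_row() += arma::conv_to<arma::frowvec>::from(b);
  zero_pads(*out, nz, ny, nx);
  return make_act(out);
}

// [[Rcpp::export]]
Rcpp::List nn_conv1_bwd(SEXP Ap, int nz, int ny, int nx, const arma::mat &W,
                        SEXP Gp) {
  act_ptr A(Ap), G(Gp);
  zero_pads(*G, nz, ny, nx);
  const fmat Wf = arma::conv_to<fmat>::from(W);
  fmat *dA = new fmat((*G) * Wf.t());
  fmat dW = A->t() * (*G);
  arma::frowvec db = arma::sum(*G, 0);
  return List::create(Named("dA") = make_act(dA),
                      Named("dW") = arma::conv_to<mat>::from(dW),
                      Named("db") = arma::conv_to<arma::rowvec>::from(db));
}

// ---- pooling / upsampling / plumbing --------------------------------------

// [[Rcpp::export]]
Rcpp::List nn_pool(SEXP Ap, int nz, int ny, int nx) {
  act_ptr A(Ap);
  const int C = A->n_cols;
  const int oz = nz / 2, oy = ny / 2, ox = nx / 2;
  const int pz = nz + 2, py = ny + 2;
  const int qz = oz + 2, qy = oy + 2;
  fmat *out = new fmat(pad_n(oz, oy, ox), C, arma::fill::zeros);
  arma::umat *arg = new arma::umat(out->n_rows, C, arma::fill::zeros);
  for (int ix = 0; ix < ox; ix++)
    for (int iy = 0; iy < oy; iy++)
      for (int iz = 0; iz < oz; iz++) {
        const int r = (iz + 1) + qz * ((iy + 1) + qy * (ix + 1));
        for (int c = 0; c < C; c++) {
          float best = -std::numeric_limits<float>::infinity();
          int bi = 0;
          for (int d = 0; d < 8; d++) {
            const int sz = 2 * iz + (d & 1), sy = 2 * iy + ((d >> 1) & 1),
                      sx = 2 * ix + ((d >> 2) & 1);
            const int ri = (sz + 1) + pz * ((sy + 1) + py * (sx + 1));
            if ((*A)(ri, c) > best) { best = (*A)(ri, c); bi = ri; }
          }
          (*out)(r, c) = best;
          (*arg)(r, c) = bi;
        }
      }
  return List::create(Named("out") = make_act(out),
                      Named("arg") = Rcpp::XPtr<arma::umat>(arg, true));
}

// [[Rcpp::export]]
SEXP nn_pool_bwd(SEXP Gp, SEXP argp, int nz, int ny, int nx) {
  act_ptr G(Gp);
  Rcpp::XPtr<arma::umat> arg(argp);
  const int C = G->n_cols;
  const int oz = nz / 2, oy = ny / 2, ox = nx / 2;
  const int qz = oz + 2, qy = oy + 2;
  fmat *dA = new fmat(pad_n(nz, ny, nx), C, arma::fill::zeros);
  for (int ix = 0; ix < ox; ix++)
    for (int iy = 0; iy < oy; iy++)
      for (int iz = 0; iz < oz; iz++) {
        const int r = (iz + 1) + qz * ((iy + 1) + qy * (ix + 1));
        for (int c = 0; c < C; c++) (*dA)((*arg)(r, c), c) += (*G)(r, c);
      }
  return make_act(dA);
}

// nearest-neighbour 2x upsampling: input dims (nz,ny,nx) -> (2nz,2ny,2nx)
// [[Rcpp::export]]
SEXP nn_upsample(SEXP Ap, int nz, int ny, int nx) {
  act_ptr A(Ap);
  const int C = A->n_cols;
  const int oz = 2 * nz, oy = 2 * ny, ox = 2 * nx;
  const int pz = nz + 2, py = ny + 2;
  const int qz = oz + 2, qy = oy + 2;
  fmat *out = new fmat(pad_n(oz, oy, ox), C, arma::fill::zeros);
  for (int c = 0; c < C; c++) {
    const float *src = A->colptr(c);
    float *dst = out->colptr(c);
    for (int ix = 0; ix < ox; ix++)
      for (int iy = 0; iy < oy; iy++) {
        const int rb = 1 + qz * ((iy + 1) + qy * (ix + 1));
        const int sb = 1 + pz * ((iy / 2 + 1) + py * (ix / 2 + 1));
        for (int iz = 0; iz < oz; iz++) dst[rb + iz] = src[sb + iz / 2];
      }
  }
  return make_act(out);
}

// [[Rcpp::export]]
SEXP nn_upsample_bwd(SEXP Gp, int nz, int ny, int nx) {
  act_ptr G(Gp);
  const int C = G->n_cols;
  const int oz = 2 * nz, oy = 2 * ny, ox = 2 * nx;
  const int pz = nz + 2, py = ny + 2;
  const int qz = oz + 2, qy = oy + 2;
  fmat *dA = new fmat(pad_n(nz, ny, nx), C, arma::fill::zeros);
  for (int c = 0; c < C; c++) {
    const float *src = G->colptr(c);
    float *dst = dA->colptr(c);
    for (int ix = 0; ix < ox; ix++)
      for (int iy = 0; iy < oy; iy++) {
        const int rb = 1 + qz * ((iy + 1) + qy * (ix + 1));
        const int sb = 1 + pz * ((iy / 2 + 1) + py * (ix / 2 + 1));
        for (int iz = 0; iz < oz; iz++) dst[sb + iz / 2] += src[rb + iz];
      }
  }
  return make_act(dA);
}

// [[Rcpp::export]]
SEXP nn_concat(SEXP Ap, SEXP Bp) {
  act_ptr A(Ap), B(Bp);
  fmat *out = new fmat(arma::join_rows(*A, *B));
  return make_act(out);
}

// [[Rcpp::export]]
SEXP nn_cols(SEXP Ap, int from, int to) {
  act_ptr A(Ap);
  fmat *out = new fmat(A->cols(from, to));
  return make_act(out);
}

// [[Rcpp::export]]
SEXP nn_add(SEXP Ap, SEXP Bp) {
  act_ptr A(Ap), B(Bp);
  fmat *out = new fmat(*A + *B);
  return make_act(out);
}

// inverted dropout; draws from R's RNG so a single seed controls the run
// [[Rcpp::export]]
Rcpp::List nn_dropout(SEXP Ap, double p) {
  act_ptr A(Ap);
  fmat *mask = new fmat(A->n_rows, A->n_cols);
  const float scale = static_cast<float>(1.0 / (1.0 - p));
  for (uword i = 0; i < mask->n_elem; i++) {
    (*mask)(i) = (unif_rand() >= p) ? scale : 0.0f;
  }
  fmat *out = new fmat((*A) % (*mask));
  return List::create(Named("out") = make_act(out),
                      Named("mask") = make_act(mask));
}

// [[Rcpp::export]]
SEXP nn_mul(SEXP Ap, SEXP Bp) {
  act_ptr A(Ap), B(Bp);
  fmat *out = new fmat((*A) % (*B));
  return make_act(out);
}

// ---- geometry kernels (double precision) -----------------------------------

static inline double get_vox(const arma::vec &v, int nz, int ny, int nx,
                             int iz, int iy, int ix) {
  return v(iz + static_cast<uword>(nz) * (iy + static_cast<uword>(ny) * ix));
}

// volume rotation: out(p) = in(Rinv (p - c) + c), trilinear, p = (x,y,z)
// R is the rotation applied to the volume; dims (n,n,n), cubic.
// [[Rcpp::export]]
arma::vec cpp_rotate_trilinear(const arma::vec &v, int n, const arma::mat &R,
                               double fill) {
  arma::vec out(static_cast<uword>(n) * n * n);
  const double c = (n - 1) / 2.0;
  const mat Ri = R.t(); // inverse of a rotation
  uword k = 0;
  for (int ix = 0; ix < n; ix++)
    for (int iy = 0; iy < n; iy++)
      for (int iz = 0; iz < n; iz++) {
        const double x = ix - c, y = iy - c, z = iz - c;
        const double xs = Ri(0, 0) * x + Ri(0, 1) * y + Ri(0, 2) * z + c;
        const double ys = Ri(1, 0) * x + Ri(1, 1) * y + Ri(1, 2) * z + c;
        const double zs = Ri(2, 0) * x + Ri(2, 1) * y + Ri(2, 2) * z + c;
        if (xs < 0 || xs > n - 1 || ys < 0 || ys > n - 1 || zs < 0 ||
            zs > n - 1) {
          out(k++) = fill;
          continue;
        }
        const int x0 = std::min((int)std::floor(xs), n - 2);
        const int y0 = std::min((int)std::floor(ys), n - 2);
        const int z0 = std::min((int)std::floor(zs), n - 2);
        const double fx = xs - x0, fy = ys - y0, fz = zs - z0;
        double acc = 0.0;
        for (int d = 0; d < 8; d++) {
          const int ax = x0 + ((d >> 2) & 1), ay = y0 + ((d >> 1) & 1),
                    az = z0 + (d & 1);
          const double w = (((d >> 2) & 1) ? fx : 1 - fx) *
                           (((d >> 1) & 1) ? fy : 1 - fy) *
                           ((d & 1) ? fz : 1 - fz);
          acc += w * get_vox(v, n, n, n, az, ay, ax);
        }
        out(k++) = acc;
      }
  return out;
}

// parallel-beam projection about the y (tilt) axis.  For tilt angle a the
// detector frame (u, v=y) maps into the volume as
//   (x, z) = u * (cos a, -sin a) + t * (sin a, cos a),
// and the projection integrates along t.  Returns an (ny, nx, K) stack.
// [[Rcpp::export]]
arma::vec cpp_project(const arma::vec &v, int nz, int ny, int nx,
                      const arma::vec &angles) {
  const int K = angles.n_elem;
  arma::vec out(static_cast<uword>(ny) * nx * K, arma::fill::zeros);
  const double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0;
  for (int k = 0; k < K; k++) {
    const double ca = std::cos(angles(k)), sa = std::sin(angles(k));
    for (int iu = 0; iu < nx; iu++) {
      const double du = iu - cx;
      for (int it = 0; it < nz; it++) {
        const double dt = it - cz;
        const double xs = cx + ca * du + sa * dt;
        const double zs = cz - sa * du + ca * dt;
        if (xs < 0 || xs > nx - 1 || zs < 0 || zs > nz - 1) continue;
        const int x0 = std::min((int)std::floor(xs), nx - 2);
        const int z0 = std::min((int)std::floor(zs), nz - 2);
        const double fx = xs - x0, fz = zs - z0;
        for (int iy = 0; iy < ny; iy++) {
          const double s =
              (1 - fx) * ((1 - fz) * get_vox(v, nz, ny, nx, z0, iy, x0) +
                          fz * get_vox(v, nz, ny, nx, z0 + 1, iy, x0)) +
              fx * ((1 - fz) * get_vox(v, nz, ny, nx, z0, iy, x0 + 1) +
                    fz * get_vox(v, nz, ny, nx, z0 + 1, iy, x0 + 1));
          out(iy + static_cast<uword>(ny) * (iu + static_cast<uword>(nx) * k)) +=
              s;
        }
      }
    }
  }
  return out;
}

// back-projection of a filtered stack (ny, nx, K) into a (nz, ny, nx) volume;
// detector coordinate of volume point (x, z) at angle a is
//   u = cos a * (x - cx) - sin a * (z - cz) + cx.
// [[Rcpp::export]]
arma::vec cpp_backproject(const arma::vec &stack, int ny, int nx,
                          const arma::vec &angles, int nz) {
  const int K = angles.n_elem;
  arma::vec out(static_cast<uword>(nz) * ny * nx, arma::fill::zeros);
  const double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0;
  for (int k = 0; k < K; k++) {
    const double ca = std::cos(angles(k)), sa = std::sin(angles(k));
    for (int ix = 0; ix < nx; ix++) {
      for (int iz = 0; iz < nz; iz++) {
        const double u = ca * (ix - cx) - sa * (iz - cz) + cx;
        if (u < 0 || u > nx - 1) continue;
        const int u0 = std::min((int)std::floor(u), nx - 2);
        const double fu = u - u0;
        for (int iy = 0; iy < ny; iy++) {
          const uword b = iy + static_cast<uword>(ny) *
                                   (u0 + static_cast<uword>(nx) * k);
          const double s = (1 - fu) * stack(b) + fu * stack(b + ny);
          out(iz + static_cast<uword>(nz) * (iy + static_cast<uword>(ny) * ix)) +=
              s;
        }
      }
    }
  }
  return out;
}
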