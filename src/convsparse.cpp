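// Convolutional sparse-coding primitives.
//
// Geometry convention (shared with the R side): an image is H x W x C, a
// dictionary of nf kernels of side k is a (k*k*C) x nf matrix whose column f
// is the kernel unrolled column-major as (row, col, channel). Feature maps
// are mh x mw x nf with mh = ceil(H/s), mw = ceil(W/s) for stride s; map
// position (i, j) (0-based) anchors its k x k window at image row i*s - p,
// col j*s - p, where p = floor((k - s) / 2) gives "same"-style zero padding
// (2048 px at stride 4 -> 512 x 512 maps). Out-of-image pixels read as zero.
//
// The dense correlation Phi^T(x) is an im2col + BLAS GEMM, blocked over map
// positions so full-slide tiles never materialize the whole patch matrix;
// the reconstruction Phi * a exploits sparsity by scatter-adding one scaled
// kernel per nonzero coefficient.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const uword kBlockDoubles = 1u << 24;  // ~128 MB im2col blocks

// Fill P (bs x k*k*C) with zero-padded patches for map positions
// [pos0, pos0 + bs), positions ordered column-major over the mh x mw lattice.
static void im2col_block(const cube& img, mat& P, uword pos0, uword bs,
                         uword mh, int k, int s, int p) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  P.zeros();
  for (uword b = 0; b < bs; ++b) {
    const uword pos = pos0 + b;
    const int i = pos % mh, j = pos / mh;
    const int r0 = i * s - p, c0 = j * s - p;
    const int rlo = std::max(0, -r0), rhi = std::min(k, H - r0);
    const int clo = std::max(0, -c0), chi = std::min(k, W - c0);
    if (rlo >= rhi || clo >= chi) continue;
    for (int ch = 0; ch < C; ++ch)
      for (int c = clo; c < chi; ++c) {
        const double* src = &img(r0 + rlo, c0 + c, ch);
        double* dst = &P(b, rlo + c * k + ch * k * k);
        // P is row-indexed by position: stride between patch entries is n_rows
        for (int r = rlo; r < rhi; ++r)
          dst[(r - rlo) * (long)P.n_rows] = src[r - rlo];
      }
  }
}

// out += coef * kernel(col f of K) placed at map position (i, j), clipped.
static void scatter_kernel(cube& out, const mat& K, uword f, double coef,
                           int i, int j, int k, int s, int p) {
  const int H = out.n_rows, W = out.n_cols, C = out.n_slices;
  const int r0 = i * s - p, c0 = j * s - p;
  const int rlo = std::max(0, -r0), rhi = std::min(k, H - r0);
  const int clo = std::max(0, -c0), chi = std::min(k, W - c0);
  const double* kf = K.colptr(f);
  for (int ch = 0; ch < C; ++ch)
    for (int c = clo; c < chi; ++c) {
      double* dst = &out(r0 + rlo, c0 + c, ch);
      const double* src = kf + rlo + c * k + ch * k * k;
      for (int r = 0; r < rhi - rlo; ++r) dst[r] += coef * src[r];
    }
}

static cube reconstruct_mat(const mat& A, const mat& K, int H, int W, int C,
                            uword mh, int k, int s, int p) {
  cube out(H, W, C, fill::zeros);
  for (uword f = 0; f < A.n_cols; ++f) {
    const double* col = A.colptr(f);
    for (uword pos = 0; pos < A.n_rows; ++pos)
      if (col[pos] != 0.0)
        scatter_kernel(out, K, f, col[pos], pos % mh, pos / mh, k, s, p);
  }
  return out;
}

static void correlate_into(const cube& img, const mat& K, mat& D,
                           uword mh, uword mw, int k, int s, int p) {
  const uword npos = mh * mw;
  const uword pdim = K.n_rows;
  const uword block = std::max<uword>(256, kBlockDoubles / pdim);
  mat P(std::min(block, npos), pdim);
  for (uword pos0 = 0; pos0 < npos; pos0 += block) {
    const uword bs = std::min(block, npos - pos0);
    if (P.n_rows != bs) P.set_size(bs, pdim);
    im2col_block(img, P, pos0, bs, mh, k, s, p);
    D.rows(pos0, pos0 + bs - 1) = P * K;
  }
}

// [[Rcpp::export]]
arma::cube cs_correlate(const arma::cube& img, const arma::mat& K,
                        int k, int s, int p) {
  const uword mh = (img.n_rows + s - 1) / s, mw = (img.n_cols + s - 1) / s;
  cube out(mh, mw, K.n_cols);
  mat D(out.memptr(), mh * mw, K.n_cols, false, true);
  correlate_into(img, K, D, mh, mw, k, s, p);
  return out;
}

// [[Rcpp::export]]
arma::cube cs_reconstruct(const arma::cube& maps, const arma::mat& K,
                          int H, int W, int C, int k, int s, int p) {
  const mat A(const_cast<double*>(maps.memptr()),
              maps.n_rows * maps.n_cols, maps.n_slices, false, true);
  return reconstruct_mat(A, K, H, W, C, maps.n_rows, k, s, p);
}

// Descent direction for the dictionary on one image: d(1/2 ||I - Phi a||^2)
// / d(phi_f) = -sum_pos resid_patch(pos) * a_f(pos), returned with the sign
// of the *negative* gradient, i.e. P(resid)^T A, a (k*k*C) x nf matrix.
// [[Rcpp::export]]
arma::mat cs_dict_grad(const arma::cube& img, const arma::cube& maps,
                       const arma::mat& K, int k, int s, int p) {
  const uword mh = maps.n_rows, mw = maps.n_cols;
  const mat A(const_cast<double*>(maps.memptr()), mh * mw, maps.n_slices,
              false, true);
  cube resid = img - reconstruct_mat(A, K, img.n_rows, img.n_cols,
                                     img.n_slices, mh, k, s, p);
  const uword npos = mh * mw, pdim = K.n_rows;
  const uword block = std::max<uword>(256, kBlockDoubles / pdim);
  mat G(pdim, K.n_cols, fill::zeros);
  mat P(std::min(block, npos), pdim);
  for (uword pos0 = 0; pos0 < npos; pos0 += block) {
    const uword bs = std::min(block, npos - pos0);
    if (P.n_rows != bs) P.set_size(bs, pdim);
    im2col_block(resid, P, pos0, bs, mh, k, s, p);
    G += P.t() * A.rows(pos0, pos0 + bs - 1);
  }
  return G;
}

// LCA dynamics in residual form: u <- u + dt*(Phi^T(I - Phi a) + a - u),
// a = soft_threshold(u, lambda). Energy E = 1/2 ||I - Phi a||^2 +
// lambda ||a||_1 is recorded after every update; iteration stops early when
// the relative energy change drops below tol.
// [[Rcpp::export]]
Rcpp::List cs_lca(const arma::cube& img, const arma::mat& K,
                  int k, int s, int p, double lambda, double dt,
                  int n_iter, double tol) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  const uword mh = (H + s - 1) / s, mw = (W + s - 1) / s;
  const uword npos = mh * mw, nf = K.n_cols;
  mat U(npos, nf, fill::zeros), A(npos, nf, fill::zeros);
  cube resid = img;  // a = 0 initially
  std::vector<double> energy;
  energy.reserve(n_iter);
  const uword pdim = K.n_rows;
  const uword block = std::max<uword>(256, kBlockDoubles / pdim);
  mat P(std::min(block, npos), pdim);
  // potentials need ~tau to charge before the energy trace is informative,
  // and the flat all-zero-code phase must not satisfy the stopping rule
  const int burn_in = std::min(n_iter - 1, (int)std::ceil(1.0 / dt));
  bool activated = false;
  int used = 0;
  for (int t = 0; t < n_iter; ++t) {
    for (uword pos0 = 0; pos0 < npos; pos0 += block) {
      const uword bs = std::min(block, npos - pos0);
      if (P.n_rows != bs) P.set_size(bs, pdim);
      im2col_block(resid, P, pos0, bs, mh, k, s, p);
      U.rows(pos0, pos0 + bs - 1) +=
          dt * (P * K + A.rows(pos0, pos0 + bs - 1) -
                U.rows(pos0, pos0 + bs - 1));
    }
    A = sign(U) % clamp(abs(U) - lambda, 0.0, datum::inf);
    resid = img - reconstruct_mat(A, K, H, W, C, mh, k, s, p);
    const double E = 0.5 * accu(square(resid)) + lambda * accu(abs(A));
    energy.push_back(E);
    used = t + 1;
    if (!activated && any(vectorise(A) != 0.0)) activated = true;
    if (activated && t > burn_in) {
      const double prev = energy[t - 1];
      if (std::abs(E - prev) < tol * std::abs(prev)) break;
    }
  }
  // sequence the copies to cap peak memory on full-slide tiles
  resid.reset();
  P.reset();
  cube maps(mh, mw, nf);
  std::memcpy(maps.memptr(), A.memptr(), sizeof(double) * npos * nf);
  A.reset();
  cube pots(mh, mw, nf);
  std::memcpy(pots.memptr(), U.memptr(), sizeof(double) * npos * nf);
  U.reset();
  return Rcpp::List::create(Rcpp::Named("maps") = maps,
                            Rcpp::Named("potentials") = pots,
                            Rcpp::Named("energy") = energy,
                            Rcpp::Named("iterations") = used);
}
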