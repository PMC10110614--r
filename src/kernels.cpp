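// Compiled numerical kernels: 2-D convolution (im2col + GEMM) with dilation,
// 2x2 max pooling, 2x nearest-neighbour upsampling, and brute-force
// distance-weighted kNN label propagation.
//
// Feature maps are arma::cube with layout (height, width, channels).
// Convolution weights arrive flattened as (kh*kw*c_in, c_out) matrices where
// the row index runs kernel-row fastest, then kernel-col, then input channel
// (the R side builds them the same way). All convolutions are "same":
// zero padding of d*(k-1)/2 per side for odd k.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Transposed im2col with dilation: output (H*W, k*k*c_in). Row index runs
// over output pixels in column-major spatial order (i + j*H); column index
// q = c*k*k + kj*k + ki. This layout makes every fill a contiguous (or
// near-contiguous) column copy, and the convolution a tall-skinny GEMM
// cols_t * w whose result is already in cube memory order.
static arma::mat im2col_t(const arma::cube& x, int k, int d) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = d * (k - 1) / 2;
  arma::mat cols((size_t)H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = c * k * k + kj * k + ki;
        const int di = ki * d - pad, dj = kj * d - pad;
        double* dst = cols.colptr(q);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        if (i1 <= i0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const double* src = x.slice_colptr(c, sj);
          std::copy(src + i0 + di, src + i1 + di, dst + (size_t)j * H + i0);
        }
      }
    }
  }
  return cols;
}

// scatter-add transpose of im2col_t
static arma::cube col2im_t(const arma::mat& cols, int H, int W, int C,
                           int k, int d) {
  const int pad = d * (k - 1) / 2;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = c * k * k + kj * k + ki;
        const int di = ki * d - pad, dj = kj * d - pad;
        const double* src = cols.colptr(q);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        if (i1 <= i0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          double* dst = x.slice_colptr(c, sj) + di;
          const double* s = src + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] += s[i];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(rng = false)]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int k, int d) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = w.n_cols;
  arma::mat cols = im2col_t(x, k, d);            // (H*W, k*k*cin)
  arma::mat y = cols * w;                        // (H*W, cout)
  y.each_row() += b.t();
  return arma::cube(y.memptr(), H, W, cout);     // same memory order
}

// [[Rcpp::export(rng = false)]]
List conv2d_bw(const arma::cube& x, const arma::mat& w, const arma::cube& dy,
               int k, int d) {
  const int H = x.n_rows, W = x.n_cols, cin = x.n_slices;
  const int cout = dy.n_slices;
  const arma::mat dym(const_cast<double*>(dy.memptr()), (size_t)H * W, cout,
                      false, true);              // view, no copy
  arma::mat cols = im2col_t(x, k, d);
  arma::mat dw = cols.t() * dym;                 // (k*k*cin, cout)
  arma::vec db = arma::sum(dym, 0).t();
  arma::mat dcols = dym * w.t();                 // (H*W, k*k*cin)
  arma::cube dx = col2im_t(dcols, H, W, cin, k, d);
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx);
}

// 2x2 max pool, stride 2. Even H, W assumed (the R side pads to a grid).
// Returns pooled map and the linear (0-based, per-slice) argmax index.
// [[Rcpp::export(rng = false)]]
List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube amax(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        double best = sl(i0, j0);
        int bi = i0, bj = j0;
        // deterministic first-max in column-major scan of the 2x2 window
        if (sl(i0 + 1, j0) > best) { best = sl(i0 + 1, j0); bi = i0 + 1; bj = j0; }
        if (sl(i0, j0 + 1) > best) { best = sl(i0, j0 + 1); bi = i0; bj = j0 + 1; }
        if (sl(i0 + 1, j0 + 1) > best) { best = sl(i0 + 1, j0 + 1); bi = i0 + 1; bj = j0 + 1; }
        y(i, j, c) = best;
        amax(i, j, c) = (arma::uword)(bi + bj * H);
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(rng = false)]]
arma::cube maxpool2_bw(const arma::cube& dy, const arma::ucube& amax,
                       int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = dx.slice(c).memptr();
    const arma::mat& g = dy.slice(c);
    const arma::umat& a = amax.slice(c);
    for (arma::uword j = 0; j < g.n_cols; ++j)
      for (arma::uword i = 0; i < g.n_rows; ++i)
        dst[a(i, j)] += g(i, j);
  }
  return dx;
}

// [[Rcpp::export(rng = false)]]
arma::cube upsample2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(rng = false)]]
arma::cube upsample2_bw(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// Distance-weighted kNN vote over labeled vessel pixels.
//
// q: (nq, 2) query pixel coordinates (row, col); p: (np, 2) labeled pixel
// coordinates in row-major scan order; lab: class per labeled pixel
// (1 = artery, 2 = vein). Neighbour order is (distance, scan index): an
// equidistant k-th neighbour resolves to the earlier scan position.
// weighted: 1/d voting; otherwise uniform. Weighted-vote ties go to artery.
// Returns 1/2 per query.
static int vote_of(const std::vector<std::pair<double, int>>& cand, int k,
                   const IntegerVector& lab, bool weighted) {
  double wa = 0.0, wv = 0.0;
  for (int j = 0; j < k; ++j) {
    const double w = weighted ? 1.0 / std::sqrt(cand[j].first) : 1.0;
    if (lab[cand[j].second] == 1) wa += w; else wv += w;
  }
  return (wa >= wv) ? 1 : 2;
}

// [[Rcpp::export(rng = false)]]
IntegerVector knn_vote(const arma::mat& q, const arma::mat& p,
                       const IntegerVector& lab, int k, bool weighted) {
  const int nq = q.n_rows, np = p.n_rows;
  IntegerVector out(nq);
  if (np <= 512) {
    // brute force: all distances, deterministic (distance, scan-index) order
    std::vector<std::pair<double, int>> d(np);
    for (int iq = 0; iq < nq; ++iq) {
      const double qr = q(iq, 0), qc = q(iq, 1);
      for (int ip = 0; ip < np; ++ip) {
        const double dr = p(ip, 0) - qr, dc = p(ip, 1) - qc;
        d[ip] = std::make_pair(dr * dr + dc * dc, ip);
      }
      std::partial_sort(d.begin(), d.begin() + k, d.end());
      out[iq] = vote_of(d, k, lab, weighted);
    }
    return out;
  }
  // grid-bucketed exact search: labeled points hashed to square cells,
  // queries expand Chebyshev rings until no unexplored cell can hold a
  // point at distance <= the current k-th (ties included, so the
  // (distance, scan-index) order matches the brute-force path exactly)
  double rmin = p.col(0).min(), rmax = p.col(0).max();
  double cmin = p.col(1).min(), cmax = p.col(1).max();
  const double area = std::max((rmax - rmin) * (cmax - cmin), 1.0);
  const double cell = std::max(1.0, std::sqrt(area * k / np) * 1.5);
  const int gr = (int)((rmax - rmin) / cell) + 1;
  const int gc = (int)((cmax - cmin) / cell) + 1;
  std::vector<std::vector<int>> bucket((size_t)gr * gc);
  for (int ip = 0; ip < np; ++ip) {
    const int bi = (int)((p(ip, 0) - rmin) / cell);
    const int bj = (int)((p(ip, 1) - cmin) / cell);
    bucket[(size_t)bi * gc + bj].push_back(ip);  // ascending scan index
  }
  const int ring_max = std::max(gr, gc);
  std::vector<std::pair<double, int>> cand;
  for (int iq = 0; iq < nq; ++iq) {
    const double qr = q(iq, 0), qc = q(iq, 1);
    int bi = (int)((qr - rmin) / cell), bj = (int)((qc - cmin) / cell);
    bi = std::min(std::max(bi, 0), gr - 1);
    bj = std::min(std::max(bj, 0), gc - 1);
    cand.clear();
    double kth = R_PosInf;
    for (int R = 0; R <= ring_max; ++R) {
      if (cand.size() >= (size_t)k) {
        std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
        kth = cand[k - 1].first;
        const double lb = (R - 1) * cell;  // min distance to ring-R cells
        if (R > 0 && lb > 0 && lb * lb > kth) break;
      }
      bool any_cell = false;
      for (int di = -R; di <= R; ++di) {
        const int ci = bi + di;
        if (ci < 0 || ci >= gr) continue;
        const int step = (std::abs(di) == R) ? 1 : 2 * R;
        for (int dj = -R; dj <= R; dj += (R == 0 ? 1 : step)) {
          const int cj = bj + dj;
          if (cj < 0 || cj >= gc) continue;
          any_cell = true;
          for (int ip : bucket[(size_t)ci * gc + cj]) {
            const double dr = p(ip, 0) - qr, dc = p(ip, 1) - qc;
            cand.push_back(std::make_pair(dr * dr + dc * dc, ip));
          }
        }
      }
      if (!any_cell && cand.size() >= (size_t)k) break;
    }
    std::partial_sort(cand.begin(),
                      cand.begin() + std::min((size_t)k, cand.size()),
                      cand.end());
    out[iq] = vote_of(cand, k, lab, weighted);
  }
  return out;
}
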