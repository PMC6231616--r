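#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <climits>

using namespace Rcpp;

// half-sample symmetric reflection: ... 1 0 | 0 1 ... n-1 | n-1 n-2 ...
static inline int mirror_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    else i = 2 * n - i - 1;
  }
  return i;
}

// Non-local means on a [0,1] intensity matrix.
//
// For every pixel i the output is the weight-normalized average of the
// intensities in its (2*wr+1)^2 search window, with
//   w(i,j) = exp(-d(i,j) / h^2),
// d(i,j) the Gaussian-weighted mean squared difference of the (2*kr+1)^2
// patches around i and j (Gaussian sigma = kr/2, weights summing to 1).
// The self weight is replaced by the maximum of the other window weights.
// Boundaries are handled by symmetric (mirror) padding of kr+wr pixels; both
// patch pixels and window neighbours are read from the padded field.
//
// The per-offset decomposition below evaluates, for each window offset, the
// squared-difference image followed by a separable convolution with the
// normalized Gaussian, which is algebraically identical to the per-pixel
// patch loop but runs in O(N * wr^2 * kr) instead of O(N * wr^2 * kr^2).
// [[Rcpp::export]]
NumericMatrix nlm_filter_cpp(NumericMatrix img, int kr, int wr, double h) {
  const int H = img.nrow(), W = img.ncol();
  const int P = kr + wr;
  const int Hp = H + 2 * P, Wp = W + 2 * P;
  const int ks = 2 * kr + 1;

  std::vector<double> pad((size_t)Hp * Wp);
  for (int c = 0; c < Wp; ++c) {
    int cs = mirror_idx(c - P, W);
    for (int r = 0; r < Hp; ++r)
      pad[(size_t)c * Hp + r] = img(mirror_idx(r - P, H), cs);
  }

  std::vector<double> g(ks);
  double sigma = kr / 2.0, gsum = 0.0;
  for (int t = 0; t < ks; ++t) {
    double u = t - kr;
    g[t] = (sigma > 0) ? std::exp(-u * u / (2.0 * sigma * sigma)) : (u == 0.0);
    gsum += g[t];
  }
  for (int t = 0; t < ks; ++t) g[t] /= gsum;

  std::vector<double> num((size_t)H * W, 0.0), den((size_t)H * W, 0.0),
      maxw((size_t)H * W, 0.0);
  std::vector<double> D((size_t)Hp * Wp), T((size_t)Hp * Wp);
  const double inv_h2 = 1.0 / (h * h);

  // patch distances are symmetric: dist(i, i+o) = dist(i+o, i), so each
  // offset in a half space serves both directions. The distance field is
  // evaluated on the wr-extended domain so the reverse direction is defined
  // at border pixels whose mirrored neighbour lies outside the image.
  const int e_rlo = P - wr, e_rhi = P + H - 1 + wr;   // extended center rows
  const int e_clo = P - wr, e_chi = P + W - 1 + wr;
  const int d_rlo = e_rlo - kr, d_rhi = e_rhi + kr;   // rows where D is needed
  const int d_clo = e_clo - kr, d_chi = e_chi + kr;
  std::vector<double> dist((size_t)Hp * Wp);

  for (int dy = -wr; dy <= wr; ++dy) {
    for (int dx = 0; dx <= wr; ++dx) {
      if (dx == 0 && dy <= 0) continue;              // half space
      const int rl = std::max(d_rlo, -dy), rh = std::min(d_rhi, Hp - 1 - dy);
      const int cl = std::max(d_clo, -dx), ch = std::min(d_chi, Wp - 1 - dx);
      for (int c = cl; c <= ch; ++c) {
        const double *a = &pad[(size_t)c * Hp];
        const double *b = &pad[(size_t)(c + dx) * Hp + dy];
        double *d = &D[(size_t)c * Hp];
        for (int r = rl; r <= rh; ++r) {
          double u = a[r] - b[r];
          d[r] = u * u;
        }
      }
      // vertical then horizontal Gaussian pass over the extended domain
      const int cvl = std::max(cl, d_clo), cvh = std::min(ch, d_chi);
      for (int c = cvl; c <= cvh; ++c) {
        const double *d = &D[(size_t)c * Hp];
        double *t = &T[(size_t)c * Hp];
        const int rvl = std::max(e_rlo, rl + kr), rvh = std::min(e_rhi, rh - kr);
        for (int r = rvl; r <= rvh; ++r) {
          double s = 0.0;
          for (int u = 0; u < ks; ++u) s += g[u] * d[r - kr + u];
          t[r] = s;
        }
      }
      const int ecl = std::max(e_clo, cl + kr), ech = std::min(e_chi, ch - kr);
      const int erl = std::max(e_rlo, rl + kr), erh = std::min(e_rhi, rh - kr);
      for (int c = ecl; c <= ech; ++c) {
        double *ds = &dist[(size_t)c * Hp];
        for (int r = erl; r <= erh; ++r) {
          double s = 0.0;
          for (int u = 0; u < ks; ++u) s += g[u] * T[(size_t)(c - kr + u) * Hp + r];
          ds[r] = s;
        }
      }
      // forward direction: center i in the image, neighbour i + o
      for (int cc = 0; cc < W; ++cc) {
        const int c = cc + P;
        if (c + dx > Wp - 1) continue;
        const double *vcol = &pad[(size_t)(c + dx) * Hp + dy];
        const double *ds = &dist[(size_t)c * Hp];
        for (int rr = 0; rr < H; ++rr) {
          const int r = rr + P;
          double w = std::exp(-ds[r] * inv_h2);
          size_t o = (size_t)cc * H + rr;
          num[o] += w * vcol[r];
          den[o] += w;
          if (w > maxw[o]) maxw[o] = w;
        }
      }
      // reverse direction: center m in the image, neighbour m - o
      for (int cc = 0; cc < W; ++cc) {
        const int c = cc + P;
        if (c - dx < 0) continue;
        const double *vcol = &pad[(size_t)(c - dx) * Hp - dy];
        const double *ds = &dist[(size_t)(c - dx) * Hp - dy];
        for (int rr = 0; rr < H; ++rr) {
          const int r = rr + P;
          double w = std::exp(-ds[r] * inv_h2);
          size_t o = (size_t)cc * H + rr;
          num[o] += w * vcol[r];
          den[o] += w;
          if (w > maxw[o]) maxw[o] = w;
        }
      }
    }
  }

  NumericMatrix out(H, W);
  for (int cc = 0; cc < W; ++cc)
    for (int rr = 0; rr < H; ++rr) {
      size_t o = (size_t)cc * H + rr;
      double v = img(rr, cc);
      double sw = maxw[o] > 0.0 ? maxw[o] : 1.0;  // window of size 1 fallback
      double nm = num[o] + sw * v;
      double dn = den[o] + sw;
      out(rr, cc) = nm / dn;
    }
  return out;
}

// Multi-scale dense SIFT.
//
// Frames sit on a regular grid with spacing `step`; at bin size b a frame
// covers a support of 4b x 4b pixels split into 4x4 spatial cells.
// Gradients are central differences (one-sided at the borders); gradient
// magnitude is distributed linearly over the two adjacent of 8 orientation
// bins; spatial pooling is flat (each pixel contributes to the cell that
// contains it), evaluated with channel-interleaved integral images that are
// shared across all scales. Descriptor layout:
// d = orientation + 8 * (4 * cell_row + cell_col). Descriptors are
// L2-normalized, clamped at 0.2 and renormalized; frames whose mean gradient
// magnitude falls below `contrast_threshold` are flagged and zeroed.
// Frames are enumerated column-major (frame rows fastest), matching R.
// Returns one (descriptors, flags, nr, nc) block per bin size.
// [[Rcpp::export]]
List dsift_multi_cpp(NumericMatrix img, int step, IntegerVector bin_sizes,
                     double contrast_threshold) {
  const int H = img.nrow(), W = img.ncol();
  int min_support = INT_MAX;
  for (int s = 0; s < bin_sizes.size(); ++s)
    min_support = std::min(min_support, 4 * bin_sizes[s]);
  if (H < min_support || W < min_support) {
    // smaller than every descriptor support: skip the gradient stage
    List out(bin_sizes.size());
    for (int s = 0; s < bin_sizes.size(); ++s)
      out[s] = List::create(_["descriptors"] = NumericMatrix(0, 128),
                            _["flags"] = LogicalVector(0),
                            _["nr"] = 0, _["nc"] = 0);
    return out;
  }

  const size_t Np = (size_t)H * W;
  std::vector<double> chan(8 * Np, 0.0), mag(Np, 0.0);
  const double bin_scale = 8.0 / (2.0 * M_PI);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double gx, gy;
      if (c == 0)          gx = img(r, 1) - img(r, 0);
      else if (c == W - 1) gx = img(r, W - 1) - img(r, W - 2);
      else                 gx = 0.5 * (img(r, c + 1) - img(r, c - 1));
      if (r == 0)          gy = img(1, c) - img(0, c);
      else if (r == H - 1) gy = img(H - 1, c) - img(H - 2, c);
      else                 gy = 0.5 * (img(r + 1, c) - img(r - 1, c));
      double m = std::sqrt(gx * gx + gy * gy);
      if (m <= 0.0) continue;
      double th = std::atan2(gy, gx);
      if (th < 0) th += 2.0 * M_PI;
      double ob = th * bin_scale;
      int o0 = (int)std::floor(ob);
      double f = ob - o0;
      o0 &= 7;
      int o1 = (o0 + 1) & 7;
      size_t px = (size_t)c * H + r;
      chan[o0 * Np + px] += m * (1.0 - f);
      chan[o1 * Np + px] += m * f;
      mag[px] += m;
    }
  }

  // integral images over the 8 orientation channels plus the magnitude,
  // stored channel-interleaved ((r, c) -> 9 consecutive doubles) so that a
  // cell's per-channel box sums read four short contiguous blocks instead
  // of striding across megabyte-sized planes
  const int Hi = H + 1, Wi = W + 1;
  std::vector<double> integ((size_t)9 * Hi * Wi, 0.0);
  {
    std::vector<double> colsum(9);
    for (int c = 1; c < Wi; ++c) {
      std::fill(colsum.begin(), colsum.end(), 0.0);
      const double *prev = &integ[(size_t)(c - 1) * Hi * 9];
      double *cur = &integ[(size_t)c * Hi * 9];
      for (int r = 1; r < Hi; ++r) {
        size_t px = (size_t)(c - 1) * H + (r - 1);
        for (int ch = 0; ch < 8; ++ch) colsum[ch] += chan[ch * Np + px];
        colsum[8] += mag[px];
        double *o = cur + (size_t)r * 9;
        const double *p = prev + (size_t)r * 9;
        for (int ch = 0; ch < 9; ++ch) o[ch] = p[ch] + colsum[ch];
      }
    }
  }
  auto corner = [&](int r, int c) -> const double * {
    return &integ[((size_t)c * Hi + r) * 9];
  };
  // inclusive pixel box [r0,r1] x [c0,c1] on channel ch
  auto boxsum1 = [&](int ch, int r0, int c0, int r1, int c1) {
    return corner(r1 + 1, c1 + 1)[ch] - corner(r1 + 1, c0)[ch]
         - corner(r0, c1 + 1)[ch] + corner(r0, c0)[ch];
  };

  List out(bin_sizes.size());
  std::vector<double> fmaj, dbuf(128);
  for (int s = 0; s < bin_sizes.size(); ++s) {
    const int bin_size = bin_sizes[s];
    const int support = 4 * bin_size;
    if (H < support || W < support) {
      out[s] = List::create(_["descriptors"] = NumericMatrix(0, 128),
                            _["flags"] = LogicalVector(0),
                            _["nr"] = 0, _["nc"] = 0);
      continue;
    }
    const int nr = (H - support) / step + 1;
    const int nc = (W - support) / step + 1;
    const int nf = nr * nc;
    NumericMatrix desc(nf, 128);         // one row per frame
    LogicalVector flags(nf);
    const double area = (double)support * support;
    double *descp = REAL(desc);
    // descriptors are assembled frame-major and transposed in blocks at the
    // end; writing rows of `desc` directly would miss cache on every store
    fmaj.resize((size_t)nf * 128);

    for (int fc = 0; fc < nc; ++fc) {
      const int c0 = fc * step;
      for (int fr = 0; fr < nr; ++fr) {
        const int r0 = fr * step;
        const int fi = fc * nr + fr;
        double energy = boxsum1(8, r0, c0, r0 + support - 1, c0 + support - 1) / area;
        if (energy < contrast_threshold) {
          flags[fi] = true;
          double *z = fmaj.data() + (size_t)fi * 128;
          std::fill(z, z + 128, 0.0);
          continue;
        }
        double *d = dbuf.data();
        double nrm2 = 0.0;
        for (int a = 0; a < 4; ++a) {
          int rr0 = r0 + a * bin_size, rr1 = rr0 + bin_size;   // integral rows
          for (int b = 0; b < 4; ++b) {
            int cc0 = c0 + b * bin_size, cc1 = cc0 + bin_size; // integral cols
            const double *p00 = corner(rr0, cc0), *p01 = corner(rr0, cc1);
            const double *p10 = corner(rr1, cc0), *p11 = corner(rr1, cc1);
            double *dd = d + 8 * (4 * a + b);
            for (int o = 0; o < 8; ++o) {
              // cancellation in the integral differences can leave a tiny
              // negative residue on empty cells; descriptors are sums of
              // non-negative mass, so clamp at zero
              double v = p11[o] - p01[o] - p10[o] + p00[o];
              if (v < 0) v = 0;
              dd[o] = v;
              nrm2 += v * v;
            }
          }
        }
        double nrm = std::sqrt(nrm2);
        double *row = &fmaj[(size_t)fi * 128];
        if (nrm <= 0.0) {
          flags[fi] = true;
          std::fill(row, row + 128, 0.0);
          continue;
        }
        nrm2 = 0.0;
        for (int t = 0; t < 128; ++t) {
          d[t] /= nrm;
          if (d[t] > 0.2) d[t] = 0.2;
          nrm2 += d[t] * d[t];
        }
        nrm = std::sqrt(nrm2);
        for (int t = 0; t < 128; ++t) row[t] = d[t] / nrm;
      }
    }

    // blocked transpose frame-major -> column-major n x 128
    const int B = 32;
    for (int f0 = 0; f0 < nf; f0 += B) {
      int f1 = std::min(f0 + B, nf);
      for (int t = 0; t < 128; ++t) {
        double *dst = descp + (size_t)t * nf;
        for (int f = f0; f < f1; ++f) dst[f] = fmaj[(size_t)f * 128 + t];
      }
    }
    out[s] = List::create(_["descriptors"] = desc, _["flags"] = flags,
                          _["nr"] = nr, _["nc"] = nc);
  }
  return out;
}

// Pack descriptor rows into 8-bit fixed point (round(v * 255)), dropping
// rows whose `keep` flag is false. Layout: frame-major, 128 bytes per frame.
// [[Rcpp::export]]
RawVector pack_descriptors_cpp(NumericMatrix desc, LogicalVector keep) {
  const int n = desc.nrow(), d = desc.ncol();
  int m = 0;
  for (int i = 0; i < n; ++i) if (keep[i]) ++m;
  RawVector out((size_t)m * d);
  Rbyte *o = out.begin();
  int row = 0;
  for (int i = 0; i < n; ++i) {
    if (!keep[i]) continue;
    Rbyte *dst = o + (size_t)row * d;
    for (int t = 0; t < d; ++t) {
      double v = desc(i, t) * 255.0;
      if (v < 0) v = 0; else if (v > 255) v = 255;
      dst[t] = (Rbyte)(v + 0.5);
    }
    ++row;
  }
  return out;
}

// Exact nearest-center scan over packed 8-bit descriptors: distances are
// computed on the decoded values b/255, identical (up to rounding) to
// unpacking followed by linear_quantize_cpp.
// [[Rcpp::export]]
List quantize_packed_cpp(RawVector packed, int d, NumericMatrix centers) {
  const int k = centers.nrow();
  if (centers.ncol() != d) stop("descriptor dimension (%d) does not match codebook (%d)",
                                d, centers.ncol());
  const size_t n = packed.size() / d;
  std::vector<double> pts((size_t)k * d);
  for (int j = 0; j < k; ++j)
    for (int t = 0; t < d; ++t) pts[(size_t)j * d + t] = centers(j, t);
  const double inv255 = 1.0 / 255.0;
  IntegerVector idx(n);
  NumericVector dist2(n);
  std::vector<double> q(d);
  const Rbyte *p = packed.begin();
  int warm = -1;   // consecutive frames are similar: seed the bound with the
                   // previous winner, which keeps the scan exact but tight
  for (size_t i = 0; i < n; ++i) {
    const Rbyte *b = p + i * d;
    for (int t = 0; t < d; ++t) q[t] = b[t] * inv255;
    double best = R_PosInf;
    int bi = -1;
    if (warm >= 0) {
      const double *c = &pts[(size_t)warm * d];
      double d2 = 0.0;
      for (int t = 0; t < d; ++t) { double u = q[t] - c[t]; d2 += u * u; }
      best = d2; bi = warm;
    }
    for (int j = 0; j < k; ++j) {
      if (j == warm) continue;
      const double *c = &pts[(size_t)j * d];
      double d2 = 0.0;
      int t = 0;
      for (; t + 3 < d; t += 4) {
        double u0 = q[t] - c[t], u1 = q[t + 1] - c[t + 1];
        double u2 = q[t + 2] - c[t + 2], u3 = q[t + 3] - c[t + 3];
        d2 += u0 * u0 + u1 * u1 + u2 * u2 + u3 * u3;
        if (d2 > best) break;
      }
      if (d2 <= best) {
        for (; t < d; ++t) { double u = q[t] - c[t]; d2 += u * u; }
        if (d2 < best || (d2 == best && j < bi)) { best = d2; bi = j; }
      }
    }
    idx[i] = bi + 1;
    dist2[i] = best;
    warm = bi;
  }
  return List::create(_["idx"] = idx, _["d2"] = dist2);
}

// Exact nearest-center lookup by linear scan with the partial-distance
// cutoff; ties resolve to the lowest center index. Same contract as the
// kd-tree in exact mode, kept separate as the fast path for small codebooks.
// [[Rcpp::export]]
List linear_quantize_cpp(NumericMatrix x, NumericMatrix centers) {
  const int n = x.nrow(), d = x.ncol(), k = centers.nrow();
  if (centers.ncol() != d) stop("descriptor dimension (%d) does not match codebook (%d)",
                                d, centers.ncol());
  std::vector<double> pts((size_t)k * d), q(d);
  for (int j = 0; j < k; ++j)
    for (int t = 0; t < d; ++t) pts[(size_t)j * d + t] = centers(j, t);
  IntegerVector idx(n);
  NumericVector dist2(n);
  int warm = -1;
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < d; ++t) q[t] = x(i, t);
    double best = R_PosInf;
    int bi = -1;
    if (warm >= 0) {
      const double *c = &pts[(size_t)warm * d];
      double d2 = 0.0;
      for (int t = 0; t < d; ++t) { double u = q[t] - c[t]; d2 += u * u; }
      best = d2; bi = warm;
    }
    for (int j = 0; j < k; ++j) {
      if (j == warm) continue;
      const double *c = &pts[(size_t)j * d];
      double d2 = 0.0;
      int t = 0;
      for (; t + 3 < d; t += 4) {
        double u0 = q[t] - c[t], u1 = q[t + 1] - c[t + 1];
        double u2 = q[t + 2] - c[t + 2], u3 = q[t + 3] - c[t + 3];
        d2 += u0 * u0 + u1 * u1 + u2 * u2 + u3 * u3;
        if (d2 > best) break;
      }
      if (d2 <= best) {
        for (; t < d; ++t) { double u = q[t] - c[t]; d2 += u * u; }
        if (d2 < best || (d2 == best && j < bi)) { best = d2; bi = j; }
      }
    }
    idx[i] = bi + 1;
    dist2[i] = best;
    warm = bi;
  }
  return List::create(_["idx"] = idx, _["d2"] = dist2);
}

// ---- kd-tree nearest-center quantization -----------------------------------

namespace {

struct KdNode {
  int dim;          // -1 for leaf
  double split;
  int left, right;  // children (internal) ...
  int start, end;   // ... or [start, end) into perm (leaf)
};

struct KdTree {
  int d, n, leaf_size;
  const double *pts;           // n points, point-major (pts[i*d + t])
  std::vector<int> perm;
  std::vector<KdNode> nodes;

  int build(int start, int end) {
    KdNode nd;
    if (end - start <= leaf_size) {
      nd.dim = -1; nd.start = start; nd.end = end; nd.left = nd.right = -1;
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    int best_dim = 0; double best_spread = -1.0;
    for (int t = 0; t < d; ++t) {
      double lo = R_PosInf, hi = R_NegInf;
      for (int i = start; i < end; ++i) {
        double v = pts[(size_t)perm[i] * d + t];
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (hi - lo > best_spread) { best_spread = hi - lo; best_dim = t; }
    }
    int mid = start + (end - start) / 2;
    std::nth_element(perm.begin() + start, perm.begin() + mid, perm.begin() + end,
                     [&](int a, int b) {
                       return pts[(size_t)a * d + best_dim] < pts[(size_t)b * d + best_dim];
                     });
    nd.dim = best_dim;
    nd.split = pts[(size_t)perm[mid] * d + best_dim];
    int self = (int)nodes.size();
    nodes.push_back(nd);
    int l = build(start, mid);
    int r = build(mid, end);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }
};

struct QueryState {
  const KdTree *tree;
  const double *q;
  double best_d2;
  int best_idx;
  long examined, budget;   // budget <= 0: unlimited (exact search)
};

void kd_search(QueryState &st, int node) {
  const KdTree &T = *st.tree;
  const KdNode &nd = T.nodes[node];
  if (nd.dim < 0) {
    for (int i = nd.start; i < nd.end; ++i) {
      if (st.budget > 0 && st.examined >= st.budget) return;
      int p = T.perm[i];
      const double *x = &T.pts[(size_t)p * T.d];
      double d2 = 0.0;
      for (int t = 0; t < T.d; ++t) {
        double u = st.q[t] - x[t];
        d2 += u * u;
        if (d2 > st.best_d2) break;  // partial-distance cutoff
      }
      ++st.examined;
      if (d2 < st.best_d2 || (d2 == st.best_d2 && p < st.best_idx)) {
        st.best_d2 = d2;
        st.best_idx = p;
      }
    }
    return;
  }
  double diff = st.q[nd.dim] - nd.split;
  int near = diff < 0 ? nd.left : nd.right;
  int far = diff < 0 ? nd.right : nd.left;
  kd_search(st, near);
  if (st.budget > 0 && st.examined >= st.budget) return;
  if (diff * diff <= st.best_d2)  // <=: keep exactness under distance ties
    kd_search(st, far);
}

} // namespace

// Map each row of `x` to the index (1-based) of its nearest row of `centers`
// under L2, via a kd-tree built on the centers (split along the widest
// dimension at the median, leaves of 8). max_comparisons <= 0 requests exact
// search with branch-and-bound pruning; a positive value caps the number of
// center points examined per query (approximate, ANN-style). Distance ties
// resolve to the lowest center index. Returns word ids and squared distances.
// [[Rcpp::export]]
List kdtree_quantize_cpp(NumericMatrix x, NumericMatrix centers,
                         double max_comparisons) {
  const int n = x.nrow(), d = x.ncol(), k = centers.nrow();
  if (centers.ncol() != d) stop("descriptor dimension (%d) does not match codebook (%d)",
                                d, centers.ncol());
  if (k < 1) stop("codebook must contain at least one center");

  std::vector<double> pts((size_t)k * d);
  for (int j = 0; j < k; ++j)
    for (int t = 0; t < d; ++t) pts[(size_t)j * d + t] = centers(j, t);

  KdTree tree;
  tree.d = d; tree.n = k; tree.leaf_size = 8; tree.pts = pts.data();
  tree.perm.resize(k);
  for (int j = 0; j < k; ++j) tree.perm[j] = j;
  int root = tree.build(0, k);

  IntegerVector idx(n);
  NumericVector d2(n);
  std::vector<double> q(d);
  long budget = (max_comparisons > 0 && R_finite(max_comparisons))
                    ? (long)max_comparisons : 0;
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < d; ++t) q[t] = x(i, t);
    QueryState st{&tree, q.data(), R_PosInf, -1, 0, budget};
    kd_search(st, root);
    idx[i] = st.best_idx + 1;
    d2[i] = st.best_d2;
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}
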