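#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Resample a 3D volume under a voxel-to-voxel affine map.
// M (4x4) maps 0-based output voxel indices to continuous 0-based source
// voxel indices. interp: 0 = trilinear, 1 = nearest neighbour.
// Out-of-field voxels are filled with 0.
// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector src, IntegerVector sdim,
                                  NumericMatrix M, IntegerVector odim,
                                  int interp) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  NumericVector out(static_cast<R_xlen_t>(ox) * oy * oz);
  const double *s = src.begin();
  double *o = out.begin();
  R_xlen_t idx = 0;
  const R_xlen_t sxy = static_cast<R_xlen_t>(sx) * sy;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      const double bx = m01 * j + m02 * k + m03;
      const double by = m11 * j + m12 * k + m13;
      const double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx) {
        const double xs = m00 * i + bx;
        const double ys = m10 * i + by;
        const double zs = m20 * i + bz;
        if (interp == 1) {
          const int xi = static_cast<int>(std::floor(xs + 0.5));
          const int yi = static_cast<int>(std::floor(ys + 0.5));
          const int zi = static_cast<int>(std::floor(zs + 0.5));
          if (xi < 0 || xi >= sx || yi < 0 || yi >= sy || zi < 0 || zi >= sz)
            o[idx] = 0.0;
          else
            o[idx] = s[xi + static_cast<R_xlen_t>(yi) * sx + zi * sxy];
        } else {
          const double xf = std::floor(xs), yf = std::floor(ys), zf = std::floor(zs);
          const int x0 = static_cast<int>(xf), y0 = static_cast<int>(yf),
                    z0 = static_cast<int>(zf);
          if (x0 < -1 || x0 >= sx || y0 < -1 || y0 >= sy || z0 < -1 || z0 >= sz) {
            o[idx] = 0.0;
            continue;
          }
          const double fx = xs - xf, fy = ys - yf, fz = zs - zf;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz) {
            const int zc = z0 + dz;
            if (zc < 0 || zc >= sz) continue;
            const double wz = dz ? fz : 1.0 - fz;
            for (int dy = 0; dy < 2; ++dy) {
              const int yc = y0 + dy;
              if (yc < 0 || yc >= sy) continue;
              const double wy = dy ? fy : 1.0 - fy;
              for (int dx = 0; dx < 2; ++dx) {
                const int xc = x0 + dx;
                if (xc < 0 || xc >= sx) continue;
                const double wx = dx ? fx : 1.0 - fx;
                acc += wx * wy * wz * s[xc + static_cast<R_xlen_t>(yc) * sx + zc * sxy];
              }
            }
          }
          o[idx] = acc;
        }
      }
    }
  }
  return out;
}

// Joint histogram plus per-a-bin conditional statistics of b, in one pass.
// mask_mode 0: joint foreground (both values nonzero); 1: a nonzero only.
// Values outside [amin,amax]/[bmin,bmax] are clamped into the edge bins.
// [[Rcpp::export]]
List cpp_joint_stats(NumericVector a, NumericVector b, int bins,
                     double amin, double amax, double bmin, double bmax,
                     int mask_mode) {
  NumericMatrix joint(bins, bins);
  NumericVector n_k(bins), sum_k(bins), sum2_k(bins);
  const double awidth = (amax > amin) ? (amax - amin) : 1.0;
  const double bwidth = (bmax > bmin) ? (bmax - bmin) : 1.0;
  const R_xlen_t n = a.size();
  R_xlen_t total = 0;
  double bsum = 0.0, bsum2 = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double av = a[i], bv = b[i];
    if (av == 0.0) continue;
    if (mask_mode == 0 && bv == 0.0) continue;
    int ai = static_cast<int>((av - amin) / awidth * bins);
    int bi = static_cast<int>((bv - bmin) / bwidth * bins);
    if (ai < 0) ai = 0; else if (ai >= bins) ai = bins - 1;
    if (bi < 0) bi = 0; else if (bi >= bins) bi = bins - 1;
    joint(ai, bi) += 1.0;
    n_k[ai] += 1.0;
    sum_k[ai] += bv;
    sum2_k[ai] += bv * bv;
    bsum += bv;
    bsum2 += bv * bv;
    ++total;
  }
  return List::create(_["joint"] = joint, _["n_k"] = n_k, _["sum_k"] = sum_k,
                      _["sum2_k"] = sum2_k, _["n"] = static_cast<double>(total),
                      _["b_sum"] = bsum, _["b_sum2"] = bsum2);
}

// Connected-component labelling of a 3D logical mask.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
// Labels are assigned in raster-scan order of the first voxel reached.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector labels(n);
  std::vector<int> offs_dx, offs_dy, offs_dz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int ord = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        offs_dx.push_back(dx); offs_dy.push_back(dy); offs_dz.push_back(dz);
      }
  const int noff = static_cast<int>(offs_dx.size());
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  const R_xlen_t nxy = static_cast<R_xlen_t>(nx) * ny;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++next_label;
    labels[seed] = next_label;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int cz = static_cast<int>(cur / nxy);
      const R_xlen_t rem = cur - static_cast<R_xlen_t>(cz) * nxy;
      const int cy = static_cast<int>(rem / nx);
      const int cx = static_cast<int>(rem - static_cast<R_xlen_t>(cy) * nx);
      for (int t = 0; t < noff; ++t) {
        const int x = cx + offs_dx[t], y = cy + offs_dy[t], z = cz + offs_dz[t];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        const R_xlen_t nb = x + static_cast<R_xlen_t>(y) * nx + z * nxy;
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next_label;
          stack.push_back(nb);
        }
      }
    }
  }
  return labels;
}

// Zero-padded 1D convolution along one axis of a 3D array.
// kernel has odd length; axis is 0 (x), 1 (y) or 2 (z).
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector x, IntegerVector dim,
                                NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  NumericVector out(x.size());
  const double *s = x.begin();
  const double *kp = kernel.begin();
  double *o = out.begin();
  const R_xlen_t nxy = static_cast<R_xlen_t>(nx) * ny;
  const int alen = (axis == 0) ? nx : (axis == 1 ? ny : nz);
  const R_xlen_t stride = (axis == 0) ? 1 : (axis == 1 ? nx : nxy);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i + static_cast<R_xlen_t>(j) * nx + k * nxy;
        const int pos = (axis == 0) ? i : (axis == 1 ? j : k);
        double acc = 0.0;
        for (int t = 0; t < klen; ++t) {
          const int q = pos + t - r;
          if (q < 0 || q >= alen) continue;
          acc += kp[t] * s[idx + static_cast<R_xlen_t>(q - pos) * stride];
        }
        o[idx] = acc;
      }
    }
  }
  return out;
}

// Masked variant of cpp_reg_cost: the similarity is evaluated only at a
// precomputed list of target-foreground voxels (0-based i/j/k and their
// target intensities), which is where the joint foreground can live.
// [[Rcpp::export]]
double cpp_reg_cost_masked(NumericVector src, IntegerVector sdim,
                           NumericMatrix M, IntegerVector fi,
                           IntegerVector fj, IntegerVector fk,
                           NumericVector tval, int bins,
                           double tmin, double tmax, int cost_type) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  const double *s = src.begin();
  const R_xlen_t sxy = static_cast<R_xlen_t>(sx) * sy;
  const R_xlen_t nf = fi.size();
  std::vector<double> moved(nf, 0.0);
  double mmin = R_PosInf, mmax = R_NegInf;
  for (R_xlen_t v = 0; v < nf; ++v) {
    const int i = fi[v], j = fj[v], k = fk[v];
    const double xs = m00 * i + m01 * j + m02 * k + m03;
    const double ys = m10 * i + m11 * j + m12 * k + m13;
    const double zs = m20 * i + m21 * j + m22 * k + m23;
    const double xf = std::floor(xs), yf = std::floor(ys), zf = std::floor(zs);
    const int x0 = static_cast<int>(xf), y0 = static_cast<int>(yf),
              z0 = static_cast<int>(zf);
    if (x0 < -1 || x0 >= sx || y0 < -1 || y0 >= sy || z0 < -1 || z0 >= sz)
      continue;
    const double fx = xs - xf, fy = ys - yf, fz = zs - zf;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz) {
      const int zc = z0 + dz;
      if (zc < 0 || zc >= sz) continue;
      const double wz = dz ? fz : 1.0 - fz;
      for (int dy = 0; dy < 2; ++dy) {
        const int yc = y0 + dy;
        if (yc < 0 || yc >= sy) continue;
        const double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx < 2; ++dx) {
          const int xc = x0 + dx;
          if (xc < 0 || xc >= sx) continue;
          const double wx = dx ? fx : 1.0 - fx;
          acc += wx * wy * wz * s[xc + static_cast<R_xlen_t>(yc) * sx + zc * sxy];
        }
      }
    }
    moved[v] = acc;
    if (acc != 0.0) {
      if (acc < mmin) mmin = acc;
      if (acc > mmax) mmax = acc;
    }
  }
  const double twidth = (tmax > tmin) ? (tmax - tmin) : 1.0;
  if (cost_type == 0) {
    if (!(mmax > mmin)) return -1e6;
    const double mwidth = mmax - mmin;
    std::vector<double> joint(static_cast<size_t>(bins) * bins, 0.0);
    double total = 0.0;
    for (R_xlen_t v = 0; v < nf; ++v) {
      const double mv = moved[v];
      if (mv == 0.0) continue;
      int ai = static_cast<int>((mv - mmin) / mwidth * bins);
      int bi = static_cast<int>((tval[v] - tmin) / twidth * bins);
      if (ai < 0) ai = 0; else if (ai >= bins) ai = bins - 1;
      if (bi < 0) bi = 0; else if (bi >= bins) bi = bins - 1;
      joint[static_cast<size_t>(ai) * bins + bi] += 1.0;
      total += 1.0;
    }
    if (total < 2.0) return -1e6;
    std::vector<double> pa(bins, 0.0), pb(bins, 0.0);
    for (int a = 0; a < bins; ++a)
      for (int b = 0; b < bins; ++b) {
        const double p = joint[static_cast<size_t>(a) * bins + b] / total;
        pa[a] += p; pb[b] += p;
      }
    double mi = 0.0;
    for (int a = 0; a < bins; ++a)
      for (int b = 0; b < bins; ++b) {
        const double p = joint[static_cast<size_t>(a) * bins + b] / total;
        if (p > 0.0) mi += p * std::log(p / (pa[a] * pb[b]));
      }
    return mi;
  }
  std::vector<double> n_k(bins, 0.0), s_k(bins, 0.0), s2_k(bins, 0.0);
  double total = 0.0, bsum = 0.0, bsum2 = 0.0;
  for (R_xlen_t v = 0; v < nf; ++v) {
    const double mv = moved[v];
    if (mv == 0.0) continue;
    int bi = static_cast<int>((tval[v] - tmin) / twidth * bins);
    if (bi < 0) bi = 0; else if (bi >= bins) bi = bins - 1;
    n_k[bi] += 1.0; s_k[bi] += mv; s2_k[bi] += mv * mv;
    bsum += mv; bsum2 += mv * mv;
    total += 1.0;
  }
  if (total < 2.0) return -1e6;
  const double var_b = bsum2 / total - (bsum / total) * (bsum / total);
  if (var_b <= 0.0) return -1e6;
  double within = 0.0;
  for (int k2 = 0; k2 < bins; ++k2) {
    if (n_k[k2] > 0.0) within += s2_k[k2] - s_k[k2] * s_k[k2] / n_k[k2];
  }
  double eta2 = 1.0 - within / (total * var_b);
  if (eta2 < 0.0) eta2 = 0.0;
  if (eta2 > 1.0) eta2 = 1.0;
  return eta2;
}
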