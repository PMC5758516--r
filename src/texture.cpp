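#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Half-sample reflection of an out-of-range index into [0, n-1]
// (mirror padding: -1 -> 0, n -> n-1), as used for all filter borders.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 1D true convolution along one dimension of a matrix with reflect padding.
// dim = 1: filter runs down the rows (vertical); dim = 2: along the columns
// (horizontal). Kernel length must be odd; centre at k[K/2].
// [[Rcpp::export]]
NumericMatrix conv1d_reflect(const NumericMatrix& x, const NumericVector& k, int dim) {
  const int nr = x.nrow(), nc = x.ncol(), K = k.size(), c = K / 2;
  NumericMatrix out(nr, nc);
  const double* xp = x.begin();
  double* op = out.begin();
  const double* kp = k.begin();
  if (dim == 1) {
    for (int j = 0; j < nc; ++j) {
      const double* col = xp + static_cast<R_xlen_t>(j) * nr;
      double* oc = op + static_cast<R_xlen_t>(j) * nr;
      int i = 0;
      for (; i < nr && (i - (K - 1 - c) < 0 || i + c >= nr); ++i) {
        double s = 0.0;
        for (int t = 0; t < K; ++t) s += kp[t] * col[reflect_idx(i - (t - c), nr)];
        oc[i] = s;
      }
      // interior fast path: all taps in range
      const int hi = nr - 1 - c;
      for (; i <= hi; ++i) {
        double s = 0.0;
        const double* base = col + i + c;  // t = 0 reads col[i + c]
        for (int t = 0; t < K; ++t) s += kp[t] * base[-t];
        oc[i] = s;
      }
      for (; i < nr; ++i) {
        double s = 0.0;
        for (int t = 0; t < K; ++t) s += kp[t] * col[reflect_idx(i - (t - c), nr)];
        oc[i] = s;
      }
    }
  } else {
    for (int j = 0; j < nc; ++j) {
      double* oc = op + static_cast<R_xlen_t>(j) * nr;
      const bool interior = (j - (K - 1 - c) >= 0) && (j + c < nc);
      for (int t = 0; t < K; ++t) {
        const int jj = interior ? (j - (t - c)) : reflect_idx(j - (t - c), nc);
        const double kt = kp[t];
        const double* col = xp + static_cast<R_xlen_t>(jj) * nr;
        if (t == 0) for (int i = 0; i < nr; ++i) oc[i] = kt * col[i];
        else        for (int i = 0; i < nr; ++i) oc[i] += kt * col[i];
      }
    }
  }
  return out;
}

// Per-pixel Haralick maps from local symmetrized GLCMs.
//
// q:    integer matrix of gray levels in 0..nlev-1 (values outside mask ignored)
// mask: logical matrix; GLCM pairs require both endpoints inside the window AND mask
// radius: window half-width (window is (2r+1)^2)
// doff/coff: displacement vectors (row offset, col offset), accumulated
// symmetric: also count the reversed pair
//
// Returns an nr x nc x 13 array; pixels outside the mask, or whose window
// yields no valid pair, are NaN in all 13 maps.
// Descriptor order: energy, contrast, correlation, variance, idm, sum_average,
// sum_variance, sum_entropy, entropy, difference_variance, difference_entropy,
// imc1, imc2.
// [[Rcpp::export]]
NumericVector haralick_maps_cpp(const IntegerMatrix& q, const LogicalMatrix& mask,
                                int nlev, int radius,
                                const IntegerVector& doff, const IntegerVector& coff,
                                bool symmetric) {
  const int nr = q.nrow(), nc = q.ncol(), noff = doff.size();
  NumericVector res(static_cast<R_xlen_t>(nr) * nc * 13, NA_REAL);
  res.attr("dim") = IntegerVector::create(nr, nc, 13);
  const R_xlen_t plane = static_cast<R_xlen_t>(nr) * nc;
  double* rp = res.begin();

  // local copies with raw access
  std::vector<int> qv(nr * nc);
  std::vector<unsigned char> mv(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      qv[j * nr + i] = q(i, j);
      mv[j * nr + i] = mask(i, j) ? 1 : 0;
    }

  // integer counts: all probabilities are c / total, so every log is a
  // table lookup of log(c) for integer c
  const int side = 2 * radius + 1;
  const int max_cnt = side * side * noff * (symmetric ? 2 : 1) + 1;
  std::vector<double> logt(max_cnt + 1, 0.0);
  for (int c = 1; c <= max_cnt; ++c) logt[c] = std::log(static_cast<double>(c));

  std::vector<int> P(static_cast<size_t>(nlev) * nlev, 0);
  std::vector<int> touched;
  touched.reserve(2048);
  std::vector<int> cx(nlev), cy(nlev), cxy(2 * nlev), cmd(nlev);
  std::vector<int> tx, ty, txy, tmd;
  tx.reserve(nlev); ty.reserve(nlev); txy.reserve(2 * nlev); tmd.reserve(nlev);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mv[j * nr + i]) continue;
      const int r0 = std::max(0, i - radius), r1 = std::min(nr - 1, i + radius);
      const int c0 = std::max(0, j - radius), c1 = std::min(nc - 1, j + radius);
      touched.clear();
      int total = 0;
      for (int b = c0; b <= c1; ++b) {
        const int bo = b * nr;
        for (int a = r0; a <= r1; ++a) {
          if (!mv[bo + a]) continue;
          const int g1 = qv[bo + a];
          for (int o = 0; o < noff; ++o) {
            const int a2 = a + doff[o], b2 = b + coff[o];
            if (a2 < r0 || a2 > r1 || b2 < c0 || b2 > c1) continue;
            if (!mv[b2 * nr + a2]) continue;
            const int g2 = qv[b2 * nr + a2];
            int idx = g1 * nlev + g2;
            if (P[idx] == 0) touched.push_back(idx);
            ++P[idx];
            ++total;
            if (symmetric) {
              idx = g2 * nlev + g1;
              if (P[idx] == 0) touched.push_back(idx);
              ++P[idx];
              ++total;
            }
          }
        }
      }
      if (total == 0) continue;  // no valid pair: stays NaN

      tx.clear(); ty.clear(); txy.clear(); tmd.clear();
      const double tot = static_cast<double>(total);
      const double ltot = logt[total];

      double energy = 0.0, contrast = 0.0, hxy = 0.0, sij = 0.0, idm = 0.0,
             hxy1 = 0.0;
      for (size_t t = 0; t < touched.size(); ++t) {
        const int idx = touched[t];
        const int cnt = P[idx];
        const int gi = idx / nlev, gj = idx % nlev;
        if (cx[gi] == 0) tx.push_back(gi);
        cx[gi] += cnt;
        if (cy[gj] == 0) ty.push_back(gj);
        cy[gj] += cnt;
        if (cxy[gi + gj] == 0) txy.push_back(gi + gj);
        cxy[gi + gj] += cnt;
        const int d = gi >= gj ? gi - gj : gj - gi;
        if (cmd[d] == 0) tmd.push_back(d);
        cmd[d] += cnt;
      }
      double mux = 0.0, muy = 0.0;
      for (size_t t = 0; t < tx.size(); ++t)
        mux += (tx[t] + 1.0) * cx[tx[t]];
      for (size_t t = 0; t < ty.size(); ++t)
        muy += (ty[t] + 1.0) * cy[ty[t]];
      mux /= tot; muy /= tot;
      double vx = 0.0, vy = 0.0, hx = 0.0, hy = 0.0;
      for (size_t t = 0; t < tx.size(); ++t) {
        const int g = tx[t]; const double p = cx[g] / tot;
        vx += (g + 1.0 - mux) * (g + 1.0 - mux) * p;
        hx -= p * (logt[cx[g]] - ltot);
      }
      for (size_t t = 0; t < ty.size(); ++t) {
        const int g = ty[t]; const double p = cy[g] / tot;
        vy += (g + 1.0 - muy) * (g + 1.0 - muy) * p;
        hy -= p * (logt[cy[g]] - ltot);
      }
      for (size_t t = 0; t < touched.size(); ++t) {
        const int idx = touched[t];
        const int cnt = P[idx];
        const double p = cnt / tot;
        const int gi = idx / nlev, gj = idx % nlev;
        const double d = gi - gj;
        energy += p * p;
        contrast += d * d * p;
        sij += (gi + 1.0) * (gj + 1.0) * p;
        idm += p / (1.0 + d * d);
        hxy -= p * (logt[cnt] - ltot);
        // log(px * py) = log cx + log cy - 2 log total
        hxy1 -= p * (logt[cx[gi]] + logt[cy[gj]] - 2.0 * ltot);
      }
      const double sdxy = std::sqrt(vx * vy);
      const double correlation = (sdxy > 1e-12) ? (sij - mux * muy) / sdxy : 0.0;
      const double variance = vx;  // sum of squares about the marginal mean
      double sum_avg = 0.0, sum_ent = 0.0;
      for (size_t t = 0; t < txy.size(); ++t) {
        const int s = txy[t]; const double p = cxy[s] / tot;
        sum_avg += (s + 2.0) * p;  // level values are 1-based: i+j in 2..2L
        sum_ent -= p * (logt[cxy[s]] - ltot);
      }
      double sum_var = 0.0;
      for (size_t t = 0; t < txy.size(); ++t) {
        const int s = txy[t];
        sum_var += (s + 2.0 - sum_avg) * (s + 2.0 - sum_avg) * (cxy[s] / tot);
      }
      double dmean = 0.0, diff_ent = 0.0;
      for (size_t t = 0; t < tmd.size(); ++t) {
        const int d = tmd[t]; const double p = cmd[d] / tot;
        dmean += d * p;
        diff_ent -= p * (logt[cmd[d]] - ltot);
      }
      double diff_var = 0.0;
      for (size_t t = 0; t < tmd.size(); ++t) {
        const int d = tmd[t];
        diff_var += (d - dmean) * (d - dmean) * (cmd[d] / tot);
      }
      // HXY2 = -sum px(i)py(j) log(px(i)py(j)) = HX + HY exactly
      const double hxy2 = hx + hy;
      const double hmax = std::max(hx, hy);
      const double imc1 = (hmax > 1e-12) ? (hxy - hxy1) / hmax : 0.0;
      double e2 = 1.0 - std::exp(-2.0 * (hxy2 - hxy));
      if (e2 < 0.0) e2 = 0.0;
      const double imc2 = std::sqrt(e2);

      const R_xlen_t base = static_cast<R_xlen_t>(j) * nr + i;
      rp[base + 0 * plane] = energy;
      rp[base + 1 * plane] = contrast;
      rp[base + 2 * plane] = correlation;
      rp[base + 3 * plane] = variance;
      rp[base + 4 * plane] = idm;
      rp[base + 5 * plane] = sum_avg;
      rp[base + 6 * plane] = sum_var;
      rp[base + 7 * plane] = sum_ent;
      rp[base + 8 * plane] = hxy;
      rp[base + 9 * plane] = diff_var;
      rp[base + 10 * plane] = diff_ent;
      rp[base + 11 * plane] = imc1;
      rp[base + 12 * plane] = imc2;

      for (size_t t = 0; t < touched.size(); ++t) P[touched[t]] = 0;
      for (size_t t = 0; t < tx.size(); ++t) cx[tx[t]] = 0;
      for (size_t t = 0; t < ty.size(); ++t) cy[ty[t]] = 0;
      for (size_t t = 0; t < txy.size(); ++t) cxy[txy[t]] = 0;
      for (size_t t = 0; t < tmd.size(); ++t) cmd[tmd[t]] = 0;
    }
  }
  return res;
}
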