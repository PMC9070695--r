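// Core of the PSD-aware volumetric collaborative filter: block matching,
// 4-D transform shrinkage (separable orthonormal DCT on cubes, Haar across
// the grouping dimension) with per-coefficient noise standard deviations,
// hard-threshold and Wiener stages, and weighted aggregation.
//
// The filter is deterministic given its inputs (no RNG). Indexing follows
// R's column-major layout: linear index i + n0*(j + n1*k).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

namespace {

struct VolView {
  const double* p;
  int n0, n1, n2;
  inline double at(int i, int j, int k) const {
    return p[i + (std::size_t)n0 * (j + (std::size_t)n1 * k)];
  }
};

// Orthonormal DCT-II matrix, row i = basis function i.
static std::vector<double> dct_matrix(int L) {
  std::vector<double> T((std::size_t)L * L);
  for (int i = 0; i < L; ++i) {
    double c = (i == 0) ? std::sqrt(1.0 / L) : std::sqrt(2.0 / L);
    for (int a = 0; a < L; ++a) {
      T[(std::size_t)i * L + a] = c * std::cos(M_PI * (2 * a + 1) * i / (2.0 * L));
    }
  }
  return T;
}

// Apply matrix M (L x L, row-major) along one axis of an L^3 cube.
static void apply_axis(const std::vector<double>& M, double* cube, int L, int axis,
                       std::vector<double>& tmp) {
  int s0 = 1, s1 = L, s2 = L * L;
  int sa = (axis == 0) ? s0 : (axis == 1) ? s1 : s2;
  int sb, sc, nb = L, nc = L;
  if (axis == 0) { sb = s1; sc = s2; }
  else if (axis == 1) { sb = s0; sc = s2; }
  else { sb = s0; sc = s1; }
  for (int b = 0; b < nb; ++b) {
    for (int c = 0; c < nc; ++c) {
      double* base = cube + b * sb + c * sc;
      for (int i = 0; i < L; ++i) {
        double acc = 0.0;
        for (int a = 0; a < L; ++a) acc += M[(std::size_t)i * L + a] * base[a * sa];
        tmp[i] = acc;
      }
      for (int i = 0; i < L; ++i) base[i * sa] = tmp[i];
    }
  }
}

static void dct3(const std::vector<double>& T, double* cube, int L,
                 std::vector<double>& tmp) {
  apply_axis(T, cube, L, 0, tmp);
  apply_axis(T, cube, L, 1, tmp);
  apply_axis(T, cube, L, 2, tmp);
}

static void idct3(const std::vector<double>& Tt, double* cube, int L,
                  std::vector<double>& tmp) {
  apply_axis(Tt, cube, L, 0, tmp);
  apply_axis(Tt, cube, L, 1, tmp);
  apply_axis(Tt, cube, L, 2, tmp);
}

// In-place orthonormal Haar wavelet transform across the group dimension.
// data laid out as grp[g * csz + c]; transforms each coefficient c across g.
static void haar_fwd(std::vector<double>& grp, int G, int csz, std::vector<double>& buf) {
  const double s = M_SQRT1_2;
  for (int len = G; len > 1; len /= 2) {
    int half = len / 2;
    for (int c = 0; c < csz; ++c) {
      for (int g = 0; g < half; ++g) {
        double a = grp[(std::size_t)(2 * g) * csz + c];
        double b = grp[(std::size_t)(2 * g + 1) * csz + c];
        buf[g] = (a + b) * s;
        buf[half + g] = (a - b) * s;
      }
      for (int g = 0; g < len; ++g) grp[(std::size_t)g * csz + c] = buf[g];
    }
  }
}

static void haar_inv(std::vector<double>& grp, int G, int csz, std::vector<double>& buf) {
  const double s = M_SQRT1_2;
  for (int len = 2; len <= G; len *= 2) {
    int half = len / 2;
    for (int c = 0; c < csz; ++c) {
      for (int g = 0; g < half; ++g) {
        double a = grp[(std::size_t)g * csz + c];
        double d = grp[(std::size_t)(half + g) * csz + c];
        buf[2 * g] = (a + d) * s;
        buf[2 * g + 1] = (a - d) * s;
      }
      for (int g = 0; g < len; ++g) grp[(std::size_t)g * csz + c] = buf[g];
    }
  }
}

// Grid of cube origins with the given step, forcing a cube flush with the
// far edge so the whole volume is covered.
static std::vector<int> grid_positions(int n, int L, int step) {
  std::vector<int> pos;
  for (int i = 0; i + L <= n; i += step) pos.push_back(i);
  if (pos.empty() || pos.back() != n - L) pos.push_back(n - L);
  return pos;
}

struct Cand {
  double d;
  int i, j, k;
  long ord;  // raster order for deterministic tie-breaking
};

}  // namespace

// In-place orthonormal Haar transform of a length-G vector (G a power of 2).
static void haar_vec(double* v, int G, double* buf) {
  const double s = M_SQRT1_2;
  for (int len = G; len > 1; len /= 2) {
    int half = len / 2;
    for (int g = 0; g < half; ++g) {
      buf[g] = (v[2 * g] + v[2 * g + 1]) * s;
      buf[half + g] = (v[2 * g] - v[2 * g + 1]) * s;
    }
    for (int g = 0; g < len; ++g) v[g] = buf[g];
  }
}

// Noisy coefficients of cubes that overlap, or that sit at the same detector
// position displaced along the angle (streak noise is angularly constant),
// are correlated across the group. For the cube subbands listed in
// table_map, cov_table holds the cross-cube covariance of the subband as a
// function of the 3-D cube offset; the per-group-index noise variances are
// then the diagonal of the Haar-transformed G x G covariance matrix.
// Remaining subbands are treated as independent across cubes with variance
// sigma_cube^2.

// [[Rcpp::export(name = ".bm4d_core")]]
List bm4d_core(NumericVector z, NumericVector match_vol, IntegerVector dims,
               NumericVector sigma_cube, int cube, int step,
               IntegerVector search_rad,
               int max_group, double lambda, bool wiener, NumericVector pilot,
               NumericVector cov_table, IntegerVector table_map,
               IntegerVector cov_W, double preserve_var) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const int L = cube;
  const int csz = L * L * L;
  VolView Z{REAL(z), n0, n1, n2};
  VolView Mv{REAL(match_vol), n0, n1, n2};
  VolView Pv{wiener ? REAL(pilot) : REAL(z), n0, n1, n2};

  std::vector<double> T = dct_matrix(L);
  std::vector<double> Tt((std::size_t)L * L);
  for (int i = 0; i < L; ++i)
    for (int a = 0; a < L; ++a) Tt[(std::size_t)a * L + i] = T[(std::size_t)i * L + a];

  const double* sig = REAL(sigma_cube);  // per cube-coefficient noise sd

  NumericVector num((std::size_t)n0 * n1 * n2);
  NumericVector den((std::size_t)n0 * n1 * n2);
  double* numP = REAL(num);
  double* denP = REAL(den);

  std::vector<int> pos0 = grid_positions(n0, L, step);
  std::vector<int> pos1 = grid_positions(n1, L, step);
  std::vector<int> pos2 = grid_positions(n2, L, step);

  std::vector<Cand> cands;
  const int r0 = search_rad[0], r1 = search_rad[1], r2 = search_rad[2];
  cands.reserve((std::size_t)(2 * r0 + 1) * (2 * r1 + 1) * (2 * r2 + 1));
  std::vector<double> refc(csz), cbuf(csz), tmp(L);
  std::vector<double> grp((std::size_t)max_group * csz);
  std::vector<double> grpP((std::size_t)max_group * csz);
  std::vector<double> hbuf(max_group);
  std::vector<int> gi(max_group), gj(max_group), gk(max_group);

  const bool have_cov = cov_table.size() > 1;
  const int w0 = cov_W[0], w1 = cov_W[1], w2 = cov_W[2];
  const int tw0 = 2 * w0 + 1, tw1 = 2 * w1 + 1, tw2 = 2 * w2 + 1;
  const std::size_t tstride = (std::size_t)tw0 * tw1 * tw2;
  const double* covP = have_cov ? REAL(cov_table) : nullptr;
  const int* tmap = INTEGER(table_map);
  std::vector<std::size_t> pair_off((std::size_t)max_group * max_group);
  std::vector<double> C((std::size_t)max_group * max_group);
  std::vector<double> vg(max_group);

  const double eps = 1e-12;

  for (int ri : pos0) {
    for (int rj : pos1) {
      for (int rk : pos2) {
        // --- block matching on the (whitened / pilot) matching volume ---
        for (int a = 0; a < L; ++a)
          for (int b = 0; b < L; ++b)
            for (int c = 0; c < L; ++c)
              refc[a + L * (b + L * c)] = Mv.at(ri + a, rj + b, rk + c);
        int i_lo = std::max(0, ri - r0), i_hi = std::min(n0 - L, ri + r0);
        int j_lo = std::max(0, rj - r1), j_hi = std::min(n1 - L, rj + r1);
        int k_lo = std::max(0, rk - r2), k_hi = std::min(n2 - L, rk + r2);
        int n_cand = (i_hi - i_lo + 1) * (j_hi - j_lo + 1) * (k_hi - k_lo + 1);
        int G = 1;
        while (2 * G <= n_cand && 2 * G <= max_group) G *= 2;
        // sorted top-G insertion with early abort of the SSD accumulation
        cands.assign((std::size_t)G, Cand{std::numeric_limits<double>::infinity(),
                                          0, 0, 0, std::numeric_limits<long>::max()});
        auto better = [](double d, long ord, const Cand& c) {
          return d < c.d || (d == c.d && ord < c.ord);
        };
        int filled = 0;
        for (int k = k_lo; k <= k_hi; ++k) {
          for (int j = j_lo; j <= j_hi; ++j) {
            for (int i = i_lo; i <= i_hi; ++i) {
              long ord = i + (long)n0 * (j + (long)n1 * k);
              double d;
              if (i == ri && j == rj && k == rk) {
                d = -1.0;  // reference first
              } else {
                double cutoff = (filled == G) ? cands[G - 1].d :
                                std::numeric_limits<double>::infinity();
                d = 0.0;
                for (int c = 0; c < L && d <= cutoff; ++c)
                  for (int b = 0; b < L; ++b)
                    for (int a = 0; a < L; ++a) {
                      double diff = Mv.at(i + a, j + b, k + c) - refc[a + L * (b + L * c)];
                      d += diff * diff;
                    }
                if (d > cutoff) continue;
              }
              if (filled == G && !better(d, ord, cands[G - 1])) continue;
              int pos = (filled < G) ? filled++ : G - 1;
              while (pos > 0 && better(d, ord, cands[pos - 1])) {
                cands[pos] = cands[pos - 1];
                --pos;
              }
              cands[pos] = Cand{d, i, j, k, ord};
            }
          }
        }

        // --- gather group, 3-D DCT per cube ---
        for (int g = 0; g < G; ++g) {
          gi[g] = cands[g].i; gj[g] = cands[g].j; gk[g] = cands[g].k;
          double* dst = grp.data() + (std::size_t)g * csz;
          for (int c = 0; c < L; ++c)
            for (int b = 0; b < L; ++b)
              for (int a = 0; a < L; ++a)
                dst[a + L * (b + L * c)] = Z.at(gi[g] + a, gj[g] + b, gk[g] + c);
          dct3(T, dst, L, tmp);
          if (wiener) {
            double* dp = grpP.data() + (std::size_t)g * csz;
            for (int c = 0; c < L; ++c)
              for (int b = 0; b < L; ++b)
                for (int a = 0; a < L; ++a)
                  dp[a + L * (b + L * c)] = Pv.at(gi[g] + a, gj[g] + b, gk[g] + c);
            dct3(T, dp, L, tmp);
          }
        }
        haar_fwd(grp, G, csz, hbuf);
        if (wiener) haar_fwd(grpP, G, csz, hbuf);

        // --- shrinkage ---
        if (have_cov) {
          for (int g = 0; g < G; ++g) {
            for (int g2 = 0; g2 < G; ++g2) {
              int da = gi[g] - gi[g2] + w0;
              int dj = gj[g] - gj[g2] + w1;
              int dk = gk[g] - gk[g2] + w2;
              pair_off[(std::size_t)g * G + g2] =
                (std::size_t)da + (std::size_t)tw0 * (dj + (std::size_t)tw1 * dk);
            }
          }
        }
        double noise_energy = 0.0;
        for (int c = 0; c < csz; ++c) {
          int tid = have_cov ? tmap[c] : -1;
          if (tid >= 0) {
            const double* tab = covP + tstride * tid;
            for (int g = 0; g < G; ++g)
              for (int g2 = 0; g2 < G; ++g2)
                C[(std::size_t)g * G + g2] = tab[pair_off[(std::size_t)g * G + g2]];
            for (int g = 0; g < G; ++g) haar_vec(C.data() + (std::size_t)g * G, G, hbuf.data());
            for (int g2 = 0; g2 < G; ++g2) {
              for (int g = 0; g < G; ++g) vg[g] = C[(std::size_t)g * G + g2];
              haar_vec(vg.data(), G, hbuf.data());
              for (int g = 0; g < G; ++g) C[(std::size_t)g * G + g2] = vg[g];
            }
            for (int g = 0; g < G; ++g)
              vg[g] = std::max(C[(std::size_t)g * G + g], 0.0);
          } else {
            double s2 = sig[c] * sig[c];
            for (int g = 0; g < G; ++g) vg[g] = s2;
          }
          if (!wiener) {
            for (int g = 0; g < G; ++g) {
              double* co = grp.data() + (std::size_t)g * csz + c;
              if (vg[g] > 0.0 && std::fabs(*co) < lambda * std::sqrt(vg[g])) {
                *co = 0.0;
              } else {
                noise_energy += vg[g];
              }
            }
          } else {
            for (int g = 0; g < G; ++g) {
              double* co = grp.data() + (std::size_t)g * csz + c;
              double p = grpP[(std::size_t)g * csz + c];
              // preserve_var: white-noise energy belonging to the target
              // (e.g. Poisson noise during streak-only filtering) is part
              // of the spectrum to keep, not of the noise to remove.
              double p2 = p * p + preserve_var;
              double gain = (vg[g] > 0.0) ? p2 / (p2 + vg[g]) : 1.0;
              *co *= gain;
              noise_energy += gain * gain * vg[g];
            }
          }
        }
        double w = 1.0 / (eps + noise_energy);

        // --- inverse transform and aggregation ---
        haar_inv(grp, G, csz, hbuf);
        for (int g = 0; g < G; ++g) {
          double* co = grp.data() + (std::size_t)g * csz;
          idct3(Tt, co, L, tmp);
          for (int c = 0; c < L; ++c)
            for (int b = 0; b < L; ++b)
              for (int a = 0; a < L; ++a) {
                std::size_t off = (gi[g] + a) +
                  (std::size_t)n0 * ((gj[g] + b) + (std::size_t)n1 * (gk[g] + c));
                numP[off] += w * co[a + L * (b + L * c)];
                denP[off] += w;
              }
        }
      }
    }
  }
  return List::create(_["num"] = num, _["den"] = den);
}
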