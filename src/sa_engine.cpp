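// Simulated-annealing reconstruction engine.
//
// The hot loop exploits two structural facts:
//  * the perturbation is separable, delta(x,y,z) = a * gx(x) gy(y) gz(z),
//    so its shear-sum projection at angle theta factorizes into
//    px(x') (x-z profile sheared by z*tan(theta)) times gy(y);
//  * the error is quadratic, so with cached residuals R_k = P_k - I_k,
//    dE_k = a^2 * sum(px^2) * sum(gy^2) + 2a * sum_{x',y} px gy R_k.
// One step therefore costs O(footprint^2) per angle instead of a full
// reprojection, and accepted steps update volume and residuals in place.
//
// All randomness comes from R's generator (unif_rand/norm_rand), consumed
// in a fixed order per step: 3 uniforms (center), 1 normal (amplitude),
// and 1 uniform only when the proposal is uphill. This matches the R
// reference engine exactly, so one seed reproduces either path.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List sa_engine_cpp(IntegerVector dims, NumericVector measured,
                   NumericVector tan_angles,
                   NumericVector T_cyc, NumericVector k_cyc,
                   NumericVector s_cyc, int iters_per_cycle,
                   double truncation, bool nonneg) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int K = tan_angles.size();
  const int C = T_cyc.size();
  const R_xlen_t npix = (R_xlen_t)nx * ny;

  std::vector<double> V((R_xlen_t)nx * ny * nz, 0.0);
  // residuals R_k = P_k - I_k; volume starts empty, so R = -I
  std::vector<double> R((R_xlen_t)npix * K);
  double E = 0.0;
  for (R_xlen_t i = 0; i < (R_xlen_t)npix * K; ++i) {
    R[i] = -measured[i];
    E += R[i] * R[i];
  }

  std::vector<double> g(2 * (size_t)std::ceil(truncation * k_cyc[0]) + 3);
  std::vector<double> px((size_t)K * nx, 0.0);
  std::vector<int> fmin(K), fmax(K);
  NumericMatrix history(C, 7 + K);
  LogicalVector degenerate(1);
  degenerate[0] = false;

  RNGScope scope;

  for (int cyc = 0; cyc < C; ++cyc) {
    const double T = T_cyc[cyc], ksd = k_cyc[cyc], psd = s_cyc[cyc];
    const int h = (int)std::ceil(truncation * ksd);
    g.assign(2 * h + 1, 0.0);
    for (int i = -h; i <= h; ++i)
      g[i + h] = std::exp(-0.5 * (i / ksd) * (i / ksd));

    long accepted = 0, uphill = 0, uphill_acc = 0;
    for (int it = 0; it < iters_per_cycle; ++it) {
      // proposal: center (3 uniforms) then amplitude (1 normal)
      int cx = (int)(unif_rand() * nx); if (cx >= nx) cx = nx - 1;
      int cy = (int)(unif_rand() * ny); if (cy >= ny) cy = ny - 1;
      int cz = (int)(unif_rand() * nz); if (cz >= nz) cz = nz - 1;
      const double a = norm_rand() * psd;

      const int x0 = std::max(0, cx - h), x1 = std::min(nx - 1, cx + h);
      const int y0 = std::max(0, cy - h), y1 = std::min(ny - 1, cy + h);
      const int z0 = std::max(0, cz - h), z1 = std::min(nz - 1, cz + h);

      double Syy = 0.0;
      for (int y = y0; y <= y1; ++y) {
        const double gy = g[y - cy + h];
        Syy += gy * gy;
      }

      double dE = 0.0;
      for (int k = 0; k < K; ++k) {
        const double t = tan_angles[k];
        double* pk = &px[(size_t)k * nx];
        // scatter the sheared x-z kernel profile into image-x bins
        int lo = nx, hi = -1;
        for (int z = z0; z <= z1; ++z) {
          const double shift = z * t;
          const double fs = std::floor(shift);
          const double w = shift - fs;
          const int ifs = (int)fs;
          const double gz = g[z - cz + h];
          for (int x = x0; x <= x1; ++x) {
            const double gv = gz * g[x - cx + h];
            const int f = x + ifs;
            if (f >= 0 && f < nx) {
              pk[f] += gv * (1.0 - w);
              if (f < lo) lo = f;
              if (f > hi) hi = f;
            }
            if (f + 1 >= 0 && f + 1 < nx) {
              pk[f + 1] += gv * w;
              if (f + 1 < lo) lo = f + 1;
              if (f + 1 > hi) hi = f + 1;
            }
          }
        }
        fmin[k] = lo; fmax[k] = hi;
        if (hi < lo) continue;
        double Sxx = 0.0, cross = 0.0;
        const double* Rk = &R[(size_t)k * npix];
        for (int f = lo; f <= hi; ++f) {
          const double p = pk[f];
          Sxx += p * p;
          double rsum = 0.0;
          const double* col = Rk + f;  // stride nx along y
          for (int y = y0; y <= y1; ++y)
            rsum += g[y - cy + h] * col[(size_t)y * nx];
          cross += p * rsum;
        }
        dE += a * a * Sxx * Syy + 2.0 * a * cross;
      }

      // optional non-negativity constraint: a proposal that would push
      // any voxel below zero is infeasible and rejected outright (only
      // negative amplitudes can do so from a non-negative volume)
      bool feasible = true;
      if (nonneg && a < 0.0) {
        for (int z = z0; feasible && z <= z1; ++z) {
          const double agz = a * g[z - cz + h];
          for (int y = y0; feasible && y <= y1; ++y) {
            const double agzy = agz * g[y - cy + h];
            const double* vcol = &V[((R_xlen_t)z * ny + y) * nx];
            for (int x = x0; x <= x1; ++x)
              if (vcol[x] + agzy * g[x - cx + h] < 0.0) { feasible = false; break; }
          }
        }
      }

      bool accept;
      if (!feasible) accept = false;
      else if (dE <= 0.0) accept = true;
      else {
        ++uphill;
        accept = (unif_rand() < std::exp(-dE / T));
        if (accept) ++uphill_acc;
      }

      if (accept) {
        ++accepted;
        E += dE;
        // volume update: a * gx gy gz over the clipped box
        for (int z = z0; z <= z1; ++z) {
          const double agz = a * g[z - cz + h];
          for (int y = y0; y <= y1; ++y) {
            const double agzy = agz * g[y - cy + h];
            double* vcol = &V[((R_xlen_t)z * ny + y) * nx];
            for (int x = x0; x <= x1; ++x)
              vcol[x] += agzy * g[x - cx + h];
          }
        }
        // residual update: R_k += a * px (x) gy
        for (int k = 0; k < K; ++k) {
          if (fmax[k] < fmin[k]) continue;
          double* Rk = &R[(size_t)k * npix];
          const double* pk = &px[(size_t)k * nx];
          for (int y = y0; y <= y1; ++y) {
            const double agy = a * g[y - cy + h];
            double* row = Rk + (size_t)y * nx;
            for (int f = fmin[k]; f <= fmax[k]; ++f)
              row[f] += agy * pk[f];
          }
        }
      }

      // clear the touched px bins for the next step
      for (int k = 0; k < K; ++k) {
        double* pk = &px[(size_t)k * nx];
        for (int f = fmin[k]; f <= fmax[k]; ++f) pk[f] = 0.0;
      }
    }

    // cycle record: schedule values, cached error, acceptance rate and
    // per-position Pearson correlation between reprojection and input
    history(cyc, 0) = cyc + 1;
    history(cyc, 1) = T;
    history(cyc, 2) = ksd;
    history(cyc, 3) = psd;
    history(cyc, 4) = E;
    history(cyc, 5) = (double)accepted / iters_per_cycle;
    history(cyc, 6) = uphill > 0 ? (double)uphill_acc / uphill : 0.0;
    for (int k = 0; k < K; ++k) {
      const double* Rk = &R[(size_t)k * npix];
      const double* Ik = &measured[(size_t)k * npix];
      double sp = 0, sm = 0, spp = 0, smm = 0, spm = 0;
      for (R_xlen_t i = 0; i < npix; ++i) {
        const double p = Rk[i] + Ik[i], m = Ik[i];
        sp += p; sm += m; spp += p * p; smm += m * m; spm += p * m;
      }
      const double vp = spp - sp * sp / npix;
      const double vm = smm - sm * sm / npix;
      const double cv = spm - sp * sm / npix;
      if (vp <= 0.0 || vm <= 0.0) {
        history(cyc, 7 + k) = 0.0;
        degenerate[0] = true;
      } else {
        history(cyc, 7 + k) = cv / std::sqrt(vp * vm);
      }
    }
    if (cyc % 16 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector vol(V.begin(), V.end());
  NumericVector res(R.begin(), R.end());
  res.attr("dim") = IntegerVector::create(nx, ny, K);
  return List::create(_["volume"] = vol, _["residuals"] = res,
                      _["error"] = E, _["history"] = history,
                      _["degenerate"] = degenerate[0]);
}
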