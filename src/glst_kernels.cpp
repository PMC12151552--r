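#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// All kernels work in internal units (elementary charge^2 / Angstrom); the
// Coulomb constant is applied on the R side. Atom arrays arrive sorted by
// cell; cell_start is a 0-based offset vector of length n_cells + 1.

#if defined(__linux__)
extern "C" void sincos(double, double*, double*);
#define GLST_SINCOS(ph, s, c) sincos((ph), (s), (c))
#else
#define GLST_SINCOS(ph, s, c) do { *(s) = std::sin(ph); *(c) = std::cos(ph); } while (0)
#endif

static inline void trig_eval(double ph, bool single_trig, double &c, double &s) {
  if (single_trig) {
    float pf = (float)ph;
    c = (double)cosf(pf);
    s = (double)sinf(pf);
  } else {
    GLST_SINCOS(ph, &s, &c);
  }
}

// Long-range pass for one alpha group: per-cell structure factors, remote
// sums over the group's Chebyshev shell [smin, smax] via 3-D inclusive
// prefix sums (summed-area tables, open boundaries = natural clipping),
// then the per-atom energy/force pass. Node dimension is chunked to bound
// memory. Returns per-atom energy (each ordered pair counted once in each
// direction, i.e. unhalved) and forces, in sorted-atom order.
// [[Rcpp::export]]
List cpp_group_pass(NumericMatrix pos, NumericVector q, IntegerVector ncell,
                    IntegerVector cell_start, NumericMatrix K, NumericVector W,
                    int smin, int smax, int chunk, bool single_trig) {
  const int n = pos.nrow();
  const long J = K.nrow();
  const int nx = ncell[0], ny = ncell[1], nz = ncell[2];
  const long ncells = (long)nx * ny * nz;

  NumericVector E(n);
  NumericMatrix F(n, 3);
  const double *kx = &K(0, 0), *ky = &K(0, 1), *kz = &K(0, 2);
  const double *pw = &W[0];
  const double *px = &pos(0, 0), *py = &pos(0, 1), *pz = &pos(0, 2);

  if (chunk < 1) chunk = 1;
  std::vector<double> SC, SS, RC, RS;

  for (long j0 = 0; j0 < J; j0 += chunk) {
    const int jc = (int)std::min((long)chunk, J - j0);
    SC.assign(ncells * jc, 0.0);
    SS.assign(ncells * jc, 0.0);
    RC.assign(jc, 0.0);
    RS.assign(jc, 0.0);

    // structure-factor pass
    for (long ic = 0; ic < ncells; ++ic) {
      const int a0 = cell_start[ic], a1 = cell_start[ic + 1];
      if (a0 == a1) continue;
      double *sc = &SC[ic * jc], *ss = &SS[ic * jc];
      for (int a = a0; a < a1; ++a) {
        const double x = px[a], y = py[a], z = pz[a], qa = q[a];
        for (int j = 0; j < jc; ++j) {
          const long jj = j0 + j;
          const double ph = kx[jj] * x + ky[jj] * y + kz[jj] * z;
          double c, s;
          trig_eval(ph, single_trig, c, s);
          sc[j] += qa * c;
          ss[j] += qa * s;
        }
      }
    }

    // in-place 3-D inclusive prefix sums over the cell grid
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy) {
        const long base = ((long)iz * ny + iy) * nx;
        for (int ix = 1; ix < nx; ++ix) {
          double *cur = &SC[(base + ix) * jc], *prv = &SC[(base + ix - 1) * jc];
          double *curs = &SS[(base + ix) * jc], *prvs = &SS[(base + ix - 1) * jc];
          for (int j = 0; j < jc; ++j) { cur[j] += prv[j]; curs[j] += prvs[j]; }
        }
      }
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 1; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          const long cur = (((long)iz * ny + iy) * nx + ix) * jc;
          const long prv = (((long)iz * ny + iy - 1) * nx + ix) * jc;
          for (int j = 0; j < jc; ++j) { SC[cur + j] += SC[prv + j]; SS[cur + j] += SS[prv + j]; }
        }
    for (int iz = 1; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          const long cur = (((long)iz * ny + iy) * nx + ix) * jc;
          const long prv = ((((long)iz - 1) * ny + iy) * nx + ix) * jc;
          for (int j = 0; j < jc; ++j) { SC[cur + j] += SC[prv + j]; SS[cur + j] += SS[prv + j]; }
        }

    // box-sum accumulator via 8-corner inclusion-exclusion on the prefix
    // tables; sgn flips for the inner (excluded) box
    auto add_box = [&](int ix, int iy, int iz, int s, double sgn) {
      const int xhi = std::min(nx - 1, ix + s), xlo = ix - s - 1;
      const int yhi = std::min(ny - 1, iy + s), ylo = iy - s - 1;
      const int zhi = std::min(nz - 1, iz + s), zlo = iz - s - 1;
      const int xs[2] = {xhi, xlo}, ys[2] = {yhi, ylo}, zs[2] = {zhi, zlo};
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b)
          for (int c = 0; c < 2; ++c) {
            if (xs[a] < 0 || ys[b] < 0 || zs[c] < 0) continue;
            const double sg = sgn * (((a + b + c) % 2) ? -1.0 : 1.0);
            const double *pc = &SC[(((long)zs[c] * ny + ys[b]) * nx + xs[a]) * jc];
            const double *ps = &SS[(((long)zs[c] * ny + ys[b]) * nx + xs[a]) * jc];
            for (int j = 0; j < jc; ++j) { RC[j] += sg * pc[j]; RS[j] += sg * ps[j]; }
          }
    };

    // energy/force pass
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          const long ic = ((long)iz * ny + iy) * nx + ix;
          const int a0 = cell_start[ic], a1 = cell_start[ic + 1];
          if (a0 == a1) continue;
          std::fill(RC.begin(), RC.end(), 0.0);
          std::fill(RS.begin(), RS.end(), 0.0);
          add_box(ix, iy, iz, smax, 1.0);
          add_box(ix, iy, iz, smin - 1, -1.0);
          for (int a = a0; a < a1; ++a) {
            const double x = px[a], y = py[a], z = pz[a], qa = q[a];
            double ea = 0.0, fx = 0.0, fy = 0.0, fz = 0.0;
            for (int j = 0; j < jc; ++j) {
              const long jj = j0 + j;
              const double ph = kx[jj] * x + ky[jj] * y + kz[jj] * z;
              double c, s;
              trig_eval(ph, single_trig, c, s);
              const double ca = qa * c, sa = qa * s;
              const double w = pw[jj];
              ea += w * (ca * RC[j] + sa * RS[j]);
              const double g = w * (sa * RC[j] - ca * RS[j]);
              fx += g * kx[jj];
              fy += g * ky[jj];
              fz += g * kz[jj];
            }
            E[a] += ea;
            F(a, 0) += fx;
            F(a, 1) += fy;
            F(a, 2) += fz;
          }
        }
  }
  return List::create(_["energy"] = E, _["force"] = F);
}

// Per-cell structure factors (reference path; full node set in memory).
// [[Rcpp::export]]
List cpp_cell_structure_factors(NumericMatrix pos, NumericVector q,
                                IntegerVector cell_start, NumericMatrix K) {
  const int J = K.nrow();
  const long ncells = cell_start.size() - 1;
  NumericMatrix C(ncells, J), S(ncells, J);
  for (long ic = 0; ic < ncells; ++ic) {
    for (int a = cell_start[ic]; a < cell_start[ic + 1]; ++a) {
      const double x = pos(a, 0), y = pos(a, 1), z = pos(a, 2), qa = q[a];
      for (int j = 0; j < J; ++j) {
        const double ph = K(j, 0) * x + K(j, 1) * y + K(j, 2) * z;
        C(ic, j) += qa * std::cos(ph);
        S(ic, j) += qa * std::sin(ph);
      }
    }
  }
  return List::create(_["C"] = C, _["S"] = S);
}

// Short-range stage: full Coulomb over in-cell pairs and the 26-neighbor
// cells, each unordered pair once. Per-atom energies are half-shares.
// [[Rcpp::export]]
List cpp_short_range(NumericMatrix pos, NumericVector q, IntegerVector ncell,
                     IntegerVector cell_start, double ke) {
  const int n = pos.nrow();
  const int nx = ncell[0], ny = ncell[1], nz = ncell[2];
  NumericVector E(n);
  NumericMatrix F(n, 3);
  double npairs = 0.0;
  int err_a = -1, err_b = -1;

  auto interact = [&](int a, int b) {
    const double dx = pos(a, 0) - pos(b, 0);
    const double dy = pos(a, 1) - pos(b, 1);
    const double dz = pos(a, 2) - pos(b, 2);
    const double r2 = dx * dx + dy * dy + dz * dz;
    npairs += 1.0;
    if (r2 < 1e-24) {
      if (q[a] * q[b] != 0.0 && err_a < 0) { err_a = a; err_b = b; }
      return;
    }
    const double r = std::sqrt(r2);
    const double e = ke * q[a] * q[b] / r;
    E[a] += 0.5 * e;
    E[b] += 0.5 * e;
    const double g = e / r2;
    F(a, 0) += g * dx; F(a, 1) += g * dy; F(a, 2) += g * dz;
    F(b, 0) -= g * dx; F(b, 1) -= g * dy; F(b, 2) -= g * dz;
  };

  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const long ic = ((long)iz * ny + iy) * nx + ix;
        const int a0 = cell_start[ic], a1 = cell_start[ic + 1];
        for (int a = a0; a < a1; ++a)
          for (int b = a + 1; b < a1; ++b) interact(a, b);
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int jx = ix + dx, jy = iy + dy, jz = iz + dz;
              if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
                continue;
              const long jcell = ((long)jz * ny + jy) * nx + jx;
              if (jcell <= ic) continue;  // each cell pair once
              for (int a = a0; a < a1; ++a)
                for (int b = cell_start[jcell]; b < cell_start[jcell + 1]; ++b)
                  interact(a, b);
            }
      }
  return List::create(_["energy"] = E, _["force"] = F, _["npairs"] = npairs,
                      _["err_a"] = err_a + 1, _["err_b"] = err_b + 1);
}

// O(N^2) all-pairs Coulomb reference.
// [[Rcpp::export]]
List cpp_direct_coulomb(NumericMatrix pos, NumericVector q, double ke) {
  const int n = pos.nrow();
  NumericVector E(n);
  NumericMatrix F(n, 3);
  int err_a = -1, err_b = -1;
  for (int a = 0; a < n; ++a) {
    const double xa = pos(a, 0), ya = pos(a, 1), za = pos(a, 2), qa = q[a];
    for (int b = a + 1; b < n; ++b) {
      const double dx = xa - pos(b, 0), dy = ya - pos(b, 1), dz = za - pos(b, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-24) {
        if (qa * q[b] != 0.0 && err_a < 0) { err_a = a; err_b = b; }
        continue;
      }
      const double r = std::sqrt(r2);
      const double e = ke * qa * q[b] / r;
      E[a] += 0.5 * e;
      E[b] += 0.5 * e;
      const double g = e / r2;
      F(a, 0) += g * dx; F(a, 1) += g * dy; F(a, 2) += g * dz;
      F(b, 0) -= g * dx; F(b, 1) -= g * dy; F(b, 2) -= g * dz;
    }
  }
  return List::create(_["energy"] = E, _["force"] = F,
                      _["err_a"] = err_a + 1, _["err_b"] = err_b + 1);
}

// Cubature kernel (and optionally its gradient) at probe points:
// value(p) = sum_j W_j cos(k_j . p), grad(p) = -sum_j W_j k_j sin(k_j . p).
// [[Rcpp::export]]
List cpp_kernel_probe(NumericMatrix K, NumericVector W, NumericMatrix P,
                      bool want_grad) {
  const long J = K.nrow();
  const int np = P.nrow();
  NumericVector val(np);
  NumericMatrix G(want_grad ? np : 1, 3);
  for (int p = 0; p < np; ++p) {
    const double x = P(p, 0), y = P(p, 1), z = P(p, 2);
    double v = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
    if (want_grad) {
      for (long j = 0; j < J; ++j) {
        const double ph = K(j, 0) * x + K(j, 1) * y + K(j, 2) * z;
        v += W[j] * std::cos(ph);
        const double ws = W[j] * std::sin(ph);
        gx -= ws * K(j, 0); gy -= ws * K(j, 1); gz -= ws * K(j, 2);
      }
      G(p, 0) = gx; G(p, 1) = gy; G(p, 2) = gz;
    } else {
      for (long j = 0; j < J; ++j) {
        const double ph = K(j, 0) * x + K(j, 1) * y + K(j, 2) * z;
        v += W[j] * std::cos(ph);
      }
    }
    val[p] = v;
  }
  return List::create(_["value"] = val, _["grad"] = G);
}

// Cubature kernel (and gradient) on a polar probe grid: directions x a
// uniform radius grid r_i = r0 + i*dr. For each (direction, node) pair the
// radial sweep uses the rotation recurrence
//   cos(z (r+dr)) = cos(z r) cos(z dr) - sin(z r) sin(z dr)
// so only two sin/cos calls are needed per pair regardless of the number of
// radii. Returns value (and gradient) with radius fastest, direction slowest.
// [[Rcpp::export]]
List cpp_kernel_probe_radial(NumericMatrix K, NumericVector W,
                             NumericMatrix dirs, double r0, double dr, int nr,
                             bool want_grad) {
  const long J = K.nrow();
  const int nd = dirs.nrow();
  NumericVector val((long)nd * nr);
  NumericMatrix G(want_grad ? (long)nd * nr : 1, 3);
  const double *Kx = &K(0, 0), *Ky = &K(0, 1), *Kz = &K(0, 2);
  const double *pw = &W[0];
  std::vector<double> vacc(nr), gx(nr), gy(nr), gz(nr);
  for (int d = 0; d < nd; ++d) {
    const double ux = dirs(d, 0), uy = dirs(d, 1), uz = dirs(d, 2);
    std::fill(vacc.begin(), vacc.end(), 0.0);
    if (want_grad) {
      std::fill(gx.begin(), gx.end(), 0.0);
      std::fill(gy.begin(), gy.end(), 0.0);
      std::fill(gz.begin(), gz.end(), 0.0);
    }
    for (long j = 0; j < J; ++j) {
      const double kx = Kx[j], ky = Ky[j], kz = Kz[j];
      const double z = kx * ux + ky * uy + kz * uz;
      double c, s, e, f;
      GLST_SINCOS(z * r0, &s, &c);
      GLST_SINCOS(z * dr, &f, &e);
      const double w = pw[j];
      if (want_grad) {
        const double wx = w * kx, wy = w * ky, wz = w * kz;
        for (int i = 0; i < nr; ++i) {
          vacc[i] += w * c;
          gx[i] -= wx * s; gy[i] -= wy * s; gz[i] -= wz * s;
          const double cn = c * e - s * f;
          s = s * e + c * f;
          c = cn;
        }
      } else {
        for (int i = 0; i < nr; ++i) {
          vacc[i] += w * c;
          const double cn = c * e - s * f;
          s = s * e + c * f;
          c = cn;
        }
      }
    }
    for (int i = 0; i < nr; ++i) {
      val[(long)d * nr + i] = vacc[i];
      if (want_grad) {
        G((long)d * nr + i, 0) = gx[i];
        G((long)d * nr + i, 1) = gy[i];
        G((long)d * nr + i, 2) = gz[i];
      }
    }
  }
  return List::create(_["value"] = val, _["grad"] = G);
}

// Seeded rejection-sampling placement of molecule anchor sites with a
// minimum inter-site separation, accelerated by a cell hash. Uses R's RNG
// so set.seed() governs reproducibility.
// [[Rcpp::export]]
NumericMatrix cpp_place_points(int n, NumericVector box, double margin,
                               double minsep, int max_attempts) {
  NumericMatrix out(n, 3);
  const double minsep2 = minsep * minsep;
  int gx = std::max(1, (int)std::floor(box[0] / minsep));
  int gy = std::max(1, (int)std::floor(box[1] / minsep));
  int gz = std::max(1, (int)std::floor(box[2] / minsep));
  const double ex = box[0] / gx, ey = box[1] / gy, ez = box[2] / gz;
  std::vector<int> head((long)gx * gy * gz, -1), nxt(n, -1);

  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int att = 0; att < max_attempts; ++att) {
      const double x = margin + R::runif(0.0, 1.0) * (box[0] - 2 * margin);
      const double y = margin + R::runif(0.0, 1.0) * (box[1] - 2 * margin);
      const double z = margin + R::runif(0.0, 1.0) * (box[2] - 2 * margin);
      const int cx = std::min(gx - 1, (int)(x / ex));
      const int cy = std::min(gy - 1, (int)(y / ey));
      const int cz = std::min(gz - 1, (int)(z / ez));
      bool ok = true;
      for (int dz = -1; dz <= 1 && ok; ++dz)
        for (int dy = -1; dy <= 1 && ok; ++dy)
          for (int dx = -1; dx <= 1 && ok; ++dx) {
            const int jx = cx + dx, jy = cy + dy, jz = cz + dz;
            if (jx < 0 || jx >= gx || jy < 0 || jy >= gy || jz < 0 || jz >= gz)
              continue;
            for (int k = head[((long)jz * gy + jy) * gx + jx]; k >= 0; k = nxt[k]) {
              const double ddx = x - out(k, 0), ddy = y - out(k, 1), ddz = z - out(k, 2);
              if (ddx * ddx + ddy * ddy + ddz * ddz < minsep2) { ok = false; break; }
            }
          }
      if (ok) {
        out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
        const long c = ((long)cz * gy + cy) * gx + cx;
        nxt[i] = head[c];
        head[c] = i;
        placed = true;
        break;
      }
    }
    if (!placed)
      stop("packing error: could not place site %d of %d at minimum separation %g; use a larger box",
           i + 1, n, minsep);
  }
  return out;
}

// Exact short-range pair count from per-cell occupancies (no coordinates).
// [[Rcpp::export]]
double cpp_short_pair_count(IntegerVector ncell, IntegerVector counts) {
  const int nx = ncell[0], ny = ncell[1], nz = ncell[2];
  double tot = 0.0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const long ic = ((long)iz * ny + iy) * nx + ix;
        const double nc = counts[ic];
        tot += nc * (nc - 1) / 2.0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int jx = ix + dx, jy = iy + dy, jz = iz + dz;
              if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
                continue;
              const long jcell = ((long)jz * ny + jy) * nx + jx;
              if (jcell > ic) tot += nc * (double)counts[jcell];
            }
      }
  return tot;
}
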