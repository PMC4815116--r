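#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// layer index of a z coordinate given internal boundaries zb (increasing)
static inline int layer_of(const double z, const double *zb, const int nb) {
  int j = 0;
  while (j < nb && z >= zb[j]) ++j;
  return j;
}

// Monochromatic point-source (Rayleigh) summation over transducer elements,
// with straight-ray per-layer phase speed and amplitude attenuation.
// Layers are z-slabs: internal boundaries `zb` (increasing), layer j covers
// [zb[j-1], zb[j]). `k` and `alpha` are per-layer wavenumber (rad/m) and
// amplitude attenuation (Np/m). The path fraction spent in each layer is the
// z-overlap fraction of the straight segment (refraction neglected).
// Returns an np x 4 complex matrix: column 0 the kernel sum
// area * exp(i*phase - attn) / r, columns 1-3 its exact gradient with
// respect to the field point, (i*k_loc - a_loc - 1/r) * kernel * rhat,
// where k_loc, a_loc are the local (point-layer) wavenumber/attenuation
// (gradient of the optical path is the local index times the ray
// direction). The -i*omega*rho*u0/(2*pi) prefactor is applied by the R
// caller. `fast_trig` evaluates the reduced-range trig in single precision
// (used for the cutout correction patch).
// [[Rcpp::export]]
ComplexMatrix rayleigh_sum_cpp(NumericVector ex, NumericVector ey,
                               NumericVector ez, NumericVector ea,
                               NumericVector px, NumericVector py,
                               NumericVector pz,
                               NumericVector k, NumericVector alpha,
                               NumericVector zb, bool fast_trig = false) {
  const int ne = ex.size(), np = px.size(), nl = k.size(), nb = zb.size();
  const double twopi = 2.0 * M_PI;
  ComplexMatrix out(np, 4);
  for (int ip = 0; ip < np; ++ip) {
    const double x = px[ip], y = py[ip], z = pz[ip];
    const int jloc = (nl == 1) ? 0 : layer_of(z, REAL(zb), nb);
    const double kloc = k[jloc], aloc = alpha[jloc];
    double re = 0.0, im = 0.0;
    double gre[3] = {0, 0, 0}, gim[3] = {0, 0, 0};
    for (int ie = 0; ie < ne; ++ie) {
      const double dx = x - ex[ie], dy = y - ey[ie], dz = z - ez[ie];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r <= 0.0) continue;
      double phase, attn;
      if (nl == 1) {
        phase = k[0] * r;
        attn = alpha[0] * r;
      } else {
        const double zlo = std::min(ez[ie], z), zhi = std::max(ez[ie], z);
        const double dztot = zhi - zlo;
        phase = 0.0; attn = 0.0;
        if (dztot <= 0.0) {
          phase = kloc * r;
          attn = aloc * r;
        } else {
          const double scale = r / dztot;
          for (int j = 0; j < nl; ++j) {
            const double lo = (j == 0) ? -1e300 : zb[j - 1];
            const double hi = (j == nl - 1) ? 1e300 : zb[j];
            const double ov = std::min(zhi, hi) - std::max(zlo, lo);
            if (ov > 0.0) {
              const double L = ov * scale;
              phase += k[j] * L;
              attn += alpha[j] * L;
            }
          }
        }
      }
      double kre, kim;
      if (fast_trig) {
        const float amp = expf((float)(-attn)) * (float)(ea[ie] / r);
        const float phr = (float)(phase - twopi * std::floor(phase / twopi));
        kre = amp * cosf(phr);
        kim = amp * sinf(phr);
      } else {
        const double amp = ea[ie] * std::exp(-attn) / r;
        kre = amp * std::cos(phase);
        kim = amp * std::sin(phase);
      }
      re += kre;
      im += kim;
      // (i*kloc - aloc - 1/r) * kernel
      const double fre = -aloc - 1.0 / r, fim = kloc;
      const double pre = fre * kre - fim * kim;
      const double pim = fre * kim + fim * kre;
      const double u[3] = {dx / r, dy / r, dz / r};
      for (int c = 0; c < 3; ++c) {
        gre[c] += pre * u[c];
        gim[c] += pim * u[c];
      }
    }
    out(ip, 0).r = re;
    out(ip, 0).i = im;
    for (int c = 0; c < 3; ++c) {
      out(ip, c + 1).r = gre[c];
      out(ip, c + 1).i = gim[c];
    }
  }
  return out;
}

// effective per-meter wavenumber and attenuation of the straight segment
// from z0 to z1 through the layer stack (z-overlap fractions)
static inline void layer_eff(const double z0, const double z1,
                             const double *k, const double *alpha,
                             const double *zb, const int nl,
                             double &keff, double &aeff) {
  if (nl == 1) { keff = k[0]; aeff = alpha[0]; return; }
  const double zlo = std::min(z0, z1), zhi = std::max(z0, z1);
  const double dztot = zhi - zlo;
  if (dztot <= 0.0) {
    int j = 0;
    while (j < nl - 1 && z1 >= zb[j]) ++j;
    keff = k[j]; aeff = alpha[j];
    return;
  }
  keff = 0.0; aeff = 0.0;
  for (int j = 0; j < nl; ++j) {
    const double lo = (j == 0) ? -1e300 : zb[j - 1];
    const double hi = (j == nl - 1) ? 1e300 : zb[j];
    const double ov = std::min(zhi, hi) - std::max(zlo, lo);
    if (ov > 0.0) {
      const double f = ov / dztot;
      keff += k[j] * f;
      aeff += alpha[j] * f;
    }
  }
}

// Rayleigh field of the axisymmetric (hole-free) spherical cap at points
// (r, z) in the meridian plane, by ring decomposition: the polar direction
// is discretized into n_rings rings and the azimuthal integral of
// exp(i k d - alpha d) / d over each ring is taken by midpoint quadrature
// with a node count adapted to the phase spread across the ring
// (the integrand is periodic, so the midpoint rule converges spectrally).
// The cap apex is at z = 0, the focus at z = R. Layered media as in
// rayleigh_sum_cpp. Returns an np x 3 complex matrix: kernel sum, and its
// exact gradient components along the cylindrical radial and z directions
// (same normalization as rayleigh_sum_cpp).
// [[Rcpp::export]]
ComplexMatrix rayleigh_ring_cpp(double R, double psi_max, int n_rings,
                                NumericVector pr, NumericVector pz,
                                NumericVector k, NumericVector alpha,
                                NumericVector zb,
                                double node_factor = 1.6, int node_base = 24) {
  const int np = pr.size(), nl = k.size(), nb = zb.size();
  const double dpsi = psi_max / n_rings;
  const double twopi = 2.0 * M_PI;
  std::vector<double> rho_e(n_rings), z_e(n_rings), area(n_rings);
  for (int i = 0; i < n_rings; ++i) {
    const double psi = (i + 0.5) * dpsi;
    rho_e[i] = R * std::sin(psi);
    z_e[i] = R * (1.0 - std::cos(psi));
    area[i] = twopi * R * R * std::sin(psi) * dpsi;
  }
  ComplexMatrix out(np, 3);
  for (int ip = 0; ip < np; ++ip) {
    const double r = pr[ip], z = pz[ip];
    const int jloc = (nl == 1) ? 0 : layer_of(z, REAL(zb), nb);
    const double kloc = k[jloc], aloc = alpha[jloc];
    double re = 0.0, im = 0.0, grre = 0.0, grim = 0.0, gzre = 0.0, gzim = 0.0;
    for (int i = 0; i < n_rings; ++i) {
      const double dz = z - z_e[i];
      double keff, aeff;
      layer_eff(z_e[i], z, REAL(k), REAL(alpha),
                nb ? REAL(zb) : nullptr, nl, keff, aeff);
      const double base = rho_e[i] * rho_e[i] + r * r + dz * dz;
      const double cross = 2.0 * rho_e[i] * r;
      const double dmin = std::sqrt(std::max(base - cross, 0.0));
      const double dmax = std::sqrt(base + cross);
      const int n = node_base + (int)std::ceil(node_factor * keff * (dmax - dmin));
      const double w = area[i] / n;
      double sre = 0.0, sim = 0.0;         // kernel
      double srr = 0.0, sri = 0.0;         // kernel * (r - rho_e cos phi)/d
      double szr = 0.0, szi = 0.0;         // kernel * dz/d
      for (int j = 0; j < n; ++j) {
        const double phi = (j + 0.5) * M_PI / n;
        const double cphi = std::cos(phi);
        const double d = std::sqrt(base - cross * cphi);
        const double ph = keff * d;
        const float phr = (float)(ph - twopi * std::floor(ph / twopi));
        const float am = expf((float)(-aeff * d)) / (float)d;
        const double kre = am * cosf(phr), kim = am * sinf(phr);
        sre += kre; sim += kim;
        // direction cosines of the ray at the field point
        const double ur = (r - rho_e[i] * cphi) / d;
        const double uz = dz / d;
        const double fre = -aloc - 1.0 / d, fim = kloc;
        const double pre = fre * kre - fim * kim;
        const double pim = fre * kim + fim * kre;
        srr += pre * ur; sri += pim * ur;
        szr += pre * uz; szi += pim * uz;
      }
      re += w * sre; im += w * sim;
      grre += w * srr; grim += w * sri;
      gzre += w * szr; gzim += w * szi;
    }
    out(ip, 0).r = re;   out(ip, 0).i = im;
    out(ip, 1).r = grre; out(ip, 1).i = grim;
    out(ip, 2).r = gzre; out(ip, 2).i = gzim;
  }
  return out;
}

// One explicit Euler step of the generalized Pennes equation.
// T, Tout, Q, D are nx*ny*nz vectors (x fastest). Medium properties vary per
// z plane. The boundary condition is Dirichlet at the body temperature Tb on
// all six faces. The temperature-dependent excess specific heat (denaturation
// + vaporization) is a lookup table `ct_bump` on temperatures
// ct_t0 + i*ct_dt, applied only in tissue planes. Perfusion shuts down
// linearly with accumulated dose, vanishing at `dose_destroy`.
// Writes the updated temperature into Tout (preallocated, modified in place).
// [[Rcpp::export]]
void bioheat_step_cpp(NumericVector T, NumericVector Tout, NumericVector Q,
                      NumericVector D,
                      int nx, int ny, int nz, double dx, double dt,
                      NumericVector kz, NumericVector rhoz,
                      NumericVector wb0z, NumericVector C0z,
                      LogicalVector tissuez,
                      NumericVector ct_bump, double ct_t0, double ct_dt,
                      double rho_b, double C_b, double T_b,
                      double dose_destroy) {
  const double inv_dx2 = 1.0 / (dx * dx);
  const int sx = 1, sy = nx, sz = nx * ny;
  const int nct = ct_bump.size();
  const double *Tp = REAL(T), *Qp = REAL(Q), *Dp = REAL(D);
  double *To = REAL(Tout);
  for (int kk = 0; kk < nz; ++kk) {
    const double kt = kz[kk], rho_t = rhoz[kk], wb0 = wb0z[kk], C0 = C0z[kk];
    const bool tis = tissuez[kk];
    for (int jj = 0; jj < ny; ++jj) {
      const int base = kk * sz + jj * sy;
      if (kk == 0 || kk == nz - 1 || jj == 0 || jj == ny - 1) {
        for (int ii = 0; ii < nx; ++ii) To[base + ii] = T_b;
        continue;
      }
      To[base] = T_b;
      To[base + nx - 1] = T_b;
      for (int ii = 1; ii < nx - 1; ++ii) {
        const int id = base + ii;
        const double Tc = Tp[id];
        const double lap = (Tp[id - sx] + Tp[id + sx] + Tp[id - sy] +
                            Tp[id + sy] + Tp[id - sz] + Tp[id + sz] -
                            6.0 * Tc) * inv_dx2;
        double Ct = C0;
        if (tis) {
          double u = (Tc - ct_t0) / ct_dt;
          if (u > 0.0 && u < nct - 1) {
            const int i0 = (int)u;
            const double w = u - i0;
            Ct += (1.0 - w) * ct_bump[i0] + w * ct_bump[i0 + 1];
          }
        }
        double perf = 0.0;
        if (wb0 > 0.0) {
          const double f = 1.0 - Dp[id] / dose_destroy;
          if (f > 0.0) perf = f * wb0 * rho_b * C_b * (T_b - Tc);
        }
        To[id] = Tc + dt * (kt * lap + perf + Qp[id]) / (rho_t * Ct);
      }
    }
  }
}

// CEM43 thermal dose increment D += dt * 0.5^(43 - T) (in place), cumulative
// boiling mask update (boiled |= T > T_boil, in place), and the field maximum
// temperature, in one pass.
// [[Rcpp::export]]
double dose_update_cpp(NumericVector D, NumericVector T, double dt,
                       double T_boil, LogicalVector boiled) {
  const int n = D.size();
  double *Dp = REAL(D);
  const double *Tp = REAL(T);
  int *bp = LOGICAL(boiled);
  double tmax = -std::numeric_limits<double>::infinity();
  const double ln2 = 0.6931471805599453;
  for (int i = 0; i < n; ++i) {
    const double t = Tp[i];
    Dp[i] += dt * std::exp(ln2 * (t - 43.0));
    if (t > T_boil) bp[i] = 1;
    if (t > tmax) tmax = t;
  }
  return tmax;
}

// Minimum Euclidean distance (in voxel units) to a seed set, limited to a
// ball of radius `radius` voxels: the workhorse behind the morphological
// dilation of the bubble cloud and the inverse-distance weight W1.
// `seed` holds 0-based linear indices into an nx*ny*nz array. Returns a
// vector with the distance where it is <= radius and +Inf elsewhere; seeds
// themselves get 0.
// [[Rcpp::export]]
NumericVector dilate_distance_cpp(IntegerVector seed, int nx, int ny, int nz,
                                  double radius) {
  const int n = nx * ny * nz;
  NumericVector dist(n, R_PosInf);
  const int r = (int)std::floor(radius);
  std::vector<int> di, dj, dk;
  std::vector<double> dd;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      for (int c = -r; c <= r; ++c) {
        const double d = std::sqrt((double)(a * a + b * b + c * c));
        if (d <= radius) {
          di.push_back(a); dj.push_back(b); dk.push_back(c); dd.push_back(d);
        }
      }
  const int no = di.size();
  double *dp = REAL(dist);
  for (int s = 0; s < seed.size(); ++s) {
    const int id = seed[s];
    const int i = id % nx, j = (id / nx) % ny, kk = id / (nx * ny);
    for (int o = 0; o < no; ++o) {
      const int ii = i + di[o], jj = j + dj[o], ko = kk + dk[o];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || ko < 0 || ko >= nz)
        continue;
      const int t = ii + nx * (jj + ny * ko);
      if (dd[o] < dp[t]) dp[t] = dd[o];
    }
  }
  return dist;
}

// Largest 6-connected component of a voxel mask. `idx` holds 0-based linear
// indices of the true voxels; returns the 0-based indices of the largest
// component (BFS flood fill).
// [[Rcpp::export]]
IntegerVector largest_component_cpp(IntegerVector idx, int nx, int ny, int nz) {
  if (idx.size() == 0) return IntegerVector(0);
  std::vector<char> in(static_cast<size_t>(nx) * ny * nz, 0);
  for (int s = 0; s < idx.size(); ++s) in[idx[s]] = 1;
  std::vector<int> best, cur, stack;
  for (int s = 0; s < idx.size(); ++s) {
    const int start = idx[s];
    if (in[start] != 1) continue;
    cur.clear();
    stack.clear();
    stack.push_back(start);
    in[start] = 2;
    while (!stack.empty()) {
      const int id = stack.back();
      stack.pop_back();
      cur.push_back(id);
      const int i = id % nx, j = (id / nx) % ny, kk = id / (nx * ny);
      const int nb[6][3] = {{i - 1, j, kk}, {i + 1, j, kk}, {i, j - 1, kk},
                            {i, j + 1, kk}, {i, j, kk - 1}, {i, j, kk + 1}};
      for (int q = 0; q < 6; ++q) {
        const int ii = nb[q][0], jj = nb[q][1], ko = nb[q][2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || ko < 0 || ko >= nz)
          continue;
        const int t = ii + nx * (jj + ny * ko);
        if (in[t] == 1) { in[t] = 2; stack.push_back(t); }
      }
    }
    if (cur.size() > best.size()) best = cur;
  }
  return IntegerVector(best.begin(), best.end());
}
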