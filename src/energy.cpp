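#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Coulomb constant e^2/(4 pi eps0) in kJ/mol * Angstrom / e^2
static const double KCOUL = 1389.35458;

// Lennard-Jones 12-6 with per-pair cap on the repulsive blow-up.
static inline double lj_pair(double r2, double sig, double eps, double cap) {
  if (r2 < 1e-6) return cap;  // grid point on top of an atom
  double s2 = (sig * sig) / r2;
  double s6 = s2 * s2 * s2;
  double e = 4.0 * eps * (s6 * s6 - s6);
  return (e > cap) ? cap : e;
}

// Distance-dependent dielectric eps(r) = 4r gives E = k q1 q2 / (4 r^2).
// r is floored at rmin so grid points buried inside atoms stay finite.
static inline double coul_pair(double r2, double qq, double rmin) {
  double r2eff = (r2 < rmin * rmin) ? rmin * rmin : r2;
  return KCOUL * qq / (4.0 * r2eff);
}

// [[Rcpp::export]]
double cpp_pose_energy(NumericMatrix probe_xyz, NumericVector psig,
                       NumericVector peps, NumericVector pq,
                       NumericMatrix rec_xyz, NumericVector rsig,
                       NumericVector reps, NumericVector rq,
                       double cutoff, double cap, double rmin) {
  const int np = probe_xyz.nrow(), nr = rec_xyz.nrow();
  const double c2 = cutoff * cutoff;
  double e = 0.0;
  for (int i = 0; i < np; ++i) {
    const double xi = probe_xyz(i, 0), yi = probe_xyz(i, 1), zi = probe_xyz(i, 2);
    for (int j = 0; j < nr; ++j) {
      const double dx = xi - rec_xyz(j, 0), dy = yi - rec_xyz(j, 1),
                   dz = zi - rec_xyz(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > c2) continue;
      e += lj_pair(r2, 0.5 * (psig[i] + rsig[j]), std::sqrt(peps[i] * reps[j]), cap);
      const double qq = pq[i] * rq[j];
      if (qq != 0.0) e += coul_pair(r2, qq, rmin);
    }
  }
  return e;
}

// Build per-class LJ channels plus a unit-charge electrostatic channel.
// Grid linear index = ix + nx*(iy + ny*iz), 0-based.
// [[Rcpp::export]]
List cpp_build_grids(NumericMatrix rec_xyz, NumericVector rsig,
                     NumericVector reps, NumericVector rq,
                     NumericVector origin, double spacing, IntegerVector dims,
                     NumericVector csig, NumericVector ceps,
                     double cutoff, double cap, double rmin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nchan = csig.size();
  const R_xlen_t npts = (R_xlen_t)nx * ny * nz;
  List out(nchan + 1);
  std::vector<double*> ch(nchan);
  for (int c = 0; c < nchan; ++c) {
    NumericVector v(npts);
    out[c] = v;
    ch[c] = REAL(v);
  }
  NumericVector elec(npts);
  out[nchan] = elec;
  double* el = REAL(elec);

  const int nr = rec_xyz.nrow();
  const double c2 = cutoff * cutoff;
  for (int j = 0; j < nr; ++j) {
    const double ax = rec_xyz(j, 0), ay = rec_xyz(j, 1), az = rec_xyz(j, 2);
    const int ix0 = std::max(0, (int)std::ceil((ax - cutoff - origin[0]) / spacing));
    const int ix1 = std::min(nx - 1, (int)std::floor((ax + cutoff - origin[0]) / spacing));
    const int iy0 = std::max(0, (int)std::ceil((ay - cutoff - origin[1]) / spacing));
    const int iy1 = std::min(ny - 1, (int)std::floor((ay + cutoff - origin[1]) / spacing));
    const int iz0 = std::max(0, (int)std::ceil((az - cutoff - origin[2]) / spacing));
    const int iz1 = std::min(nz - 1, (int)std::floor((az + cutoff - origin[2]) / spacing));
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * spacing - az;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > c2) continue;
        const R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + ix * spacing - ax;
          const double r2 = dx * dx + dyz2;
          if (r2 > c2) continue;
          const R_xlen_t idx = base + ix;
          for (int c = 0; c < nchan; ++c)
            ch[c][idx] += lj_pair(r2, 0.5 * (csig[c] + rsig[j]),
                                  std::sqrt(ceps[c] * reps[j]), cap);
          if (rq[j] != 0.0) el[idx] += coul_pair(r2, rq[j], rmin);
        }
      }
    }
  }
  return out;
}

static inline double trilinear(const double* g, int nx, int ny, int nz,
                               const double* origin, double spacing,
                               double x, double y, double z) {
  const double gx = (x - origin[0]) / spacing;
  const double gy = (y - origin[1]) / spacing;
  const double gz = (z - origin[2]) / spacing;
  const int ix = (int)std::floor(gx), iy = (int)std::floor(gy),
            iz = (int)std::floor(gz);
  if (ix < 0 || iy < 0 || iz < 0 || ix >= nx - 1 || iy >= ny - 1 || iz >= nz - 1)
    return 0.0;  // outside the box: beyond cutoff from every atom by construction
  const double fx = gx - ix, fy = gy - iy, fz = gz - iz;
  const R_xlen_t i000 = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
  const R_xlen_t dyo = nx, dzo = (R_xlen_t)nx * ny;
  const double c00 = g[i000] * (1 - fx) + g[i000 + 1] * fx;
  const double c10 = g[i000 + dyo] * (1 - fx) + g[i000 + dyo + 1] * fx;
  const double c01 = g[i000 + dzo] * (1 - fx) + g[i000 + dzo + 1] * fx;
  const double c11 = g[i000 + dyo + dzo] * (1 - fx) + g[i000 + dyo + dzo + 1] * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_interp(NumericVector grid, IntegerVector dims,
                         NumericVector origin, double spacing,
                         NumericMatrix pts) {
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = trilinear(REAL(grid), dims[0], dims[1], dims[2], REAL(origin),
                       spacing, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

struct Cand {
  double e;
  int rot;
  R_xlen_t idx;
};
struct CandWorse {
  // max-heap: "worst" candidate on top; ties resolved so that the later
  // (rot, idx) counts as worse, keeping the earliest candidate on ties
  bool operator()(const Cand& a, const Cand& b) const {
    if (a.e != b.e) return a.e < b.e;
    if (a.rot != b.rot) return a.rot < b.rot;
    return a.idx < b.idx;
  }
};

// Exhaustive rotation x translation scan of the energy grids.
// rot: 9 x nrot column-major rotation matrices. chan: list of LJ channels in
// the order referenced by chanidx (0-based per probe atom), last element of
// `grids` is the electrostatic channel.
// [[Rcpp::export]]
NumericMatrix cpp_sample_poses(List grids, IntegerVector dims,
                               NumericVector origin, double spacing,
                               NumericMatrix body, IntegerVector chanidx,
                               NumericVector q, NumericMatrix rot,
                               int retain) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int natom = body.nrow();
  const int nrot = rot.ncol();
  const int nchan = grids.size() - 1;
  std::vector<const double*> g(nchan + 1);
  for (int c = 0; c <= nchan; ++c) g[c] = REAL((SEXP)grids[c]);
  const double* org = REAL(origin);

  std::priority_queue<Cand, std::vector<Cand>, CandWorse> heap;
  std::vector<double> ox(natom), oy(natom), oz(natom);
  // per-atom precomputed corner weights / linear offsets for the fast path:
  // translations sit exactly on grid points, so the trilinear weights of an
  // atom depend only on the rotation, not on the translation
  std::vector<double> w(natom * 8);
  std::vector<R_xlen_t> coff(natom * 8);
  const R_xlen_t dyo = nx, dzo = (R_xlen_t)nx * ny;
  const R_xlen_t corner[8] = {0, 1, dyo, dyo + 1, dzo, dzo + 1,
                              dzo + dyo, dzo + dyo + 1};

  for (int r = 0; r < nrot; ++r) {
    const double* R = &rot(0, r);
    int lox = 0, hix = nx - 1, loy = 0, hiy = ny - 1, loz = 0, hiz = nz - 1;
    for (int a = 0; a < natom; ++a) {
      const double bx = body(a, 0), by = body(a, 1), bz = body(a, 2);
      ox[a] = R[0] * bx + R[3] * by + R[6] * bz;
      oy[a] = R[1] * bx + R[4] * by + R[7] * bz;
      oz[a] = R[2] * bx + R[5] * by + R[8] * bz;
      const double gx = ox[a] / spacing, gy = oy[a] / spacing,
                   gz = oz[a] / spacing;
      const int bxi = (int)std::floor(gx), byi = (int)std::floor(gy),
                bzi = (int)std::floor(gz);
      const double fx = gx - bxi, fy = gy - byi, fz = gz - bzi;
      const double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy},
                   wz[2] = {1 - fz, fz};
      for (int c = 0; c < 8; ++c) {
        w[a * 8 + c] = wx[c & 1] * wy[(c >> 1) & 1] * wz[(c >> 2) & 1];
        coff[a * 8 + c] = bxi + dyo * byi + dzo * bzi + corner[c];
      }
      // translation range where all 8 corners of this atom stay in bounds
      lox = std::max(lox, -bxi);
      hix = std::min(hix, nx - 2 - bxi);
      loy = std::max(loy, -byi);
      hiy = std::min(hiy, ny - 2 - byi);
      loz = std::max(loz, -bzi);
      hiz = std::min(hiz, nz - 2 - bzi);
    }
    R_xlen_t idx = 0;
    for (int iz = 0; iz < nz; ++iz) {
      const double pz = org[2] + iz * spacing;
      const bool zin = iz >= loz && iz <= hiz;
      for (int iy = 0; iy < ny; ++iy) {
        const double py = org[1] + iy * spacing;
        const bool yzin = zin && iy >= loy && iy <= hiy;
        for (int ix = 0; ix < nx; ++ix, ++idx) {
          double e = 0.0;
          if (yzin && ix >= lox && ix <= hix) {
            for (int a = 0; a < natom; ++a) {
              const double* gc = g[chanidx[a]];
              const double* wa = &w[a * 8];
              const R_xlen_t* ca = &coff[a * 8];
              double ea = wa[0] * gc[idx + ca[0]] + wa[1] * gc[idx + ca[1]] +
                          wa[2] * gc[idx + ca[2]] + wa[3] * gc[idx + ca[3]] +
                          wa[4] * gc[idx + ca[4]] + wa[5] * gc[idx + ca[5]] +
                          wa[6] * gc[idx + ca[6]] + wa[7] * gc[idx + ca[7]];
              if (q[a] != 0.0) {
                const double* ge = g[nchan];
                ea += q[a] * (wa[0] * ge[idx + ca[0]] + wa[1] * ge[idx + ca[1]] +
                              wa[2] * ge[idx + ca[2]] + wa[3] * ge[idx + ca[3]] +
                              wa[4] * ge[idx + ca[4]] + wa[5] * ge[idx + ca[5]] +
                              wa[6] * ge[idx + ca[6]] + wa[7] * ge[idx + ca[7]]);
              }
              e += ea;
            }
          } else {
            const double px = org[0] + ix * spacing;
            for (int a = 0; a < natom; ++a) {
              const double x = px + ox[a], y = py + oy[a], z = pz + oz[a];
              e += trilinear(g[chanidx[a]], nx, ny, nz, org, spacing, x, y, z);
              if (q[a] != 0.0)
                e += q[a] *
                     trilinear(g[nchan], nx, ny, nz, org, spacing, x, y, z);
            }
          }
          if ((int)heap.size() < retain) {
            heap.push({e, r, idx});
          } else if (e < heap.top().e) {
            heap.pop();
            heap.push({e, r, idx});
          }
        }
      }
    }
  }
  const int nkeep = (int)heap.size();
  NumericMatrix out(nkeep, 3);
  for (int i = nkeep - 1; i >= 0; --i) {
    const Cand c = heap.top();
    heap.pop();
    out(i, 0) = c.rot + 1;        // 1-based rotation index
    out(i, 1) = (double)c.idx + 1;  // 1-based grid index
    out(i, 2) = c.e;
  }
  return out;
}

static void rodrigues(const double* w, double theta, double* R) {
  // rotation matrix for angle theta about unit axis w, column-major
  const double c = std::cos(theta), s = std::sin(theta), t = 1.0 - c;
  R[0] = c + w[0] * w[0] * t;
  R[1] = w[1] * w[0] * t + w[2] * s;
  R[2] = w[2] * w[0] * t - w[1] * s;
  R[3] = w[0] * w[1] * t - w[2] * s;
  R[4] = c + w[1] * w[1] * t;
  R[5] = w[2] * w[1] * t + w[0] * s;
  R[6] = w[0] * w[2] * t + w[1] * s;
  R[7] = w[1] * w[2] * t - w[0] * s;
  R[8] = w[2] * w[2] * t + w[0] * s;
}

static void matmul3(const double* A, const double* B, double* C) {
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i)
      C[i + 3 * j] = A[i] * B[3 * j] + A[i + 3] * B[1 + 3 * j] + A[i + 6] * B[2 + 3 * j];
}

// Energy and its gradient (net force on the probe, net torque about the probe
// centroid). Capped LJ pairs and distance-floored Coulomb pairs contribute
// zero gradient, matching the flat regions of the capped energy surface.
static double energy_force_torque(const double* R, const double* t,
                                  const NumericMatrix& body,
                                  const NumericVector& psig,
                                  const NumericVector& peps,
                                  const NumericVector& pq,
                                  const NumericMatrix& rec,
                                  const NumericVector& rsig,
                                  const NumericVector& reps,
                                  const NumericVector& rq, double cutoff,
                                  double cap, double rmin, double* F,
                                  double* T) {
  const int np = body.nrow(), nr = rec.nrow();
  const double c2 = cutoff * cutoff;
  double e = 0.0;
  F[0] = F[1] = F[2] = T[0] = T[1] = T[2] = 0.0;
  for (int i = 0; i < np; ++i) {
    const double bx = body(i, 0), by = body(i, 1), bz = body(i, 2);
    const double ax = R[0] * bx + R[3] * by + R[6] * bz + t[0];
    const double ay = R[1] * bx + R[4] * by + R[7] * bz + t[1];
    const double az = R[2] * bx + R[5] * by + R[8] * bz + t[2];
    double fx = 0.0, fy = 0.0, fz = 0.0;
    for (int j = 0; j < nr; ++j) {
      const double dx = ax - rec(j, 0), dy = ay - rec(j, 1), dz = az - rec(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > c2) continue;
      const double sig = 0.5 * (psig[i] + rsig[j]);
      const double eps = std::sqrt(peps[i] * reps[j]);
      const double s2 = sig * sig / r2, s6 = s2 * s2 * s2;
      const double elj = 4.0 * eps * (s6 * s6 - s6);
      if (elj > cap) {
        e += cap;  // flat capped region, no LJ force
      } else {
        e += elj;
        // dE/dr2 = 4 eps (-6 s12 + 3 s6)/r2 ; F = -2 * dE/dr2 * dvec
        const double dEdr2 = 4.0 * eps * (-6.0 * s6 * s6 + 3.0 * s6) / r2;
        fx += -2.0 * dEdr2 * dx;
        fy += -2.0 * dEdr2 * dy;
        fz += -2.0 * dEdr2 * dz;
      }
      const double qq = pq[i] * rq[j];
      if (qq != 0.0) {
        if (r2 < rmin * rmin) {
          e += KCOUL * qq / (4.0 * rmin * rmin);
        } else {
          e += KCOUL * qq / (4.0 * r2);
          const double dEdr2 = -KCOUL * qq / (4.0 * r2 * r2);
          fx += -2.0 * dEdr2 * dx;
          fy += -2.0 * dEdr2 * dy;
          fz += -2.0 * dEdr2 * dz;
        }
      }
    }
    F[0] += fx;
    F[1] += fy;
    F[2] += fz;
    // torque about the centroid (= t, body centroid at origin)
    const double rx = ax - t[0], ry = ay - t[1], rz = az - t[2];
    T[0] += ry * fz - rz * fy;
    T[1] += rz * fx - rx * fz;
    T[2] += rx * fy - ry * fx;
  }
  return e;
}

// Rigid-body steepest descent with backtracking line search; monotone
// descent, so the returned energy never exceeds the input energy.
// R0: nposes x 9 (column-major rotation per row), t0: nposes x 3.
// Returns nposes x 14: R (9), t (3), energy, converged flag.
// [[Rcpp::export]]
NumericMatrix cpp_minimize_poses(NumericMatrix body, NumericVector psig,
                                 NumericVector peps, NumericVector pq,
                                 NumericMatrix rec, NumericVector rsig,
                                 NumericVector reps, NumericVector rq,
                                 NumericMatrix R0, NumericMatrix t0,
                                 double cutoff, double cap, double rmin,
                                 int maxit, double tol) {
  const int nposes = R0.nrow();
  const int np = body.nrow();
  double rmax = 0.0;
  for (int i = 0; i < np; ++i) {
    double r = std::sqrt(body(i, 0) * body(i, 0) + body(i, 1) * body(i, 1) +
                         body(i, 2) * body(i, 2));
    if (r > rmax) rmax = r;
  }
  NumericMatrix out(nposes, 14);
  double R[9], t[3], F[3], T[3], Rnew[9], tnew[3], step[9], Fn[3], Tn[3];
  for (int p = 0; p < nposes; ++p) {
    for (int k = 0; k < 9; ++k) R[k] = R0(p, k);
    for (int k = 0; k < 3; ++k) t[k] = t0(p, k);
    double e = energy_force_torque(R, t, body, psig, peps, pq, rec, rsig, reps,
                                   rq, cutoff, cap, rmin, F, T);
    int converged = 0;
    for (int it = 0; it < maxit; ++it) {
      const double fn = std::sqrt(F[0] * F[0] + F[1] * F[1] + F[2] * F[2]);
      const double tn = std::sqrt(T[0] * T[0] + T[1] * T[1] + T[2] * T[2]);
      if (fn < tol && tn < tol) {
        converged = 1;
        break;
      }
      // initial step scaled so the largest atom displacement is ~0.2 A
      double lambda = 0.2 / (fn + tn * rmax + 1e-12);
      bool improved = false;
      for (int bt = 0; bt < 25; ++bt) {
        for (int k = 0; k < 3; ++k) tnew[k] = t[k] + lambda * F[k];
        if (tn * lambda > 1e-14 && tn > 1e-12 && np > 1) {
          const double w[3] = {T[0] / tn, T[1] / tn, T[2] / tn};
          rodrigues(w, lambda * tn, step);
          matmul3(step, R, Rnew);
        } else {
          for (int k = 0; k < 9; ++k) Rnew[k] = R[k];
        }
        const double enew =
            energy_force_torque(Rnew, tnew, body, psig, peps, pq, rec, rsig,
                                reps, rq, cutoff, cap, rmin, Fn, Tn);
        if (enew < e - 1e-10) {
          e = enew;
          for (int k = 0; k < 9; ++k) R[k] = Rnew[k];
          for (int k = 0; k < 3; ++k) t[k] = tnew[k];
          for (int k = 0; k < 3; ++k) {
            F[k] = Fn[k];
            T[k] = Tn[k];
          }
          improved = true;
          break;
        }
        lambda *= 0.5;
      }
      if (!improved) {
        converged = 1;  // no downhill move at tiny step: local minimum
        break;
      }
    }
    for (int k = 0; k < 9; ++k) out(p, k) = R[k];
    for (int k = 0; k < 3; ++k) out(p, 9 + k) = t[k];
    out(p, 12) = e;
    out(p, 13) = converged;
  }
  return out;
}

// Heavy-atom pair contact counting: counts per residue the number of
// (probe atom, residue atom) pairs with distance <= radius (inclusive).
// rec_res: 1-based residue index per receptor atom; nres: number of residues.
// [[Rcpp::export]]
IntegerVector cpp_count_contacts(NumericMatrix rec_xyz, IntegerVector rec_res,
                                 int nres, NumericMatrix probe_xyz,
                                 double radius) {
  const int nr = rec_xyz.nrow(), np = probe_xyz.nrow();
  const double r2max = radius * radius;
  IntegerVector counts(nres);
  for (int j = 0; j < nr; ++j) {
    const double x = rec_xyz(j, 0), y = rec_xyz(j, 1), z = rec_xyz(j, 2);
    const int res = rec_res[j] - 1;
    int c = 0;
    for (int i = 0; i < np; ++i) {
      const double dx = x - probe_xyz(i, 0), dy = y - probe_xyz(i, 1),
                   dz = z - probe_xyz(i, 2);
      if (dx * dx + dy * dy + dz * dz <= r2max) ++c;
    }
    counts[res] += c;
  }
  return counts;
}
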