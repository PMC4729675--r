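// Compiled kernels for coarse-grained rigid-body docking:
// 8-6 pair potential + Coulomb, receptor grids with trilinear
// interpolation, an adaptive-step rigid-body minimizer, and O(n^2)
// RMSD scans for pose dedup and leader clustering.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double COULOMB = 332.0636;  // kcal/mol * A / e^2

// 8-6 pair energy and d(E)/d(r2) for one pair.
// attractive: eps*((R/r)^8 - (R/r)^6); repulsive: eps*((R/r)^8 + (R/r)^6)
static inline void pair86(double eps, double rb, bool attr, double r2,
                          double &e, double &dedr2) {
  if (r2 < 1e-2) r2 = 1e-2;  // guard against singularity at overlap
  double x2 = rb * rb / r2;
  double x6 = x2 * x2 * x2;
  double x8 = x6 * x2;
  if (attr) {
    e = eps * (x8 - x6);
    dedr2 = eps * (3.0 * x6 - 4.0 * x8) / r2;
  } else {
    e = eps * (x8 + x6);
    dedr2 = -eps * (4.0 * x8 + 3.0 * x6) / r2;
  }
}

static inline void pair_elec(double qq, double r2, bool dd, double scale,
                             double &e, double &dedr2) {
  if (r2 < 1e-2) r2 = 1e-2;
  if (dd) {            // distance-dependent dielectric eps(r) = r
    e = scale * COULOMB * qq / r2;
    dedr2 = -e / r2;
  } else {             // constant dielectric 1
    double r = std::sqrt(r2);
    e = scale * COULOMB * qq / r;
    dedr2 = -0.5 * e / r2;
  }
}

// Direct pairwise energy between fragment and receptor beads.
// Types are 0-based compact indices into EPS/RB/ATTR.
// [[Rcpp::export]]
double pair_energy_cpp(NumericMatrix fpos, IntegerVector ftyp, NumericVector fq,
                       NumericMatrix rpos, IntegerVector rtyp, NumericVector rq,
                       NumericMatrix EPS, NumericMatrix RB, LogicalMatrix ATTR,
                       double cutoff2, bool use_cutoff, bool dd_dielectric,
                       double coulomb_scale) {
  int nf = fpos.nrow(), nr = rpos.nrow();
  double total = 0.0;
  for (int i = 0; i < nf; ++i) {
    double xi = fpos(i, 0), yi = fpos(i, 1), zi = fpos(i, 2);
    int ti = ftyp[i];
    double qi = fq[i];
    for (int j = 0; j < nr; ++j) {
      double dx = xi - rpos(j, 0), dy = yi - rpos(j, 1), dz = zi - rpos(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (use_cutoff && r2 > cutoff2) continue;
      double e, g;
      pair86(EPS(ti, rtyp[j]), RB(ti, rtyp[j]), ATTR(ti, rtyp[j]), r2, e, g);
      total += e;
      if (qi != 0.0 && rq[j] != 0.0) {
        pair_elec(qi * rq[j], r2, dd_dielectric, coulomb_scale, e, g);
        total += e;
      }
    }
  }
  return total;
}

// Direct energy + gradient w.r.t. fragment bead coordinates.
// [[Rcpp::export]]
List pair_energy_gradient_cpp(NumericMatrix fpos, IntegerVector ftyp,
                              NumericVector fq, NumericMatrix rpos,
                              IntegerVector rtyp, NumericVector rq,
                              NumericMatrix EPS, NumericMatrix RB,
                              LogicalMatrix ATTR, double cutoff2,
                              bool use_cutoff, bool dd_dielectric,
                              double coulomb_scale) {
  int nf = fpos.nrow(), nr = rpos.nrow();
  NumericMatrix grad(nf, 3);
  double total = 0.0;
  for (int i = 0; i < nf; ++i) {
    double xi = fpos(i, 0), yi = fpos(i, 1), zi = fpos(i, 2);
    int ti = ftyp[i];
    double qi = fq[i];
    double gx = 0, gy = 0, gz = 0;
    for (int j = 0; j < nr; ++j) {
      double dx = xi - rpos(j, 0), dy = yi - rpos(j, 1), dz = zi - rpos(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (use_cutoff && r2 > cutoff2) continue;
      double e, dedr2;
      pair86(EPS(ti, rtyp[j]), RB(ti, rtyp[j]), ATTR(ti, rtyp[j]), r2, e, dedr2);
      total += e;
      double f = 2.0 * dedr2;
      if (qi != 0.0 && rq[j] != 0.0) {
        double ee, gg;
        pair_elec(qi * rq[j], r2, dd_dielectric, coulomb_scale, ee, gg);
        total += ee;
        f += 2.0 * gg;
      }
      gx += f * dx; gy += f * dy; gz += f * dz;
    }
    grad(i, 0) = gx; grad(i, 1) = gy; grad(i, 2) = gz;
  }
  return List::create(_["energy"] = total, _["gradient"] = grad);
}

// Precompute receptor grids: for each probe type slot one potential grid
// and its analytic gradient, plus a final slot with the per-unit-charge
// electrostatic potential. Layout: idx = i + nx*(j + ny*(k + nz*slot)).
// [[Rcpp::export]]
List build_grid_cpp(NumericMatrix rpos, IntegerVector rtyp, NumericVector rq,
                    IntegerVector probe_types, NumericMatrix EPS,
                    NumericMatrix RB, LogicalMatrix ATTR,
                    NumericVector origin, double spacing,
                    IntegerVector dims, bool dd_dielectric,
                    double coulomb_scale) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int P = probe_types.size();
  int nslot = P + 1;
  R_xlen_t npts = (R_xlen_t)nx * ny * nz;
  NumericVector V(npts * nslot), Gx(npts * nslot), Gy(npts * nslot),
      Gz(npts * nslot);
  int nr = rpos.nrow();
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * spacing;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * spacing;
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + i * spacing;
        R_xlen_t base = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int b = 0; b < nr; ++b) {
          double dx = x - rpos(b, 0), dy = y - rpos(b, 1), dz = z - rpos(b, 2);
          double r2 = dx * dx + dy * dy + dz * dz;
          int tb = rtyp[b];
          for (int p = 0; p < P; ++p) {
            int tp = probe_types[p];
            double e, dedr2;
            pair86(EPS(tp, tb), RB(tp, tb), ATTR(tp, tb), r2, e, dedr2);
            R_xlen_t idx = base + npts * p;
            V[idx] += e;
            double f = 2.0 * dedr2;
            Gx[idx] += f * dx; Gy[idx] += f * dy; Gz[idx] += f * dz;
          }
          if (rq[b] != 0.0) {
            double e, dedr2;
            pair_elec(rq[b], r2, dd_dielectric, coulomb_scale, e, dedr2);
            R_xlen_t idx = base + npts * P;
            V[idx] += e;
            double f = 2.0 * dedr2;
            Gx[idx] += f * dx; Gy[idx] += f * dy; Gz[idx] += f * dz;
          }
        }
      }
    }
  }
  return List::create(_["V"] = V, _["Gx"] = Gx, _["Gy"] = Gy, _["Gz"] = Gz);
}

struct GridView {
  const double *V, *Gx, *Gy, *Gz;
  double ox, oy, oz, h;
  int nx, ny, nz;
  R_xlen_t npts;
};

// Trilinear interpolation of potential and gradient for one bead in one
// slot. Returns false when the point is outside the grid (treated as zero
// potential; the COM restraint steers far poses).
static bool interp(const GridView &g, int slot, double x, double y, double z,
                   double &v, double &gx, double &gy, double &gz) {
  double fx = (x - g.ox) / g.h, fy = (y - g.oy) / g.h, fz = (z - g.oz) / g.h;
  int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
  if (i < 0 || j < 0 || k < 0 || i >= g.nx - 1 || j >= g.ny - 1 ||
      k >= g.nz - 1) {
    v = gx = gy = gz = 0.0;
    return false;
  }
  double tx = fx - i, ty = fy - j, tz = fz - k;
  R_xlen_t off = g.npts * slot;
  double vv = 0, ggx = 0, ggy = 0, ggz = 0;
  for (int dk = 0; dk < 2; ++dk) {
    double wz = dk ? tz : 1 - tz;
    for (int dj = 0; dj < 2; ++dj) {
      double wy = dj ? ty : 1 - ty;
      for (int di = 0; di < 2; ++di) {
        double w = (di ? tx : 1 - tx) * wy * wz;
        R_xlen_t idx = off + (i + di) +
            (R_xlen_t)g.nx * ((j + dj) + (R_xlen_t)g.ny * (k + dk));
        vv += w * g.V[idx];
        ggx += w * g.Gx[idx]; ggy += w * g.Gy[idx]; ggz += w * g.Gz[idx];
      }
    }
  }
  v = vv; gx = ggx; gy = ggy; gz = ggz;
  return true;
}

// [[Rcpp::export]]
List grid_energy_cpp(NumericMatrix fpos, IntegerVector fslot, NumericVector fq,
                     List grid, NumericVector origin, double spacing,
                     IntegerVector dims, int nprobe) {
  NumericVector V = grid["V"], Gx = grid["Gx"], Gy = grid["Gy"],
      Gz = grid["Gz"];
  GridView g{REAL(V), REAL(Gx), REAL(Gy), REAL(Gz),
             origin[0], origin[1], origin[2], spacing,
             dims[0], dims[1], dims[2],
             (R_xlen_t)dims[0] * dims[1] * dims[2]};
  int nf = fpos.nrow();
  NumericMatrix grad(nf, 3);
  double total = 0.0;
  for (int b = 0; b < nf; ++b) {
    double v, gx, gy, gz;
    interp(g, fslot[b], fpos(b, 0), fpos(b, 1), fpos(b, 2), v, gx, gy, gz);
    total += v;
    grad(b, 0) = gx; grad(b, 1) = gy; grad(b, 2) = gz;
    if (fq[b] != 0.0) {
      interp(g, nprobe, fpos(b, 0), fpos(b, 1), fpos(b, 2), v, gx, gy, gz);
      total += fq[b] * v;
      grad(b, 0) += fq[b] * gx;
      grad(b, 1) += fq[b] * gy;
      grad(b, 2) += fq[b] * gz;
    }
  }
  return List::create(_["energy"] = total, _["gradient"] = grad);
}

static inline void rot_apply(const double R[9], const double *p, double *out) {
  out[0] = R[0] * p[0] + R[1] * p[1] + R[2] * p[2];
  out[1] = R[3] * p[0] + R[4] * p[1] + R[5] * p[2];
  out[2] = R[6] * p[0] + R[7] * p[1] + R[8] * p[2];
}

// Rodrigues: R = exp([w]_x)
static void exp_rot(const double w[3], double R[9]) {
  double th = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (th < 1e-14) {
    R[0] = R[4] = R[8] = 1; R[1] = R[2] = R[3] = R[5] = R[6] = R[7] = 0;
    return;
  }
  double kx = w[0] / th, ky = w[1] / th, kz = w[2] / th;
  double c = std::cos(th), s = std::sin(th), v = 1 - c;
  R[0] = c + kx * kx * v;      R[1] = kx * ky * v - kz * s; R[2] = kx * kz * v + ky * s;
  R[3] = ky * kx * v + kz * s; R[4] = c + ky * ky * v;      R[5] = ky * kz * v - kx * s;
  R[6] = kz * kx * v - ky * s; R[7] = kz * ky * v + kx * s; R[8] = c + kz * kz * v;
}

static void mat_mul(const double A[9], const double B[9], double C[9]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[3 * i + j] = A[3 * i] * B[j] + A[3 * i + 1] * B[3 + j] +
                     A[3 * i + 2] * B[6 + j];
}

struct EnergyCtx {
  bool use_grid;
  GridView g;
  int nprobe;
  const NumericMatrix *rpos;
  const IntegerVector *rtyp;
  const NumericVector *rq;
  const NumericMatrix *EPS, *RB;
  const LogicalMatrix *ATTR;
  bool dd;
  double coulomb_scale;
};

// energy + gradient (w.r.t. bead coords) of a placed fragment
static double ctx_energy(const EnergyCtx &c, const NumericMatrix &pos,
                         const IntegerVector &slot, const NumericVector &fq,
                         NumericMatrix &grad) {
  int nf = pos.nrow();
  double total = 0.0;
  if (c.use_grid) {
    for (int b = 0; b < nf; ++b) {
      double v, gx, gy, gz;
      interp(c.g, slot[b], pos(b, 0), pos(b, 1), pos(b, 2), v, gx, gy, gz);
      total += v; grad(b, 0) = gx; grad(b, 1) = gy; grad(b, 2) = gz;
      if (fq[b] != 0.0) {
        interp(c.g, c.nprobe, pos(b, 0), pos(b, 1), pos(b, 2), v, gx, gy, gz);
        total += fq[b] * v;
        grad(b, 0) += fq[b] * gx; grad(b, 1) += fq[b] * gy;
        grad(b, 2) += fq[b] * gz;
      }
    }
  } else {
    int nr = c.rpos->nrow();
    for (int i = 0; i < nf; ++i) {
      double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
      int ti = slot[i];
      double qi = fq[i], gx = 0, gy = 0, gz = 0;
      for (int j = 0; j < nr; ++j) {
        double dx = xi - (*c.rpos)(j, 0), dy = yi - (*c.rpos)(j, 1),
               dz = zi - (*c.rpos)(j, 2);
        double r2 = dx * dx + dy * dy + dz * dz;
        double e, dedr2;
        pair86((*c.EPS)(ti, (*c.rtyp)[j]), (*c.RB)(ti, (*c.rtyp)[j]),
               (*c.ATTR)(ti, (*c.rtyp)[j]), r2, e, dedr2);
        total += e;
        double f = 2.0 * dedr2;
        if (qi != 0.0 && (*c.rq)[j] != 0.0) {
          double ee, gg;
          pair_elec(qi * (*c.rq)[j], r2, c.dd, c.coulomb_scale, ee, gg);
          total += ee;
          f += 2.0 * gg;
        }
        gx += f * dx; gy += f * dy; gz += f * dz;
      }
      grad(i, 0) = gx; grad(i, 1) = gy; grad(i, 2) = gz;
    }
  }
  return total;
}

// Rigid-body minimization of one pose by adaptive-step projected gradient
// descent with a monotone (backtracking) acceptance rule. The pose is
// R*X + t over conformer coordinates X; rotations are applied about the
// current fragment COM so translation and rotation decouple.
// [[Rcpp::export]]
List minimize_cpp(NumericMatrix X, NumericVector R0, NumericVector t0,
                  IntegerVector slot, NumericVector fq, List grid,
                  NumericVector origin, double spacing, IntegerVector dims,
                  int nprobe, bool use_grid, NumericMatrix rpos,
                  IntegerVector rtyp, NumericVector rq, NumericMatrix EPS,
                  NumericMatrix RB, LogicalMatrix ATTR, bool dd_dielectric,
                  double coulomb_scale, NumericVector com_rec,
                  double restraint_k, int steps, double gtol) {
  int nf = X.nrow();
  NumericVector V, Gx, Gy, Gz;
  GridView g{};
  if (use_grid) {
    V = grid["V"]; Gx = grid["Gx"]; Gy = grid["Gy"]; Gz = grid["Gz"];
    g = GridView{REAL(V), REAL(Gx), REAL(Gy), REAL(Gz),
                 origin[0], origin[1], origin[2], spacing,
                 dims[0], dims[1], dims[2],
                 (R_xlen_t)dims[0] * dims[1] * dims[2]};
  }
  EnergyCtx ctx{use_grid, g, nprobe, &rpos, &rtyp, &rq,
                &EPS, &RB, &ATTR, dd_dielectric, coulomb_scale};

  double R[9];
  for (int i = 0; i < 9; ++i) R[i] = R0[i];
  double t[3] = {t0[0], t0[1], t0[2]};

  NumericMatrix pos(nf, 3), grad(nf, 3), trial(nf, 3);
  auto place = [&](const double Rm[9], const double tv[3], NumericMatrix &out) {
    for (int b = 0; b < nf; ++b) {
      double p[3] = {X(b, 0), X(b, 1), X(b, 2)}, q[3];
      rot_apply(Rm, p, q);
      out(b, 0) = q[0] + tv[0];
      out(b, 1) = q[1] + tv[1];
      out(b, 2) = q[2] + tv[2];
    }
  };
  auto full_energy = [&](NumericMatrix &p, NumericMatrix &gr) {
    double e = ctx_energy(ctx, p, slot, fq, gr);
    // COM restraint toward the receptor COM: k * d^2
    double cx = 0, cy = 0, cz = 0;
    for (int b = 0; b < nf; ++b) { cx += p(b, 0); cy += p(b, 1); cz += p(b, 2); }
    cx /= nf; cy /= nf; cz /= nf;
    double dx = cx - com_rec[0], dy = cy - com_rec[1], dz = cz - com_rec[2];
    e += restraint_k * (dx * dx + dy * dy + dz * dz);
    double f = 2.0 * restraint_k / nf;
    for (int b = 0; b < nf; ++b) {
      gr(b, 0) += f * dx; gr(b, 1) += f * dy; gr(b, 2) += f * dz;
    }
    return e;
  };

  place(R, t, pos);
  double e = full_energy(pos, grad);
  if (!std::isfinite(e)) {
    return List::create(_["R"] = R0, _["t"] = t0, _["energy"] = e,
                        _["iters"] = 0, _["converged"] = false,
                        _["ok"] = false);
  }
  // rotation step scale: radius of gyration of the conformer
  double rg2 = 0;
  {
    double cx = 0, cy = 0, cz = 0;
    for (int b = 0; b < nf; ++b) { cx += X(b, 0); cy += X(b, 1); cz += X(b, 2); }
    cx /= nf; cy /= nf; cz /= nf;
    for (int b = 0; b < nf; ++b) {
      double dx = X(b, 0) - cx, dy = X(b, 1) - cy, dz = X(b, 2) - cz;
      rg2 += dx * dx + dy * dy + dz * dz;
    }
    rg2 /= nf;
    if (rg2 < 1.0) rg2 = 1.0;
  }

  double lambda = 0.1;
  int it = 0;
  bool converged = false;
  for (it = 0; it < steps; ++it) {
    // force (translation) and torque (rotation about fragment COM)
    double F[3] = {0, 0, 0}, T[3] = {0, 0, 0};
    double cx = 0, cy = 0, cz = 0;
    for (int b = 0; b < nf; ++b) { cx += pos(b, 0); cy += pos(b, 1); cz += pos(b, 2); }
    cx /= nf; cy /= nf; cz /= nf;
    for (int b = 0; b < nf; ++b) {
      double gx = grad(b, 0), gy = grad(b, 1), gz = grad(b, 2);
      F[0] += gx; F[1] += gy; F[2] += gz;
      double rx = pos(b, 0) - cx, ry = pos(b, 1) - cy, rz = pos(b, 2) - cz;
      T[0] += ry * gz - rz * gy;
      T[1] += rz * gx - rx * gz;
      T[2] += rx * gy - ry * gx;
    }
    double gnorm = std::sqrt(F[0] * F[0] + F[1] * F[1] + F[2] * F[2] +
                             (T[0] * T[0] + T[1] * T[1] + T[2] * T[2]) / rg2);
    if (gnorm < gtol) { converged = true; break; }

    bool accepted = false;
    for (int bt = 0; bt < 30; ++bt) {
      double dt[3] = {-lambda * F[0], -lambda * F[1], -lambda * F[2]};
      double w[3] = {-lambda * T[0] / rg2, -lambda * T[1] / rg2,
                     -lambda * T[2] / rg2};
      double dR[9], Rn[9];
      exp_rot(w, dR);
      mat_mul(dR, R, Rn);
      // rotate about current COM: t_new chosen so COM moves only by dt
      // x' = dR*(R x + t - c) + c + dt  =>  R' = dR R, t' = dR(t - c) + c + dt
      double tmc[3] = {t[0] - cx, t[1] - cy, t[2] - cz}, rt[3];
      rot_apply(dR, tmc, rt);
      double tn[3] = {rt[0] + cx + dt[0], rt[1] + cy + dt[1],
                      rt[2] + cz + dt[2]};
      place(Rn, tn, trial);
      NumericMatrix gtrial(nf, 3);
      double etrial = full_energy(trial, gtrial);
      if (std::isfinite(etrial) && etrial <= e) {
        for (int i = 0; i < 9; ++i) R[i] = Rn[i];
        t[0] = tn[0]; t[1] = tn[1]; t[2] = tn[2];
        pos = clone(trial);
        grad = gtrial;
        e = etrial;
        lambda *= 1.5;
        if (lambda > 10.0) lambda = 10.0;
        accepted = true;
        break;
      }
      lambda *= 0.4;
      if (lambda < 1e-9) break;
    }
    if (!accepted) { converged = true; break; }
  }
  NumericVector Rout(9), tout(3);
  for (int i = 0; i < 9; ++i) Rout[i] = R[i];
  for (int i = 0; i < 3; ++i) tout[i] = t[i];
  return List::create(_["R"] = Rout, _["t"] = tout, _["energy"] = e,
                      _["iters"] = it, _["converged"] = converged,
                      _["ok"] = true);
}

// Greedy removal of redundant poses. `coords` holds one pose per row
// (flattened bead coordinates, 3*m columns), sorted best-energy-first.
// A pose is dropped iff its plain RMSD to a better, kept pose of the same
// conformer is strictly below `tol`.
// [[Rcpp::export]]
LogicalVector greedy_dedup_cpp(NumericMatrix coords, IntegerVector conformer,
                               double tol) {
  int n = coords.nrow(), m3 = coords.ncol();
  double thr = tol * tol * (m3 / 3);  // compare sum of squared diffs
  LogicalVector keep(n, true);
  std::vector<int> kept;
  kept.reserve(n);
  for (int i = 0; i < n; ++i) {
    bool dup = false;
    for (int kj : kept) {
      if (conformer[kj] != conformer[i]) continue;
      double ss = 0;
      for (int c = 0; c < m3; ++c) {
        double d = coords(i, c) - coords(kj, c);
        ss += d * d;
        if (ss >= thr) break;
      }
      if (ss < thr) { dup = true; break; }
    }
    keep[i] = !dup;
    if (!dup) kept.push_back(i);
  }
  return keep;
}

// Greedy leader clustering in row (rank) order: a pose joins the first
// cluster whose representative is within `radius` (plain RMSD), else it
// founds a new cluster. Returns 1-based cluster ids per pose.
// [[Rcpp::export]]
IntegerVector leader_cluster_cpp(NumericMatrix coords, double radius) {
  int n = coords.nrow(), m3 = coords.ncol();
  double thr = radius * radius * (m3 / 3);
  IntegerVector cl(n);
  std::vector<int> reps;
  for (int i = 0; i < n; ++i) {
    int assigned = 0;
    for (size_t r = 0; r < reps.size(); ++r) {
      double ss = 0;
      int rep = reps[r];
      for (int c = 0; c < m3; ++c) {
        double d = coords(i, c) - coords(rep, c);
        ss += d * d;
        if (ss > thr) break;
      }
      if (ss <= thr) { assigned = (int)r + 1; break; }
    }
    if (!assigned) {
      reps.push_back(i);
      assigned = (int)reps.size();
    }
    cl[i] = assigned;
  }
  return cl;
}

// All pairwise plain RMSDs between flattened pose coordinates of equal
// bead count. Returns an n x n symmetric matrix.
// [[Rcpp::export]]
NumericMatrix pose_rmsd_matrix_cpp(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow(), m3 = a.ncol();
  NumericMatrix out(n, m);
  double inv = 3.0 / m3;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double ss = 0;
      for (int c = 0; c < m3; ++c) {
        double d = a(i, c) - b(j, c);
        ss += d * d;
      }
      out(i, j) = std::sqrt(ss * inv);
    }
  }
  return out;
}
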