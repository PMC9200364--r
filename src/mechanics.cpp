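// Bead-spring force field and overdamped Langevin (Ermak-McCammon)
// integration kernels.  Units: nm, pN, pN nm, pN ps/nm, ps.
//
// Energy components are accumulated into six slots:
//   0 U_MT  (MT stretch + bend + minus-end anchor restraints)
//   1 U_KT  (centromere spring, corona grid, corona-to-KT)
//   2 U_CH  (arm stretch + bend + cohesin)
//   3 U_att (Ndc80 attachment springs)
//   4 U_rep (repulsive 12-power excluded volume)
//   5 U_mem (soft harmonic membrane repulsion outside the ellipsoid)

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct ForceField {
  int n;
  NumericMatrix bonds, angles, posres, dirres, attach;
  std::vector<int> lj_i, lj_j;          // candidate excluded-volume pairs
  std::vector<double> lj_sigma, lj_cut;
  double eps;
  bool has_ellipse;
  double ea, eb, ec, K_mem;
  bool has_ext;
  NumericMatrix extFm; // n x 3 external forces (optional)
  // evaluated term rows (restrict_to() filters them to an active subset)
  std::vector<int> rows_bonds, rows_angles, rows_posres, rows_dirres,
      rows_attach, mem_beads;

  ForceField(int n_, NumericMatrix bonds_, NumericMatrix angles_,
             NumericMatrix posres_, NumericMatrix dirres_,
             NumericMatrix attach_, IntegerVector ljclass,
             NumericVector radius, double eps_, double cutmult,
             IntegerMatrix excl, NumericVector ellipse, double K_mem_,
             Nullable<NumericMatrix> extF_)
    : n(n_), bonds(bonds_), angles(angles_), posres(posres_),
      dirres(dirres_), attach(attach_), eps(eps_), K_mem(K_mem_) {
    has_ext = extF_.isNotNull();
    if (has_ext) extFm = extF_.get();
    has_ellipse = ellipse.size() == 3;
    if (has_ellipse) { ea = ellipse[0]; eb = ellipse[1]; ec = ellipse[2]; }
    // excluded-volume candidates: class pairs (1,2) and (2,2), minus bonded
    std::unordered_set<long long> ex;
    for (int r = 0; r < excl.nrow(); ++r) {
      long long a = excl(r, 0) - 1, b = excl(r, 1) - 1;
      if (a > b) std::swap(a, b);
      ex.insert(a * (long long)n + b);
    }
    std::vector<int> c1, c2;
    for (int i = 0; i < n; ++i) {
      if (ljclass[i] == 1) c1.push_back(i);
      else if (ljclass[i] == 2) c2.push_back(i);
    }
    auto add_pair = [&](int a, int b) {
      long long lo = a < b ? a : b, hi = a < b ? b : a;
      if (ex.count(lo * (long long)n + hi)) return;
      lj_i.push_back(a); lj_j.push_back(b);
      double s = radius[a] + radius[b];
      lj_sigma.push_back(s);
      lj_cut.push_back(s * cutmult);
    };
    for (size_t a = 0; a < c1.size(); ++a)
      for (size_t b = 0; b < c2.size(); ++b) add_pair(c1[a], c2[b]);
    for (size_t a = 0; a < c2.size(); ++a)
      for (size_t b = a + 1; b < c2.size(); ++b) add_pair(c2[a], c2[b]);
    for (int r = 0; r < bonds.nrow(); ++r) rows_bonds.push_back(r);
    for (int r = 0; r < angles.nrow(); ++r) rows_angles.push_back(r);
    for (int r = 0; r < posres.nrow(); ++r) rows_posres.push_back(r);
    for (int r = 0; r < dirres.nrow(); ++r) rows_dirres.push_back(r);
    for (int r = 0; r < attach.nrow(); ++r) rows_attach.push_back(r);
    for (int i = 0; i < n; ++i) mem_beads.push_back(i);
  }

  // keep only interaction terms that touch at least one active bead
  void restrict_to(const std::vector<char>& act) {
    auto filt2 = [&](std::vector<int>& rows, NumericMatrix& m, int ci,
                     int cj) {
      std::vector<int> keep;
      for (int r : rows) {
        if (act[(int)m(r, ci) - 1] || (cj >= 0 && act[(int)m(r, cj) - 1]))
          keep.push_back(r);
      }
      rows.swap(keep);
    };
    filt2(rows_bonds, bonds, 0, 1);
    {
      std::vector<int> keep;
      for (int r : rows_angles)
        if (act[(int)angles(r, 0) - 1] || act[(int)angles(r, 1) - 1] ||
            act[(int)angles(r, 2) - 1])
          keep.push_back(r);
      rows_angles.swap(keep);
    }
    filt2(rows_posres, posres, 0, -1);
    filt2(rows_dirres, dirres, 0, 1);
    filt2(rows_attach, attach, 0, 1);
    std::vector<int> ki, kj; std::vector<double> ks, kc;
    for (size_t q = 0; q < lj_i.size(); ++q) {
      if (act[lj_i[q]] || act[lj_j[q]]) {
        ki.push_back(lj_i[q]); kj.push_back(lj_j[q]);
        ks.push_back(lj_sigma[q]); kc.push_back(lj_cut[q]);
      }
    }
    lj_i.swap(ki); lj_j.swap(kj); lj_sigma.swap(ks); lj_cut.swap(kc);
    std::vector<int> kb;
    for (int i : mem_beads) if (act[i]) kb.push_back(i);
    mem_beads.swap(kb);
  }

  // nearest point q on the ellipsoid surface from exterior point p; returns
  // the separation distance and fills q (projected-Newton on the Lagrange
  // multiplier; f is convex decreasing so Newton from t = 0 is monotone)
  double surface_point(const double* p, double* q) const {
    const double s2[3] = {ea * ea, eb * eb, ec * ec};
    double t = 0.0;
    for (int it = 0; it < 200; ++it) {
      double f = -1.0, fp = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = s2[k] + t;
        double w = p[k] * std::sqrt(s2[k]) / d;
        f += w * w;
        fp += -2.0 * p[k] * p[k] * s2[k] / (d * d * d);
      }
      if (std::fabs(f) < 1e-13) break;
      t -= f / fp;
      if (t < 0) t = 0;
    }
    double dist2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      q[k] = p[k] * s2[k] / (s2[k] + t);
      dist2 += (p[k] - q[k]) * (p[k] - q[k]);
    }
    return std::sqrt(dist2);
  }

  // pos, F: length-3n arrays, layout x0..x(n-1), y0.., z0.. (column-major)
  void eval(const double* pos, double* F, double* U) const {
    for (int k = 0; k < 6; ++k) U[k] = 0.0;
    if (F) std::fill(F, F + 3 * n, 0.0);

    auto px = [&](int i) { return pos[i]; };
    auto py = [&](int i) { return pos[i + n]; };
    auto pz = [&](int i) { return pos[i + 2 * n]; };
    auto addF = [&](int i, double fx, double fy, double fz) {
      if (!F) return;
      F[i] += fx; F[i + n] += fy; F[i + 2 * n] += fz;
    };

    // harmonic bonds
    for (int r : rows_bonds) {
      int i = (int)bonds(r, 0) - 1, j = (int)bonds(r, 1) - 1;
      double k = bonds(r, 2), r0 = bonds(r, 3);
      int g = (int)bonds(r, 4) - 1;
      double dx = px(j) - px(i), dy = py(j) - py(i), dz = pz(j) - pz(i);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dl = d - r0;
      U[g] += 0.5 * k * dl * dl;
      if (d > 1e-12) {
        double fac = k * dl / d;  // force on i toward j when stretched
        addF(i, fac * dx, fac * dy, fac * dz);
        addF(j, -fac * dx, -fac * dy, -fac * dz);
      }
    }

    // harmonic angles (vertex j)
    for (int r : rows_angles) {
      int i = (int)angles(r, 0) - 1, j = (int)angles(r, 1) - 1,
          k = (int)angles(r, 2) - 1;
      double kt = angles(r, 3), th0 = angles(r, 4);
      int g = (int)angles(r, 5) - 1;
      double ax = px(i) - px(j), ay = py(i) - py(j), az = pz(i) - pz(j);
      double bx = px(k) - px(j), by = py(k) - py(j), bz = pz(k) - pz(j);
      double la = std::sqrt(ax * ax + ay * ay + az * az);
      double lb = std::sqrt(bx * bx + by * by + bz * bz);
      if (la < 1e-12 || lb < 1e-12) continue;
      double c = (ax * bx + ay * by + az * bz) / (la * lb);
      if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
      double th = std::acos(c);
      double dth = th - th0;
      U[g] += 0.5 * kt * dth * dth;
      double s = std::sqrt(1.0 - c * c);
      double coef = (s > 1e-8) ? kt * dth / s : kt; // -dU/dtheta / sin
      // dcos/da = b/(la lb) - c a/la^2 ; F_i = coef * dcos/da
      double fix = coef * (bx / (la * lb) - c * ax / (la * la));
      double fiy = coef * (by / (la * lb) - c * ay / (la * la));
      double fiz = coef * (bz / (la * lb) - c * az / (la * la));
      double fkx = coef * (ax / (la * lb) - c * bx / (lb * lb));
      double fky = coef * (ay / (la * lb) - c * by / (lb * lb));
      double fkz = coef * (az / (la * lb) - c * bz / (lb * lb));
      addF(i, fix, fiy, fiz);
      addF(k, fkx, fky, fkz);
      addF(j, -(fix + fkx), -(fiy + fky), -(fiz + fkz));
    }

    // position restraints (MT minus-end anchors) -> U_MT
    for (int r : rows_posres) {
      int i = (int)posres(r, 0) - 1;
      double kr = posres(r, 4);
      double dx = px(i) - posres(r, 1), dy = py(i) - posres(r, 2),
             dz = pz(i) - posres(r, 3);
      U[0] += 0.5 * kr * (dx * dx + dy * dy + dz * dz);
      addF(i, -kr * dx, -kr * dy, -kr * dz);
    }

    // direction restraints (anchor orientation) -> U_MT
    for (int r : rows_dirres) {
      int im = (int)dirres(r, 0) - 1, ib = (int)dirres(r, 1) - 1;
      double dxu = dirres(r, 2), dyu = dirres(r, 3), dzu = dirres(r, 4);
      double kt = dirres(r, 5);
      double ux = px(ib) - px(im), uy = py(ib) - py(im), uz = pz(ib) - pz(im);
      double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
      if (lu < 1e-12) continue;
      double c = (ux * dxu + uy * dyu + uz * dzu) / lu;
      if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
      double th = std::acos(c);
      U[0] += 0.5 * kt * th * th;
      double s = std::sqrt(1.0 - c * c);
      double coef = (s > 1e-8) ? kt * th / s : kt;
      double fbx = coef * (dxu - c * ux / lu) / lu;
      double fby = coef * (dyu - c * uy / lu) / lu;
      double fbz = coef * (dzu - c * uz / lu) / lu;
      addF(ib, fbx, fby, fbz);
      addF(im, -fbx, -fby, -fbz);
    }

    // Ndc80 attachment springs
    for (int r : rows_attach) {
      int i = (int)attach(r, 0) - 1, j = (int)attach(r, 1) - 1;
      double k = attach(r, 2), l0 = attach(r, 3);
      double dx = px(j) - px(i), dy = py(j) - py(i), dz = pz(j) - pz(i);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dl = d - l0;
      U[3] += 0.5 * k * dl * dl;
      if (d > 1e-12) {
        double fac = k * dl / d;
        addF(i, fac * dx, fac * dy, fac * dz);
        addF(j, -fac * dx, -fac * dy, -fac * dz);
      }
    }

    // repulsive 12-power excluded volume
    for (size_t q = 0; q < lj_i.size(); ++q) {
      int i = lj_i[q], j = lj_j[q];
      double dx = px(j) - px(i), dy = py(j) - py(i), dz = pz(j) - pz(i);
      double d2 = dx * dx + dy * dy + dz * dz;
      double cut = lj_cut[q];
      if (d2 >= cut * cut) continue;
      double d = std::sqrt(d2);
      if (d < 1e-9) stop("overlapping bead centers in excluded-volume pair");
      double sr = lj_sigma[q] / d;
      double sr12 = std::pow(sr, 12);
      U[4] += eps * sr12;
      double fac = 12.0 * eps * sr12 / (d * d);  // * vector = repulsion
      addF(i, -fac * dx, -fac * dy, -fac * dz);
      addF(j, fac * dx, fac * dy, fac * dz);
    }

    // membrane
    if (has_ellipse) {
      for (int i : mem_beads) {
        double x = px(i), y = py(i), z = pz(i);
        double zeta = (x / ea) * (x / ea) + (y / eb) * (y / eb) +
                      (z / ec) * (z / ec);
        if (zeta <= 1.0) continue;
        double p[3] = {x, y, z}, q[3];
        double rdist = surface_point(p, q);
        U[5] += 0.5 * K_mem * rdist * rdist;
        // U = K r^2 / 2 with r = |p - q|, grad_p r = (p - q)/r exactly
        if (rdist > 1e-12) {
          addF(i, -K_mem * (p[0] - q[0]), -K_mem * (p[1] - q[1]),
               -K_mem * (p[2] - q[2]));
        }
      }
    }

    if (F && has_ext)
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) F[i + k * n] += extFm(i, k);
  }
};

static ForceField make_ff(NumericMatrix pos, NumericVector radius,
                          NumericMatrix bonds, NumericMatrix angles,
                          NumericMatrix posres, NumericMatrix dirres,
                          NumericMatrix attach, IntegerVector ljclass,
                          double eps, double cutmult, IntegerMatrix excl,
                          NumericVector ellipse, double K_mem,
                          Nullable<NumericMatrix> extF) {
  return ForceField(pos.nrow(), bonds, angles, posres, dirres, attach,
                    ljclass, radius, eps, cutmult, excl, ellipse, K_mem,
                    extF);
}

// [[Rcpp::export]]
List ff_eval_cpp(NumericMatrix pos, NumericVector radius,
                 LogicalVector frozen, NumericMatrix bonds,
                 NumericMatrix angles, NumericMatrix posres,
                 NumericMatrix dirres, NumericMatrix attach,
                 IntegerVector ljclass, double eps, double cutmult,
                 IntegerMatrix excl, NumericVector ellipse, double K_mem,
                 Nullable<NumericMatrix> extF, bool want_forces) {
  ForceField ff = make_ff(pos, radius, bonds, angles, posres, dirres, attach,
                          ljclass, eps, cutmult, excl, ellipse, K_mem, extF);
  int n = pos.nrow();
  double U[6];
  NumericMatrix F;
  if (want_forces) {
    F = NumericMatrix(n, 3);
    ff.eval(REAL(pos), REAL(F), U);
    for (int i = 0; i < n; ++i)
      if (frozen[i]) { F(i, 0) = 0; F(i, 1) = 0; F(i, 2) = 0; }
  } else {
    ff.eval(REAL(pos), nullptr, U);
  }
  double tot = U[0] + U[1] + U[2] + U[3] + U[4] + U[5];
  List out = List::create(
      _["U_MT"] = U[0], _["U_KT"] = U[1], _["U_CH"] = U[2],
      _["U_att"] = U[3], _["U_rep"] = U[4], _["U_mem"] = U[5],
      _["total"] = tot);
  if (want_forces) out["forces"] = F;
  return out;
}

// T = 0 steepest-descent relaxation: r += (F/gamma) dt until max |F| < ftol.
// [[Rcpp::export]]
List ld_relax_cpp(NumericMatrix pos, NumericVector radius,
                  LogicalVector frozen, NumericVector gamma,
                  NumericMatrix bonds, NumericMatrix angles,
                  NumericMatrix posres, NumericMatrix dirres,
                  NumericMatrix attach, IntegerVector ljclass, double eps,
                  double cutmult, IntegerMatrix excl, NumericVector ellipse,
                  double K_mem, Nullable<NumericMatrix> extF,
                  NumericVector dt, double ftol, int max_steps,
                  IntegerVector active, double max_disp) {
  // dt is per bead: T = 0 relaxation is diagonally preconditioned descent,
  // so per-bead steps below each bead's own stability bound reach the same
  // equilibrium while letting soft, high-friction beads take full steps.
  // `active` (1-based bead indices; empty = all) restricts the moving set:
  // only interaction terms touching an active bead are evaluated, the rest
  // of the system is held fixed -- the scheduler relaxes the local
  // neighborhood of an event without paying for the whole cell.
  ForceField ff = make_ff(pos, radius, bonds, angles, posres, dirres, attach,
                          ljclass, eps, cutmult, excl, ellipse, K_mem, extF);
  int n = pos.nrow();
  std::vector<char> act(n, 1);
  if (active.size() > 0) {
    std::fill(act.begin(), act.end(), 0);
    for (int q = 0; q < active.size(); ++q) act[active[q] - 1] = 1;
    ff.restrict_to(act);
  }
  NumericMatrix out = clone(pos);
  double* r = REAL(out);
  std::vector<double> F(3 * n);
  double U[6], maxF = 0.0;
  int steps = 0;
  bool converged = false;
  for (steps = 0; steps <= max_steps; ++steps) {
    ff.eval(r, F.data(), U);
    maxF = 0.0;
    for (int i = 0; i < n; ++i) {
      if (frozen[i] || !act[i]) continue;
      double f2 = F[i] * F[i] + F[i + n] * F[i + n] +
                  F[i + 2 * n] * F[i + 2 * n];
      if (f2 > maxF) maxF = f2;
    }
    maxF = std::sqrt(maxF);
    if (maxF < ftol) { converged = true; break; }
    if (steps == max_steps) break;
    for (int i = 0; i < n; ++i) {
      if (frozen[i] || !act[i]) continue;
      double mob = dt[i] / gamma[i];
      double dx = mob * F[i], dy = mob * F[i + n], dz = mob * F[i + 2 * n];
      // trust region: steep excluded-volume contacts are not covered by
      // the harmonic stability bound, so cap the per-step displacement
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > max_disp * max_disp) {
        double sc = max_disp / std::sqrt(d2);
        dx *= sc; dy *= sc; dz *= sc;
      }
      r[i] += dx;
      r[i + n] += dy;
      r[i + 2 * n] += dz;
    }
  }
  return List::create(_["pos"] = out, _["n_steps"] = steps,
                      _["max_force"] = maxF, _["converged"] = converged);
}

// Thermal (or T = 0) trajectory: fixed number of Ermak-McCammon steps,
// sampling selected beads every `sample_every` steps.  Noise per coordinate
// is Normal(0, 2 kT dt / gamma_i).
// [[Rcpp::export]]
List ld_run_cpp(NumericMatrix pos, NumericVector radius, LogicalVector frozen,
                NumericVector gamma, NumericMatrix bonds,
                NumericMatrix angles, NumericMatrix posres,
                NumericMatrix dirres, NumericMatrix attach,
                IntegerVector ljclass, double eps, double cutmult,
                IntegerMatrix excl, NumericVector ellipse, double K_mem,
                Nullable<NumericMatrix> extF, double dt, int n_steps,
                double kT, bool noise, int sample_every,
                IntegerVector sample_beads) {
  ForceField ff = make_ff(pos, radius, bonds, angles, posres, dirres, attach,
                          ljclass, eps, cutmult, excl, ellipse, K_mem, extF);
  int n = pos.nrow();
  NumericMatrix out = clone(pos);
  double* r = REAL(out);
  std::vector<double> F(3 * n), sig(n);
  for (int i = 0; i < n; ++i)
    sig[i] = noise ? std::sqrt(2.0 * kT * dt / gamma[i]) : 0.0;
  int ns = sample_beads.size();
  int nrec = sample_every > 0 ? n_steps / sample_every : 0;
  NumericMatrix samples(nrec, 3 * ns);
  double U[6];
  RNGScope scope;
  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    ff.eval(r, F.data(), U);
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      double mob = dt / gamma[i];
      r[i] += mob * F[i];
      r[i + n] += mob * F[i + n];
      r[i + 2 * n] += mob * F[i + 2 * n];
      if (noise) {
        r[i] += sig[i] * norm_rand();
        r[i + n] += sig[i] * norm_rand();
        r[i + 2 * n] += sig[i] * norm_rand();
      }
    }
    if (sample_every > 0 && step % sample_every == 0 && rec < nrec) {
      for (int q = 0; q < ns; ++q) {
        int b = sample_beads[q] - 1;
        samples(rec, 3 * q) = r[b];
        samples(rec, 3 * q + 1) = r[b + n];
        samples(rec, 3 * q + 2) = r[b + 2 * n];
      }
      ++rec;
    }
  }
  return List::create(_["pos"] = out, _["samples"] = samples);
}
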