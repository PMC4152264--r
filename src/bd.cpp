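// Core numerics for crowded-box Brownian dynamics:
//  - harmonic stretch / bend / inter-protein repulsion energies and forces
//  - local volume fraction via exact sphere-ball lens overlaps
//  - Tokuyama mean-field H(phi)
//  - Ermak-McCammon propagator with Verlet pair lists and periodic wrapping
// All lengths Angstrom, times ns, energies kcal/mol, D in A^2/ns.

// distributions ship -O2 in CXXFLAGS after PKG_CXXFLAGS; the propagator is
// hot enough that we request full optimization at the translation unit level
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3", "no-math-errno")
#endif

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <chrono>
using namespace Rcpp;

static inline double min_image1(double d, double L) {
  // component of the minimum-image displacement, in [-L/2, L/2)
  return d - L * std::floor(d / L + 0.5);
}

static inline double tok_H(double phi) {
  if (phi <= 0.0) return 0.0;
  const double b = std::sqrt(1.125 * phi);   // (9 phi / 8)^(1/2)
  const double c = 0.6875 * phi;             // 11 phi / 16
  return 2.0 * b * b / (1.0 - b)
       - c / (1.0 + 2.0 * c)
       - b * c * (2.0 + c) / ((1.0 + c) * (1.0 - b + c));
}

// Volume of a sphere of radius a whose centre lies at distance d from the
// centre of a ball of radius R (the intersection with that ball).
static inline double sphere_ball_overlap(double d, double R, double a) {
  if (d >= R + a) return 0.0;
  if (d + a <= R) return (4.0 / 3.0) * M_PI * a * a * a;  // fully inside
  if (d + R <= a) return (4.0 / 3.0) * M_PI * R * R * R;  // ball inside sphere
  const double t = R + a - d;
  return M_PI * t * t *
         (d * d + 2.0 * d * a - 3.0 * a * a + 2.0 * d * R + 6.0 * a * R -
          3.0 * R * R) /
         (12.0 * d);
}

// [[Rcpp::export]]
double cpp_sphere_ball_overlap(double d, double R, double a) {
  return sphere_ball_overlap(d, R, a);
}

// [[Rcpp::export]]
NumericVector cpp_tokuyama_H(NumericVector phi) {
  const int n = phi.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tok_H(phi[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Energy and forces (reference O(N^2) path, used by the user-facing API and
// as one side of the dual-route tests; the run loop below has its own
// neighbor-listed path).
// ---------------------------------------------------------------------------

static void add_stretch(const std::vector<double>& x, const IntegerMatrix& bonds,
                        const NumericVector& l0, double ks, double& E,
                        std::vector<double>& F) {
  const int m = bonds.nrow();
  for (int b = 0; b < m; ++b) {
    const int i = bonds(b, 0), j = bonds(b, 1);
    double d[3];
    double r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      d[k] = x[3 * i + k] - x[3 * j + k];  // intra-protein: unwrapped coords
      r2 += d[k] * d[k];
    }
    const double r = std::sqrt(r2);
    if (r < 1e-12) stop("coincident bonded sphere centers: bond direction undefined");
    const double dl = r - l0[b];
    E += ks * dl * dl;
    const double fpref = -2.0 * ks * dl / r;  // F_i = -2 ks (r - l0) * d/r
    for (int k = 0; k < 3; ++k) {
      F[3 * i + k] += fpref * d[k];
      F[3 * j + k] -= fpref * d[k];
    }
  }
}

static void add_bend(const std::vector<double>& x, const IntegerMatrix& angles,
                     const NumericVector& th0, double g, double sin_min,
                     double& E, std::vector<double>& F) {
  const int m = angles.nrow();
  for (int t = 0; t < m; ++t) {
    const int i = angles(t, 0), j = angles(t, 1), k = angles(t, 2);  // j vertex
    double u[3], v[3];
    double nu2 = 0.0, nv2 = 0.0, dot = 0.0;
    for (int c = 0; c < 3; ++c) {
      u[c] = x[3 * i + c] - x[3 * j + c];
      v[c] = x[3 * k + c] - x[3 * j + c];
      nu2 += u[c] * u[c];
      nv2 += v[c] * v[c];
      dot += u[c] * v[c];
    }
    const double nu = std::sqrt(nu2), nv = std::sqrt(nv2);
    if (nu < 1e-12 || nv < 1e-12)
      stop("coincident spheres in angle: bend direction undefined");
    const double inv_nu = 1.0 / nu, inv_nv = 1.0 / nv;
    double cth = dot * inv_nu * inv_nv;
    if (cth > 1.0) cth = 1.0;
    if (cth < -1.0) cth = -1.0;
    const double theta = std::acos(cth);
    double sth = std::sqrt(1.0 - cth * cth);
    if (sth < sin_min) sth = sin_min;  // collinear clamp, documented
    const double dth = theta - th0[t];
    E += g * dth * dth;
    const double dE = 2.0 * g * dth;
    // dtheta/dr_i = (cth*u/nu - v/nv) / (nu*sth); symmetric for k; vertex by
    // translation invariance.
    const double inv_s = 1.0 / sth;
    const double gui = inv_nu * inv_s;
    const double gvk = inv_nv * inv_s;
    for (int c = 0; c < 3; ++c) {
      const double gi = (cth * u[c] * inv_nu - v[c] * inv_nv) * gui;
      const double gk = (cth * v[c] * inv_nv - u[c] * inv_nu) * gvk;
      F[3 * i + c] -= dE * gi;
      F[3 * k + c] -= dE * gk;
      F[3 * j + c] += dE * (gi + gk);
    }
  }
}

static void add_rep_pair(const std::vector<double>& x, int i, int j, double L,
                         double sigma, double kr, double& E,
                         std::vector<double>& F) {
  double d[3];
  double r2 = 0.0;
  for (int c = 0; c < 3; ++c) {
    d[c] = min_image1(x[3 * i + c] - x[3 * j + c], L);
    r2 += d[c] * d[c];
  }
  if (r2 >= sigma * sigma) return;
  const double r = std::sqrt(r2);
  if (r < 1e-12) stop("coincident spheres of different proteins: repulsion direction undefined");
  const double ov = sigma - r;
  E += kr * ov * ov;
  const double fpref = 2.0 * kr * ov / r;  // repulsive: pushes i away from j
  for (int c = 0; c < 3; ++c) {
    F[3 * i + c] += fpref * d[c];
    F[3 * j + c] -= fpref * d[c];
  }
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector radii,
                       IntegerVector mol, IntegerMatrix bonds,
                       NumericVector bondL0, IntegerMatrix angles,
                       NumericVector angleTheta0, double L, double ks,
                       double g, double kr, bool doStretch, bool doBend,
                       bool doRep, double sinMin) {
  const int N = pos.nrow();
  std::vector<double> x(3 * N), F(3 * N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos(i, c);
  double Es = 0.0, Eb = 0.0, Er = 0.0;
  if (doStretch) add_stretch(x, bonds, bondL0, ks, Es, F);
  if (doBend) add_bend(x, angles, angleTheta0, g, sinMin, Eb, F);
  if (doRep) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (mol[i] == mol[j]) continue;  // repulsion is inter-protein only
        add_rep_pair(x, i, j, L, radii[i] + radii[j], kr, Er, F);
      }
  }
  NumericMatrix Fout(N, 3);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) Fout(i, c) = F[3 * i + c];
  return List::create(_["E_stretch"] = Es, _["E_bend"] = Eb,
                      _["E_repulsion"] = Er, _["forces"] = Fout);
}

// [[Rcpp::export]]
NumericVector cpp_local_phi(NumericMatrix pos, NumericVector radii, double L,
                            double rcutMult, bool includeSelf, double phiMax) {
  const int N = pos.nrow();
  NumericVector phi(N);
  std::vector<double> vol(N);
  for (int i = 0; i < N; ++i)
    vol[i] = (4.0 / 3.0) * M_PI * radii[i] * radii[i] * radii[i];
  for (int i = 0; i < N; ++i) {
    const double Rcut = rcutMult * radii[i];
    double v = includeSelf ? vol[i] : 0.0;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      double r2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        const double d = min_image1(pos(i, c) - pos(j, c), L);
        r2 += d * d;
      }
      const double rc = Rcut + radii[j];
      if (r2 >= rc * rc) continue;
      v += sphere_ball_overlap(std::sqrt(r2), Rcut, radii[j]);
    }
    double f = v / ((4.0 / 3.0) * M_PI * Rcut * Rcut * Rcut);
    if (f > phiMax) f = phiMax;
    phi[i] = f;
  }
  return phi;
}

// ---------------------------------------------------------------------------
// Run loop
// ---------------------------------------------------------------------------

// fast minimum image for wrapped inputs: d in (-L, L) -> [-L/2, L/2)
// (branchless: the comparisons compile to selects, which matters in the
// pair loops where the branch pattern is unpredictable)
static inline double mi_wrapped(double d, double L, double halfL) {
  d -= L * (double)(d >= halfL);
  d += L * (double)(d < -halfL);
  return d;
}

struct PairList {
  std::vector<int> i, j;
  std::vector<double> sigma2;          // squared repulsion contact distance
  // phi pairs; lens constants are recomputed from the radii in the hot
  // pass (cheaper than streaming them from memory):
  // overlap(d) = (pi/12) (A-d)^2 (d^2 + 2Ad - 3W^2) / d for |W| < d < A,
  // = volume of the smaller body for d <= |W|, = 0 for d >= A,
  // with A = R+a, W = a-R.
  std::vector<int> pi, pj;
  std::vector<double> cut2max;
};

static void build_lists(const std::vector<double>& xw,
                        const NumericVector& radii, const IntegerVector& mol,
                        double L, double skin, bool repulsion, bool hi,
                        double rcutMult, PairList& pl) {
  const int N = radii.size();
  const double halfL = 0.5 * L;
  pl.i.clear(); pl.j.clear(); pl.sigma2.clear();
  pl.pi.clear(); pl.pj.clear(); pl.cut2max.clear();
  for (int i = 0; i < N; ++i) {
    const double xi = xw[3 * i], yi = xw[3 * i + 1], zi = xw[3 * i + 2];
    for (int j = i + 1; j < N; ++j) {
      const double dx = mi_wrapped(xi - xw[3 * j], L, halfL);
      const double dy = mi_wrapped(yi - xw[3 * j + 1], L, halfL);
      const double dz = mi_wrapped(zi - xw[3 * j + 2], L, halfL);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (repulsion && mol[i] != mol[j]) {
        const double s = radii[i] + radii[j];
        const double reach = s + skin;
        if (r2 < reach * reach) {
          pl.i.push_back(i); pl.j.push_back(j); pl.sigma2.push_back(s * s);
        }
      }
      if (hi) {
        const double Ri = rcutMult * radii[i], Rj = rcutMult * radii[j];
        const double ci = Ri + radii[j];   // A for i's ball vs sphere j
        const double cj = Rj + radii[i];
        const double reach = (ci > cj ? ci : cj) + skin;
        if (r2 < reach * reach) {
          const double cmax = ci > cj ? ci : cj;
          pl.pi.push_back(i); pl.pj.push_back(j);
          pl.cut2max.push_back(cmax * cmax);
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_run_bd(NumericMatrix pos0, NumericVector radii, IntegerVector mol,
                LogicalVector frozen, NumericVector D0, IntegerMatrix bonds,
                NumericVector bondL0, IntegerMatrix angles,
                NumericVector angleTheta0, double L, double dt, int nSteps,
                int saveEvery, double kBT, double ks, double g, double kr,
                bool repulsion, bool hi, double rcutMult, bool includeSelf,
                double phiMax, double skin, double noiseScale, bool recordPhi,
                double sinMin, bool verbose) {
  const int N = pos0.nrow();
  std::vector<double> x(3 * N), xw(3 * N), F(3 * N), disp(3 * N, 0.0);
  std::vector<double> phi(N, 0.0), Deff(N), vol(N), Rcut(N), invBall(N);
  for (int i = 0; i < N; ++i) {
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos0(i, c);
    vol[i] = (4.0 / 3.0) * M_PI * radii[i] * radii[i] * radii[i];
    Rcut[i] = rcutMult * radii[i];
    invBall[i] = 1.0 / ((4.0 / 3.0) * M_PI * Rcut[i] * Rcut[i] * Rcut[i]);
  }
  const double invL = 1.0 / L, halfL = 0.5 * L;
  for (int i = 0; i < 3 * N; ++i) xw[i] = x[i] - L * std::floor(x[i] * invL);
  double D0max = 0.0;
  for (int i = 0; i < N; ++i) if (D0[i] > D0max) D0max = D0[i];
  // single-step sanity bound: many sigma of the free step plus slack; a
  // displacement beyond this means the integration blew up
  const double max_step = 12.0 * std::sqrt(2.0 * D0max * dt) + 1.0;
  const double half_skin = 0.5 * skin;
  if (max_step > skin && (repulsion || hi))
    warning("skin is small relative to the free step; increase skin or reduce dt");

  const int nFrames = nSteps / saveEvery + 1;
  NumericVector frames((R_xlen_t)nFrames * N * 3);
  NumericVector times(nFrames);
  NumericMatrix energies(nFrames, 3);
  NumericMatrix phiFrames(recordPhi && hi ? nFrames : 0, recordPhi && hi ? N : 0);
  double maxPhiSeen = 0.0;

  PairList pl;
  build_lists(xw, radii, mol, L, skin, repulsion, hi, rcutMult, pl);
  std::vector<double> r2buf;
  std::vector<int> actbuf;
  double max_disp2 = 0.0;

  GetRNGstate();
  int frame = 0;
  long nRebuilds = 0;
  double t_phi = 0, t_force = 0, t_update = 0, t_rebuild = 0;
  using clk = std::chrono::steady_clock;
  for (int step = 0; step <= nSteps; ++step) {
    auto tp0 = clk::now();
    // phi and effective D at current positions; the pair pass is split in
    // two phases (distance filter, then lens math on the pairs inside the
    // cutoff) so the independent distance iterations pipeline instead of
    // stalling behind the sqrt/div chain of the lens evaluation
    if (hi) {
      for (int i = 0; i < N; ++i) phi[i] = includeSelf ? vol[i] : 0.0;
      const int np = pl.pi.size();
      const double PI12 = M_PI / 12.0;
      if ((int)r2buf.size() < np) { r2buf.resize(np); actbuf.resize(np); }
      // phase 1: distances and cutoff filter (independent iterations that
      // pipeline well); phase 2: lens math only on the pairs inside
      int na = 0;
      for (int p = 0; p < np; ++p) {
        const int i = pl.pi[p], j = pl.pj[p];
        const double dx = mi_wrapped(xw[3 * i] - xw[3 * j], L, halfL);
        const double dy = mi_wrapped(xw[3 * i + 1] - xw[3 * j + 1], L, halfL);
        const double dz = mi_wrapped(xw[3 * i + 2] - xw[3 * j + 2], L, halfL);
        const double r2 = dx * dx + dy * dy + dz * dz;
        r2buf[na] = r2; actbuf[na] = p;
        na += (r2 < pl.cut2max[p]);
      }
      for (int q = 0; q < na; ++q) {
        const int p = actbuf[q];
        const double r2 = r2buf[q];
        const int i = pl.pi[p], j = pl.pj[p];
        const double r = std::sqrt(r2);
        const double inv_r = 1.0 / r;
        const double ai = radii[i], aj = radii[j];
        // both directions evaluated unconditionally and masked: the inside/
        // outside pattern is unpredictable, so selects beat branches here
        const double Aii = Rcut[i] + aj, Wii = aj - Rcut[i];
        const double Ajj = Rcut[j] + ai, Wjj = ai - Rcut[j];
        const double tii = Aii - r, tjj = Ajj - r;
        double addi = (r < Aii)
            ? PI12 * tii * tii * (r2 + 2.0 * Aii * r - 3.0 * Wii * Wii) * inv_r
            : 0.0;
        double addj = (r < Ajj)
            ? PI12 * tjj * tjj * (r2 + 2.0 * Ajj * r - 3.0 * Wjj * Wjj) * inv_r
            : 0.0;
        if (r2 <= Wii * Wii)   // deep containment, rare
          addi = (aj < Rcut[i]) ? vol[j]
                                : (4.0 / 3.0) * M_PI * Rcut[i] * Rcut[i] * Rcut[i];
        if (r2 <= Wjj * Wjj)
          addj = (ai < Rcut[j]) ? vol[i]
                                : (4.0 / 3.0) * M_PI * Rcut[j] * Rcut[j] * Rcut[j];
        phi[i] += addi;
        phi[j] += addj;
      }
      for (int i = 0; i < N; ++i) {
        double f = phi[i] * invBall[i];
        if (f > maxPhiSeen) maxPhiSeen = f;
        if (f > phiMax) f = phiMax;
        phi[i] = f;
        Deff[i] = D0[i] / (1.0 + tok_H(f));
      }
    } else {
      for (int i = 0; i < N; ++i) Deff[i] = D0[i];
    }

    auto tp1 = clk::now();
    t_phi += std::chrono::duration<double>(tp1 - tp0).count();

    // forces at current positions
    std::fill(F.begin(), F.end(), 0.0);
    double Es = 0.0, Eb = 0.0, Er = 0.0;
    if (ks != 0.0) add_stretch(x, bonds, bondL0, ks, Es, F);
    if (g != 0.0) add_bend(x, angles, angleTheta0, g, sinMin, Eb, F);
    if (repulsion) {
      const int nr = pl.i.size();
      for (int p = 0; p < nr; ++p) {
        const int i = pl.i[p], j = pl.j[p];
        const double dx = mi_wrapped(xw[3 * i] - xw[3 * j], L, halfL);
        const double dy = mi_wrapped(xw[3 * i + 1] - xw[3 * j + 1], L, halfL);
        const double dz = mi_wrapped(xw[3 * i + 2] - xw[3 * j + 2], L, halfL);
        const double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= pl.sigma2[p]) continue;
        const double r = std::sqrt(r2);
        if (r < 1e-12)
          stop("coincident spheres of different proteins: repulsion direction undefined");
        const double ov = std::sqrt(pl.sigma2[p]) - r;
        Er += kr * ov * ov;
        const double fpref = 2.0 * kr * ov / r;
        F[3 * i] += fpref * dx; F[3 * i + 1] += fpref * dy; F[3 * i + 2] += fpref * dz;
        F[3 * j] -= fpref * dx; F[3 * j + 1] -= fpref * dy; F[3 * j + 2] -= fpref * dz;
      }
    }

    auto tp2 = clk::now();
    t_force += std::chrono::duration<double>(tp2 - tp1).count();

    // record frame (positions/energies/phi are those of the current step,
    // i.e. frame 0 is the initial state)
    if (step % saveEvery == 0) {
      times[frame] = step * dt;
      for (int i = 0; i < N; ++i)
        for (int c = 0; c < 3; ++c)
          frames[(R_xlen_t)frame + (R_xlen_t)nFrames * (i + (R_xlen_t)N * c)] =
              x[3 * i + c];
      energies(frame, 0) = Es;
      energies(frame, 1) = Eb;
      energies(frame, 2) = Er;
      if (recordPhi && hi)
        for (int i = 0; i < N; ++i) phiFrames(frame, i) = phi[i];
      ++frame;
      if (verbose && nSteps >= 10 && step % (nSteps / 10) == 0)
        Rcpp::Rcout << "step " << step << "/" << nSteps
                    << "  t = " << step * dt << " ns"
                    << "  E = " << Es + Eb + Er << " kcal/mol"
                    << "  max phi seen = " << maxPhiSeen << "\n";
    }
    if (step == nSteps) break;

    // Ermak-McCammon update; noise draws are taken for every sphere in a
    // fixed order so the stream is identical across HI / freeze settings
    bool rebuild = false;
    for (int i = 0; i < N; ++i) {
      const double z0 = norm_rand(), z1 = norm_rand(), z2 = norm_rand();
      if (frozen[i]) continue;
      const double D = Deff[i];
      const double drift = D * dt / kBT;
      const double sd = noiseScale * std::sqrt(2.0 * D * dt);
      const double dr0 = drift * F[3 * i + 0] + sd * z0;
      const double dr1 = drift * F[3 * i + 1] + sd * z1;
      const double dr2 = drift * F[3 * i + 2] + sd * z2;
      const double step2 = dr0 * dr0 + dr1 * dr1 + dr2 * dr2;
      if (!R_FINITE(step2) || step2 > max_step * max_step) {
        PutRNGstate();
        stop("unstable step: sphere %d moved %.3g A at step %d; reduce dt or relax the configuration",
             i + 1, std::sqrt(step2), step + 1);
      }
      x[3 * i + 0] += dr0; x[3 * i + 1] += dr1; x[3 * i + 2] += dr2;
      for (int c = 0; c < 3; ++c)
        xw[3 * i + c] = x[3 * i + c] - L * std::floor(x[3 * i + c] * invL);
      disp[3 * i + 0] += dr0; disp[3 * i + 1] += dr1; disp[3 * i + 2] += dr2;
      const double d2 = disp[3 * i + 0] * disp[3 * i + 0] +
                        disp[3 * i + 1] * disp[3 * i + 1] +
                        disp[3 * i + 2] * disp[3 * i + 2];
      if (d2 > max_disp2) max_disp2 = d2;
    }
    auto tp3 = clk::now();
    t_update += std::chrono::duration<double>(tp3 - tp2).count();
    if ((repulsion || hi) && max_disp2 > half_skin * half_skin) rebuild = true;
    if (rebuild) {
      build_lists(xw, radii, mol, L, skin, repulsion, hi, rcutMult, pl);
      std::fill(disp.begin(), disp.end(), 0.0);
      max_disp2 = 0.0;
      ++nRebuilds;
      t_rebuild += std::chrono::duration<double>(clk::now() - tp3).count();
    }
  }
  PutRNGstate();

  frames.attr("dim") = IntegerVector::create(nFrames, N, 3);
  List out = List::create(
      _["frames"] = frames, _["times"] = times, _["energies"] = energies,
      _["maxPhi"] = maxPhiSeen,
      _["timing"] = NumericVector::create(
          _["phi"] = t_phi, _["force"] = t_force, _["update"] = t_update,
          _["rebuild"] = t_rebuild, _["nRebuilds"] = (double)nRebuilds));
  if (recordPhi && hi) out["phiFrames"] = phiFrames;
  return out;
}

// Steepest descent on the repulsive energy, used to relax freshly packed
// boxes until no inter-protein overlap exceeds tol. Molecules are moved as
// rigid bodies (translated by their net repulsive force) so the internal
// reference geometry is preserved exactly.
// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos0, NumericVector radii, IntegerVector mol,
               double L, double kr, int maxIter, double tol, double maxMove) {
  const int N = pos0.nrow();
  int nMol = 0;
  for (int i = 0; i < N; ++i) if (mol[i] + 1 > nMol) nMol = mol[i] + 1;
  std::vector<double> x(3 * N), Fm(3 * nMol);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos0(i, c);
  double maxOv = 0.0;
  int it = 0;
  for (it = 0; it < maxIter; ++it) {
    std::fill(Fm.begin(), Fm.end(), 0.0);
    maxOv = 0.0;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (mol[i] == mol[j]) continue;
        double d[3];
        double r2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          d[c] = min_image1(x[3 * i + c] - x[3 * j + c], L);
          r2 += d[c] * d[c];
        }
        const double s = radii[i] + radii[j];
        if (r2 >= s * s) continue;
        const double r = std::sqrt(r2);
        double ov = s - r;
        if (ov > maxOv) maxOv = ov;
        if (r < 1e-9) continue;  // coincident centers: no direction
        const double fpref = 2.0 * kr * ov / r;
        for (int c = 0; c < 3; ++c) {
          Fm[3 * mol[i] + c] += fpref * d[c];
          Fm[3 * mol[j] + c] -= fpref * d[c];
        }
      }
    if (maxOv <= tol) break;
    double fmax = 0.0;
    for (int m = 0; m < nMol; ++m) {
      const double f2 = Fm[3 * m] * Fm[3 * m] + Fm[3 * m + 1] * Fm[3 * m + 1] +
                        Fm[3 * m + 2] * Fm[3 * m + 2];
      if (f2 > fmax) fmax = f2;
    }
    fmax = std::sqrt(fmax);
    if (fmax < 1e-14) break;
    const double scale = std::min(maxMove, 0.5 * maxOv) / fmax;
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c) x[3 * i + c] += scale * Fm[3 * mol[i] + c];
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = x[3 * i + c];
  return List::create(_["positions"] = out, _["converged"] = (maxOv <= tol),
                      _["maxOverlap"] = maxOv, _["iterations"] = it);
}
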