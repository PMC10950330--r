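// Langevin dynamics for the chromosome copolymer model.
//
// Chain of N loci: FENE bonds between consecutive loci, Lennard-Jones
// attraction between non-bonded pairs with a well depth chosen by the
// (A/B, A/B) types, and harmonic restraints on CTCF loop-anchor pairs.
// Integration is BAOAB Langevin splitting. The push-off phase is a capped
// steepest descent on the soft force field (FENE + WCA repulsion + loop
// restraints): it removes overlaps and reels the anchored pairs toward
// their rest separation quasi-statically before any dynamics runs.
//
// RNG: mt19937_64 + explicit Box-Muller so trajectories are bit-identical
// across platforms (std::normal_distribution is implementation-defined).

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Gauss {
  std::mt19937_64 eng;
  bool have_spare = false;
  double spare = 0.0;
  explicit Gauss(uint64_t seed) : eng(seed) {}
  double unif() {  // in (0,1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {  // Marsaglia polar; deterministic for a given seed
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

struct Pair { int i, j; double eps; };

// Verlet neighbor list over non-bonded pairs (|i-j| >= 2) within rc + skin;
// the pair's LJ well depth is cached at build time.
struct NeighborList {
  double rlist2, skin_half;
  std::vector<Pair> pairs;
  std::vector<double> xref, yref, zref;
  NeighborList(double rc, double skin)
      : rlist2((rc + skin) * (rc + skin)), skin_half(skin * 0.5) {}
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, const std::vector<int>& type,
             const double eps_pair[2][2]) {
    int n = (int)x.size();
    pairs.clear();
    for (int i = 0; i < n - 2; ++i)
      for (int j = i + 2; j < n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        if (dx * dx + dy * dy + dz * dz < rlist2)
          pairs.push_back({i, j, eps_pair[type[i]][type[j]]});
      }
    xref = x; yref = y; zref = z;
  }
  bool stale(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z) const {
    double m2 = skin_half * skin_half;
    for (size_t i = 0; i < x.size(); ++i) {
      double dx = x[i] - xref[i], dy = y[i] - yref[i], dz = z[i] - zref[i];
      if (dx * dx + dy * dy + dz * dz > m2) return true;
    }
    return false;
  }
};

}  // namespace

// [[Rcpp::export(name = ".ccm_run_cpp")]]
List ccm_run_cpp(NumericMatrix x0, IntegerVector type_r,
                 IntegerMatrix anchors_r,
                 double k_fene, double r0_fene,
                 double eps_aa, double eps_bb, double eps_ab,
                 double sigma, double rc,
                 double k_h, double r0_h,
                 double zeta, double mass, double kbt,
                 double dt_soft, int n_soft,
                 double dt_main, int n_equil, int n_prod,
                 int sample_every, double max_move_soft,
                 double seed) {
  const int n = x0.nrow();
  const int na = anchors_r.nrow();
  std::vector<int> type(n);
  for (int i = 0; i < n; ++i) type[i] = type_r[i];
  std::vector<int> anch_p(na), anch_q(na);
  for (int a = 0; a < na; ++a) {
    anch_p[a] = anchors_r(a, 0) - 1;
    anch_q[a] = anchors_r(a, 1) - 1;
  }
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<double> fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = x0(i, 0); y[i] = x0(i, 1); z[i] = x0(i, 2); }

  Gauss rng((uint64_t)seed);
  // Maxwell-Boltzmann start
  double vs = std::sqrt(kbt / mass);
  for (int i = 0; i < n; ++i) {
    vx[i] = vs * rng.norm(); vy[i] = vs * rng.norm(); vz[i] = vs * rng.norm();
  }

  double eps_pair[2][2] = {{eps_aa, eps_ab}, {eps_ab, eps_bb}};
  const double r02 = r0_fene * r0_fene;
  const double rc2 = rc * rc;
  const double rwca = std::pow(2.0, 1.0 / 6.0) * sigma;
  const double rwca2 = rwca * rwca;
  NeighborList nl(std::max(rc, rwca), 0.4 * sigma);

  int step_index = 0;
  double max_force = 0.0;

  auto forces = [&](bool soft_phase) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    max_force = 0.0;
    // FENE bonds (consecutive loci); diverges at r0 -> hard error upstream
    for (int i = 0; i < n - 1; ++i) {
      double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= r02) {
        return false;  // bond overstretched
      }
      double fr = -k_fene / (1.0 - r2 / r02);  // dU/dr / r
      fx[i] -= fr * dx; fy[i] -= fr * dy; fz[i] -= fr * dz;
      fx[i + 1] += fr * dx; fy[i + 1] += fr * dy; fz[i + 1] += fr * dz;
      // soft phase adds WCA between bonded neighbours too, to resolve overlap
      if (soft_phase && r2 < rwca2 && r2 > 0) {
        double inv2 = sigma * sigma / r2;
        double inv6 = inv2 * inv2 * inv2;
        double fw = 24.0 * (2.0 * inv6 * inv6 - inv6) / r2;
        fx[i] -= fw * dx; fy[i] -= fw * dy; fz[i] -= fw * dz;
        fx[i + 1] += fw * dx; fy[i + 1] += fw * dy; fz[i + 1] += fw * dz;
      }
    }
    // non-bonded pairs
    for (const Pair& p : nl.pairs) {
      double dx = x[p.i] - x[p.j], dy = y[p.i] - y[p.j], dz = z[p.i] - z[p.j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= 0) continue;
      double fw = 0.0;
      if (soft_phase) {
        if (r2 < rwca2) {
          double inv2 = sigma * sigma / r2;
          double inv6 = inv2 * inv2 * inv2;
          fw = 24.0 * (2.0 * inv6 * inv6 - inv6) / r2;
        }
      } else if (r2 < rc2) {
        double inv2 = sigma * sigma / r2;
        double inv6 = inv2 * inv2 * inv2;
        fw = 24.0 * p.eps * (2.0 * inv6 * inv6 - inv6) / r2;
      }
      if (fw != 0.0) {
        fx[p.i] += fw * dx; fy[p.i] += fw * dy; fz[p.i] += fw * dz;
        fx[p.j] -= fw * dx; fy[p.j] -= fw * dy; fz[p.j] -= fw * dz;
      }
    }
    // harmonic loop restraints
    for (int a = 0; a < na; ++a) {
      int i = anch_p[a], j = anch_q[a];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r <= 0) continue;
      double fr = -2.0 * k_h * (r - r0_h) / r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
    return true;
  };

  auto compute_max_force = [&]() {
    double m2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double f2 = fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i];
      if (f2 > m2) m2 = f2;
    }
    max_force = std::sqrt(m2);
  };

  int n_frames = (n_prod > 0 && sample_every > 0) ? n_prod / sample_every : 0;
  NumericVector frames(std::max(n_frames, 0) * n * 3);
  frames.attr("dim") = IntegerVector::create(n_frames, n, 3);
  int frame = 0;
  double ke_sum = 0.0;
  long ke_count = 0;

  nl.build(x, y, z, type, eps_pair);
  if (!forces(true))
    stop("FENE bond overstretched in initial conformation");
  compute_max_force();

  auto run_phase = [&](bool soft_phase, double dt, long nsteps,
                       bool sample, double cap) {
    (void)soft_phase;
    double c1 = std::exp(-(zeta / mass) * dt);
    double c2 = std::sqrt((1.0 - c1 * c1) * kbt / mass);
    double vmax = (cap > 0) ? cap / dt : -1.0;
    for (long s = 0; s < nsteps; ++s) {
      ++step_index;
      for (int i = 0; i < n; ++i) {  // B: half kick
        vx[i] += 0.5 * dt * fx[i] / mass;
        vy[i] += 0.5 * dt * fy[i] / mass;
        vz[i] += 0.5 * dt * fz[i] / mass;
      }
      auto drift = [&](double h) {
        for (int i = 0; i < n; ++i) {
          double ddx = h * vx[i], ddy = h * vy[i], ddz = h * vz[i];
          if (cap > 0) {
            double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
            if (d > cap) { double f = cap / d; ddx *= f; ddy *= f; ddz *= f; }
          }
          x[i] += ddx; y[i] += ddy; z[i] += ddz;
        }
      };
      drift(0.5 * dt);  // A
      for (int i = 0; i < n; ++i) {  // O
        vx[i] = c1 * vx[i] + c2 * rng.norm();
        vy[i] = c1 * vy[i] + c2 * rng.norm();
        vz[i] = c1 * vz[i] + c2 * rng.norm();
      }
      if (vmax > 0) {  // soft phase: clamp speeds so strain distributes
        for (int i = 0; i < n; ++i) {
          double sp = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i] +
                                vz[i] * vz[i]);
          if (sp > vmax) {
            double f = vmax / sp;
            vx[i] *= f; vy[i] *= f; vz[i] *= f;
          }
        }
      }
      drift(0.5 * dt);  // A
      if (nl.stale(x, y, z)) nl.build(x, y, z, type, eps_pair);
      if (!forces(soft_phase)) {
        compute_max_force();
        stop("FENE bond overstretched at step %d (max force %g)",
             step_index, max_force);
      }
      for (int i = 0; i < n; ++i) {  // B: half kick
        vx[i] += 0.5 * dt * fx[i] / mass;
        vy[i] += 0.5 * dt * fy[i] / mass;
        vz[i] += 0.5 * dt * fz[i] / mass;
      }
      if (!std::isfinite(x[0]) || !std::isfinite(fx[0]))
        stop("non-finite coordinates at step %d", step_index);
      if (sample) {
        double ke = 0.0;
        for (int i = 0; i < n; ++i)
          ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
        ke_sum += 0.5 * mass * ke;
        ++ke_count;
        if (sample_every > 0 && (s + 1) % sample_every == 0 &&
            frame < n_frames) {
          for (int i = 0; i < n; ++i) {
            frames[frame + (long)n_frames * i] = x[i];
            frames[frame + (long)n_frames * (i + (long)n)] = y[i];
            frames[frame + (long)n_frames * (i + 2L * n)] = z[i];
          }
          ++frame;
        }
      }
      if ((s & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    }
  };

  // Phase 1 (push-off): capped steepest descent on the soft force field
  // (FENE + WCA + loop restraints). Quasi-static by construction -- no
  // momentum can accumulate while stiff loop springs reel distant anchors
  // in -- and the displacement cap keeps bonds inside the FENE domain.
  for (long s = 0; s < (long)n_soft; ++s) {
    double h = dt_soft;
    if (max_force * h > max_move_soft && max_force > 0)
      h = max_move_soft / max_force;
    for (int i = 0; i < n; ++i) {
      x[i] += h * fx[i]; y[i] += h * fy[i]; z[i] += h * fz[i];
    }
    if (nl.stale(x, y, z)) nl.build(x, y, z, type, eps_pair);
    ++step_index;
    if (!forces(true))
      stop("FENE bond overstretched during push-off at step %d", step_index);
    compute_max_force();
    if ((s & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  // fresh thermal velocities for the dynamics
  for (int i = 0; i < n; ++i) {
    vx[i] = vs * rng.norm(); vy[i] = vs * rng.norm(); vz[i] = vs * rng.norm();
  }
  nl.build(x, y, z, type, eps_pair);
  if (!forces(false))
    stop("FENE bond overstretched entering main phase");
  compute_max_force();
  run_phase(false, dt_main, n_equil, false, -1.0);
  run_phase(false, dt_main, n_prod, true, -1.0);

  NumericMatrix xf(n, 3);
  for (int i = 0; i < n; ++i) { xf(i, 0) = x[i]; xf(i, 1) = y[i]; xf(i, 2) = z[i]; }
  double kin_temp = ke_count ? (2.0 / 3.0) * ke_sum / (ke_count * n) : NA_REAL;
  return List::create(_["frames"] = frames, _["final"] = xf,
                      _["kinetic_temperature"] = kin_temp,
                      _["n_frames"] = frame);
}
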