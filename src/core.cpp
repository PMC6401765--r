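// Compiled core: force field, Verlet-list neighbour search, leap-frog NVT
// integrator, and the structure-factor double sum.  All quantities are in
// reduced Lennard-Jones units (epsilon = sigma = m = kB = 1); the chain is a
// single linear molecule in unbounded space, decorated with an infinite
// square lattice of posts parallel to x (coordinates are never wrapped).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double RC  = 1.122462048309372981;   // 2^(1/6): WCA cutoff
static const double RC2 = RC * RC;

struct Model {
  int N;
  const double *angk;      // N-2 bending prefactors b*kT (may be null if N<3)
  double kappa, Ro2;       // FENE spring constant, Ro^2
  bool pair_wca;           // false => phantom chain (no bead-bead WCA)
  bool has_array;
  double Sp, Dp;           // lattice constant, bare post diameter
};

struct Terms {
  double wca, fene, bend, post;
  int bad_bond, bad_bead;  // 0-based index of first failure, -1 if none
  Terms() : wca(0), fene(0), bend(0), post(0), bad_bond(-1), bad_bead(-1) {}
  double total() const { return wca + fene + bend + post; }
};

// shifted Lennard-Jones repulsion; r2 < RC2 assumed
static inline double wca_u(double r2, double &f_over_r) {
  double inv2 = 1.0 / r2;
  double inv6 = inv2 * inv2 * inv2;
  f_over_r = 24.0 * (2.0 * inv6 * inv6 - inv6) * inv2;
  return 4.0 * (inv6 * inv6 - inv6) + 1.0;
}

// Verlet neighbour list over all bead pairs (bonded pairs included: the
// model applies WCA to bonded beads too).  Rebuilt when cumulative
// displacement could let a pair closer than RC sneak in.
struct NeighbourList {
  double skin, rv2;
  std::vector<int> pairs;        // flattened (i,j), i<j, lexicographic
  std::vector<double> ref;       // positions at last build
  NeighbourList() : skin(0.4) { rv2 = (RC + skin) * (RC + skin); }
  void build(const double *x, int N) {
    pairs.clear();
    ref.assign(x, x + 3 * N);
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
               dz = x[3*i+2] - x[3*j+2];
        if (dx*dx + dy*dy + dz*dz < rv2) { pairs.push_back(i); pairs.push_back(j); }
      }
  }
  // rebuild once two beads could have closed the skin gap: max per-bead
  // displacement since build must stay below skin/2
  bool stale(const double *x, int N) const {
    double lim = 0.25 * skin * skin, mx = 0;
    for (int i = 0; i < N; ++i) {
      double dx = x[3*i] - ref[3*i], dy = x[3*i+1] - ref[3*i+1],
             dz = x[3*i+2] - ref[3*i+2];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > mx) mx = d2;
    }
    return mx > lim;
  }
};

// post contribution for one bead: fold (y,z) into [0,Sp)^2 and sum the
// shifted WCA over the four surrounding post axes (never more than four
// can be in range for a feasible geometry)
static inline void post_term(const Model &m, double y, double z,
                             double &u, double &fy, double &fz, bool &bad) {
  double Sp = m.Sp, R = 0.5 * m.Dp;
  double yy = y - Sp * std::floor(y / Sp);
  double zz = z - Sp * std::floor(z / Sp);
  const double oy[2] = { yy, yy - Sp }, oz[2] = { zz, zz - Sp };
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b) {
      double dy = oy[a], dz = oz[b];
      double r = std::sqrt(dy * dy + dz * dz);
      double s = r - R;
      if (s >= RC) continue;
      if (s <= 0.0 || r == 0.0) { bad = true; return; }
      double fr;                 // dU/ds * (-1) / s
      double u1 = wca_u(s * s, fr);
      u += u1;
      double fmag = fr * s;      // radial force magnitude, repulsive
      fy += fmag * dy / r;
      fz += fmag * dz / r;
    }
}

static void compute_forces(const Model &m, const double *x, double *f,
                           Terms &t, const std::vector<int> *pairs) {
  int N = m.N;
  t = Terms();
  std::fill(f, f + 3 * N, 0.0);

  // WCA pairs: all pairs for the full model; bonded pairs only for the
  // phantom chain (keeps the WCA+FENE bond, drops non-bonded excluded
  // volume)
  if (!m.pair_wca) {
    for (int i = 0; i < N - 1; ++i) {
      int j = i + 1;
      double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
             dz = x[3*i+2] - x[3*j+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= RC2) continue;
      if (r2 == 0.0) { t.bad_bead = i; return; }
      double fr;
      t.wca += wca_u(r2, fr);
      f[3*i] += fr * dx;   f[3*j] -= fr * dx;
      f[3*i+1] += fr * dy; f[3*j+1] -= fr * dy;
      f[3*i+2] += fr * dz; f[3*j+2] -= fr * dz;
    }
  } else {
    if (pairs) {
      for (size_t p = 0; p < pairs->size(); p += 2) {
        int i = (*pairs)[p], j = (*pairs)[p + 1];
        double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
               dz = x[3*i+2] - x[3*j+2];
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 >= RC2) continue;
        if (r2 == 0.0) { t.bad_bead = i; return; }
        double fr;
        t.wca += wca_u(r2, fr);
        f[3*i] += fr * dx;   f[3*j] -= fr * dx;
        f[3*i+1] += fr * dy; f[3*j+1] -= fr * dy;
        f[3*i+2] += fr * dz; f[3*j+2] -= fr * dz;
      }
    } else {
      for (int i = 0; i < N - 1; ++i)
        for (int j = i + 1; j < N; ++j) {
          double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
                 dz = x[3*i+2] - x[3*j+2];
          double r2 = dx*dx + dy*dy + dz*dz;
          if (r2 >= RC2) continue;
          if (r2 == 0.0) { t.bad_bead = i; return; }
          double fr;
          t.wca += wca_u(r2, fr);
          f[3*i] += fr * dx;   f[3*j] -= fr * dx;
          f[3*i+1] += fr * dy; f[3*j+1] -= fr * dy;
          f[3*i+2] += fr * dz; f[3*j+2] -= fr * dz;
        }
    }
  }

  // FENE bonds along the chain
  for (int i = 0; i < N - 1; ++i) {
    double dx = x[3*i] - x[3*(i+1)], dy = x[3*i+1] - x[3*(i+1)+1],
           dz = x[3*i+2] - x[3*(i+1)+2];
    double l2 = dx*dx + dy*dy + dz*dz;
    if (l2 >= m.Ro2) { t.bad_bond = i; return; }
    double q = 1.0 - l2 / m.Ro2;
    t.fene += -0.5 * m.kappa * m.Ro2 * std::log(q);
    double fr = -m.kappa / q;          // attractive spring
    f[3*i] += fr * dx;   f[3*(i+1)] -= fr * dx;
    f[3*i+1] += fr * dy; f[3*(i+1)+1] -= fr * dy;
    f[3*i+2] += fr * dz; f[3*(i+1)+2] -= fr * dz;
  }

  // bending: U = k (1 + cos theta), theta the valence angle at bead i
  for (int a = 0; a + 2 < N; ++a) {
    double k = m.angk ? m.angk[a] : 0.0;
    if (k == 0.0) continue;
    int i0 = a, i1 = a + 1, i2 = a + 2;
    double ux = x[3*i0] - x[3*i1], uy = x[3*i0+1] - x[3*i1+1],
           uz = x[3*i0+2] - x[3*i1+2];
    double vx = x[3*i2] - x[3*i1], vy = x[3*i2+1] - x[3*i1+1],
           vz = x[3*i2+2] - x[3*i1+2];
    double lu2 = ux*ux + uy*uy + uz*uz, lv2 = vx*vx + vy*vy + vz*vz;
    double lu = std::sqrt(lu2), lv = std::sqrt(lv2);
    double dot = ux*vx + uy*vy + uz*vz;
    double ct = dot / (lu * lv);
    t.bend += k * (1.0 + ct);
    // grad wrt u and v of cos(theta)
    double gux = vx / (lu * lv) - ct * ux / lu2;
    double guy = vy / (lu * lv) - ct * uy / lu2;
    double guz = vz / (lu * lv) - ct * uz / lu2;
    double gvx = ux / (lu * lv) - ct * vx / lv2;
    double gvy = uy / (lu * lv) - ct * vy / lv2;
    double gvz = uz / (lu * lv) - ct * vz / lv2;
    f[3*i0]   -= k * gux; f[3*i0+1] -= k * guy; f[3*i0+2] -= k * guz;
    f[3*i2]   -= k * gvx; f[3*i2+1] -= k * gvy; f[3*i2+2] -= k * gvz;
    f[3*i1]   += k * (gux + gvx);
    f[3*i1+1] += k * (guy + gvy);
    f[3*i1+2] += k * (guz + gvz);
  }

  // bead-post interactions (x-invariant: no x force component)
  if (m.has_array) {
    for (int i = 0; i < N; ++i) {
      double u = 0, fy = 0, fz = 0; bool bad = false;
      post_term(m, x[3*i+1], x[3*i+2], u, fy, fz, bad);
      if (bad) { t.bad_bead = i; return; }
      t.post += u;
      f[3*i+1] += fy; f[3*i+2] += fz;
    }
  }
}

static Model make_model(int N, NumericVector angle_k, double kappa, double Ro,
                        bool pair_wca, bool has_array, double Sp, double Dp) {
  Model m;
  m.N = N;
  m.angk = (N >= 3 && angle_k.size() >= N - 2) ? REAL(angle_k) : NULL;
  m.kappa = kappa; m.Ro2 = Ro * Ro;
  m.pair_wca = pair_wca;
  m.has_array = has_array; m.Sp = Sp; m.Dp = Dp;
  return m;
}

// [[Rcpp::export]]
List ef_compute_cpp(NumericMatrix pos, NumericVector angle_k, double kappa,
                    double Ro, bool pair_wca, bool has_array, double Sp,
                    double Dp, std::string neighbour) {
  int N = pos.nrow();
  std::vector<double> x(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = pos(i, d);
  Model m = make_model(N, angle_k, kappa, Ro, pair_wca, has_array, Sp, Dp);
  Terms t;
  if (neighbour == "verlet") {
    NeighbourList nl;
    nl.build(x.data(), N);
    compute_forces(m, x.data(), f.data(), t, &nl.pairs);
  } else {
    compute_forces(m, x.data(), f.data(), t, NULL);
  }
  NumericMatrix forces(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) forces(i, d) = f[3*i+d];
  return List::create(_["wca"] = t.wca, _["fene"] = t.fene,
                      _["bend"] = t.bend, _["post"] = t.post,
                      _["energy"] = t.total(), _["forces"] = forces,
                      _["bad_bond"] = t.bad_bond + 1,
                      _["bad_bead"] = t.bad_bead + 1);
}

// Leap-frog NVT integrator.  Velocities enter and leave in the half-step
// convention v(t - dt/2); sampled kinetic energies use the on-step
// interpolation v(t) = (v(t-dt/2) + v(t+dt/2)) / 2.
// thermostat: 0 = none (NVE), 1 = Langevin (friction gamma, R's RNG),
//             2 = Nose-Hoover (relaxation time tauT).
// [[Rcpp::export]]
List md_run_cpp(NumericMatrix pos, NumericMatrix vel, NumericVector angle_k,
                double kappa, double Ro, bool pair_wca, bool has_array,
                double Sp, double Dp, double dt, double Temp, int thermostat,
                double gamma, double tauT, double t0, int n_equil, int n_prod,
                int sample_every, bool use_verlet) {
  int N = pos.nrow();
  std::vector<double> x(3 * N), v(3 * N), f(3 * N), vn(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) { x[3*i+d] = pos(i, d); v[3*i+d] = vel(i, d); }
  Model m = make_model(N, angle_k, kappa, Ro, pair_wca, has_array, Sp, Dp);
  NeighbourList nl;
  bool verlet = use_verlet && m.pair_wca;
  if (verlet) nl.build(x.data(), N);

  int n_total = n_equil + n_prod;
  int nf = n_prod > 0 ? (n_prod - 1) / sample_every + 1 : 0;
  NumericVector frames(nf > 0 ? (R_xlen_t)3 * N * nf : 0);
  NumericVector times(nf), pe(nf), ke(nf);

  double ndof = 3.0 * N;
  double Q = ndof * Temp * tauT * tauT;   // Nose-Hoover inertia
  double zeta = 0.0;
  double noise = std::sqrt(2.0 * gamma * Temp * dt);
  Terms t;
  compute_forces(m, x.data(), f.data(), t, verlet ? &nl.pairs : NULL);
  if (t.bad_bond >= 0 || t.bad_bead >= 0)
    stop("invalid initial configuration (bond %d / bead %d)",
         t.bad_bond + 1, t.bad_bead + 1);

  int iframe = 0;
  for (int step = 0; step < n_total; ++step) {
    // half-step velocity update
    if (thermostat == 1) {
      for (int i = 0; i < 3 * N; ++i)
        vn[i] = v[i] + dt * (f[i] - gamma * v[i]) + noise * norm_rand();
    } else if (thermostat == 2) {
      double c1 = 1.0 - 0.5 * dt * zeta, c2 = 1.0 / (1.0 + 0.5 * dt * zeta);
      double ke2 = 0;
      for (int i = 0; i < 3 * N; ++i) {
        vn[i] = (v[i] * c1 + dt * f[i]) * c2;
        ke2 += vn[i] * vn[i];
      }
      zeta += dt * (ke2 - ndof * Temp) / Q;
    } else {
      for (int i = 0; i < 3 * N; ++i) vn[i] = v[i] + dt * f[i];
    }

    // sample the state at time t (positions x, energies at x, on-step KE)
    if (step >= n_equil && (step - n_equil) % sample_every == 0) {
      double k2 = 0;
      for (int i = 0; i < 3 * N; ++i) {
        double von = 0.5 * (v[i] + vn[i]);
        k2 += von * von;
      }
      double *dst = REAL(frames) + (R_xlen_t)3 * N * iframe;
      std::copy(x.begin(), x.end(), dst);
      times[iframe] = t0 + step * dt;
      pe[iframe] = t.total();
      ke[iframe] = 0.5 * k2;
      ++iframe;
    }

    for (int i = 0; i < 3 * N; ++i) { x[i] += dt * vn[i]; v[i] = vn[i]; }

    if (verlet && nl.stale(x.data(), N)) nl.build(x.data(), N);
    compute_forces(m, x.data(), f.data(), t, verlet ? &nl.pairs : NULL);
    if (t.bad_bond >= 0)
      stop("bond overstretch (l >= R_o) at step %d, bond %d: aborting",
           step + 1, t.bad_bond + 1);
    if (t.bad_bead >= 0)
      stop("bead overlap (pair or post) at step %d, bead %d: aborting",
           step + 1, t.bad_bead + 1);
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix posF(N, 3), velF(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) { posF(i, d) = x[3*i+d]; velF(i, d) = v[3*i+d]; }
  if (nf > 0) frames.attr("dim") = IntegerVector::create(3, N, nf);
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["pe"] = pe, _["ke"] = ke,
                      _["pos"] = posF, _["vel"] = velF, _["zeta"] = zeta,
                      _["time"] = t0 + n_total * dt, _["n_frames"] = nf);
}

static inline double sinc(double u) {
  return (std::fabs(u) < 1e-8) ? 1.0 - u * u / 6.0 : std::sin(u) / u;
}

// Direct double sum of the single-chain structure factor
// S(q) = <sum_ij sinc(q r_ij)> / n^2 over the beads in idx (0-based)
// frames: 3 x N x nf array as produced by md_run_cpp
// [[Rcpp::export]]
NumericVector sq_direct_cpp(NumericVector frames, IntegerVector idx,
                            NumericVector q) {
  IntegerVector dim = frames.attr("dim");
  int N = dim[1], nf = dim[2], n = idx.size(), nq = q.size();
  NumericVector S(nq);
  const double *F = REAL(frames);
  std::vector<double> r; r.reserve((size_t)n * (n - 1) / 2);
  for (int fidx = 0; fidx < nf; ++fidx) {
    const double *X = F + (R_xlen_t)3 * N * fidx;
    r.clear();
    for (int a = 0; a < n - 1; ++a)
      for (int b = a + 1; b < n; ++b) {
        int i = idx[a], j = idx[b];
        double dx = X[3*i] - X[3*j], dy = X[3*i+1] - X[3*j+1],
               dz = X[3*i+2] - X[3*j+2];
        r.push_back(std::sqrt(dx*dx + dy*dy + dz*dz));
      }
    for (int k = 0; k < nq; ++k) {
      double s = 0;
      for (size_t p = 0; p < r.size(); ++p) s += sinc(q[k] * r[p]);
      S[k] += (n + 2.0 * s) / ((double)n * n);
    }
  }
  for (int k = 0; k < nq; ++k) S[k] /= nf;
  return S;
}

// Histogram-accelerated evaluation: pair distances binned at resolution dr
// (midpoint rule), then one pass over bins per q value.
// [[Rcpp::export]]
NumericVector sq_hist_cpp(NumericVector frames, IntegerVector idx,
                          NumericVector q, double dr) {
  IntegerVector dim = frames.attr("dim");
  int N = dim[1], nf = dim[2], n = idx.size(), nq = q.size();
  const double *F = REAL(frames);
  double rmax = 0;
  std::vector<double> rr;
  rr.reserve((size_t)nf * n * (n - 1) / 2);
  for (int fidx = 0; fidx < nf; ++fidx) {
    const double *X = F + (R_xlen_t)3 * N * fidx;
    for (int a = 0; a < n - 1; ++a)
      for (int b = a + 1; b < n; ++b) {
        int i = idx[a], j = idx[b];
        double dx = X[3*i] - X[3*j], dy = X[3*i+1] - X[3*j+1],
               dz = X[3*i+2] - X[3*j+2];
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        rr.push_back(r);
        rmax = std::max(rmax, r);
      }
  }
  int nb = (int)(rmax / dr) + 2;
  std::vector<double> hist(nb, 0.0);
  for (size_t p = 0; p < rr.size(); ++p) hist[(int)(rr[p] / dr)] += 1.0;
  NumericVector S(nq);
  for (int k = 0; k < nq; ++k) {
    double s = 0;
    for (int bbin = 0; bbin < nb; ++bbin) {
      if (hist[bbin] == 0) continue;
      s += hist[bbin] * sinc(q[k] * (bbin + 0.5) * dr);
    }
    S[k] = (n + 2.0 * s / nf) / ((double)n * n);
  }
  return S;
}
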