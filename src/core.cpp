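// Monte Carlo cores: EPBD lattice Metropolis sampler and rigid base-pair
// chain generation with closure-observable accumulation.
//
// All randomness goes through R's RNG (unif_rand/norm_rand) so that results
// are reproducible with set.seed() on the R side. Draw order is part of the
// package contract and is documented in the R wrappers:
//   chain MC, per chain: hinge uniforms for every step (only when any opening
//   probability is positive), then tilt, roll, twist normals for each step.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

typedef double mat3[3][3];

// R = Rz(a) * Ry(b) * Rz(c)
static inline void rot_zyz(double a, double b, double c, mat3 R) {
  const double ca = std::cos(a), sa = std::sin(a);
  const double cb = std::cos(b), sb = std::sin(b);
  const double cc = std::cos(c), sc = std::sin(c);
  R[0][0] = ca * cb * cc - sa * sc;
  R[0][1] = -ca * cb * sc - sa * cc;
  R[0][2] = ca * sb;
  R[1][0] = sa * cb * cc + ca * sc;
  R[1][1] = -sa * cb * sc + ca * cc;
  R[1][2] = sa * sb;
  R[2][0] = -sb * cc;
  R[2][1] = sb * sc;
  R[2][2] = cb;
}

static inline void matmul3(const mat3 A, const mat3 B, mat3 C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[i][j] = A[i][0] * B[0][j] + A[i][1] * B[1][j] + A[i][2] * B[2][j];
}

static inline void matcopy3(const mat3 A, mat3 B) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) B[i][j] = A[i][j];
}

// One Newton step toward the nearest orthogonal matrix: R <- R (3I - R^T R)/2.
// Composition drift per step is ~1e-16, so a single step every 64 compositions
// keeps the triad orthonormal to well below 1e-12.
static inline void reorthogonalize(mat3 R) {
  mat3 G;  // R^T R
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      G[i][j] = R[0][i] * R[0][j] + R[1][i] * R[1][j] + R[2][i] * R[2][j];
  mat3 H;  // (3I - G)/2
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      H[i][j] = (i == j ? 1.5 : 0.0) - 0.5 * G[i][j];
  mat3 Rn;
  matmul3(R, H, Rn);
  matcopy3(Rn, R);
}

// R = Rz(a) * Ry(b) * Rz(c) from precomputed sines/cosines
static inline void rot_zyz_cs(double ca, double sa, double cb, double sb,
                              double cc, double sc, mat3 R) {
  R[0][0] = ca * cb * cc - sa * sc;
  R[0][1] = -ca * cb * sc - sa * cc;
  R[0][2] = ca * sb;
  R[1][0] = sa * cb * cc + ca * sc;
  R[1][1] = -sa * cb * sc + ca * cc;
  R[1][2] = sa * sb;
  R[2][0] = -sb * cc;
  R[2][1] = sb * sc;
  R[2][2] = cb;
}

// Apply one base-pair step (mid-step convention) to frame (R, o).
// Angles in radians, displacements in Angstrom. Equivalent to composing
// Rz(w/2 - phi) Ry(gamma) Rz(w/2 + phi) with the translation taken in the
// half-rotated mid-step frame Rz(w/2 - phi) Ry(gamma/2) Rz(phi), where
// gamma = sqrt(tilt^2 + roll^2) and phi = atan2(tilt, roll); written with
// half-angle identities so only four trig evaluations are needed per step.
static inline void apply_step(mat3 R, double o[3], double tilt, double roll,
                              double twist, double shift, double slide,
                              double rise) {
  const double gam = std::sqrt(tilt * tilt + roll * roll);
  double cphi = 1.0, sphi = 0.0;
  if (gam > 0.0) { cphi = roll / gam; sphi = tilt / gam; }
  const double cg2 = std::cos(0.5 * gam), sg2 = std::sin(0.5 * gam);
  const double cg = 1.0 - 2.0 * sg2 * sg2;   // cos(gamma)
  const double sg = 2.0 * sg2 * cg2;         // sin(gamma)
  const double cw2 = std::cos(0.5 * twist), sw2 = std::sin(0.5 * twist);
  // a = twist/2 - phi, c = twist/2 + phi
  const double ca = cw2 * cphi + sw2 * sphi, sa = sw2 * cphi - cw2 * sphi;
  const double cc = cw2 * cphi - sw2 * sphi, sc = sw2 * cphi + cw2 * sphi;
  mat3 T, M;
  rot_zyz_cs(ca, sa, cg, sg, cc, sc, T);
  rot_zyz_cs(ca, sa, cg2, sg2, cphi, sphi, M);
  // translation expressed in the mid-step frame, then mapped to world
  const double dl[3] = {shift, slide, rise};
  double dm[3], dw[3];
  for (int i = 0; i < 3; ++i)
    dm[i] = M[i][0] * dl[0] + M[i][1] * dl[1] + M[i][2] * dl[2];
  for (int i = 0; i < 3; ++i)
    dw[i] = R[i][0] * dm[0] + R[i][1] * dm[1] + R[i][2] * dm[2];
  for (int i = 0; i < 3; ++i) o[i] += dw[i];
  mat3 Rn;
  matmul3(R, T, Rn);
  matcopy3(Rn, R);
}

// Closure observables of a frame relative to the identity start frame.
static inline void observables(const mat3 R, const double o[3], double &r,
                               double &cosg, double &cosp) {
  r = std::sqrt(o[0] * o[0] + o[1] * o[1] + o[2] * o[2]);
  cosg = R[2][2];  // normal(last) . normal(first) = z . R z
  // project last x-axis (column 0) onto the first base-pair plane (z = 0)
  const double px = R[0][0], py = R[1][0];
  const double nrm = std::sqrt(px * px + py * py);
  cosp = (nrm > 1e-12) ? (px / nrm) : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_chain_observables(NumericMatrix steps) {
  mat3 R = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  double o[3] = {0, 0, 0};
  const int n = steps.nrow();
  for (int s = 0; s < n; ++s) {
    apply_step(R, o, steps(s, 0), steps(s, 1), steps(s, 2), steps(s, 3),
               steps(s, 4), steps(s, 5));
    if ((s & 63) == 63) reorthogonalize(R);
  }
  double r, cg, cp;
  observables(R, o, r, cg, cp);
  return NumericVector::create(r, cg, cp);
}

// Generate n_chains chains and accumulate nested closure counts.
// theta0: n_steps x 6 equilibrium step parameters (tilt, roll, twist in rad;
// shift, slide, rise in Angstrom). p_open: per-step single-strand probability
// (probability of the base pair the step enters being open).
// [[Rcpp::export]]
List cpp_closure_counts(NumericMatrix theta0, NumericVector sd_ds,
                        NumericVector sd_ss, NumericVector p_open,
                        double n_chains, double rc, double cg_min,
                        double cp_min, int store_max) {
  const int n_steps = theta0.nrow();
  if (p_open.size() != n_steps) stop("p_open length must equal step count");
  bool has_hinge = false;
  for (int s = 0; s < n_steps; ++s)
    if (p_open[s] > 0.0) { has_hinge = true; break; }

  const long long N = (long long)n_chains;
  long long n_r = 0, n_g = 0, n_p = 0;
  const int ns = store_max > 0 ? (int)std::min((double)store_max, n_chains) : 0;
  NumericMatrix obs(ns, 3);
  std::vector<char> mask(n_steps, 0);

  for (long long c = 0; c < N; ++c) {
    if (has_hinge)
      for (int s = 0; s < n_steps; ++s)
        mask[s] = (unif_rand() <= p_open[s]) ? 1 : 0;
    mat3 R = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    double o[3] = {0, 0, 0};
    for (int s = 0; s < n_steps; ++s) {
      const double *sd = mask[s] ? &sd_ss[0] : &sd_ds[0];
      const double tilt = theta0(s, 0) + sd[0] * norm_rand();
      const double roll = theta0(s, 1) + sd[1] * norm_rand();
      const double twist = theta0(s, 2) + sd[2] * norm_rand();
      apply_step(R, o, tilt, roll, twist, theta0(s, 3), theta0(s, 4),
                 theta0(s, 5));
      if ((s & 63) == 63) reorthogonalize(R);
    }
    double r, cg, cp;
    observables(R, o, r, cg, cp);
    if (c < ns) { obs(c, 0) = r; obs(c, 1) = cg; obs(c, 2) = cp; }
    if (r < rc) {
      ++n_r;
      if (cg > cg_min) {
        ++n_g;
        if (cp > cp_min) ++n_p;
      }
    }
    if ((c & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["n_total"] = (double)N, _["n_r"] = (double)n_r,
                      _["n_gamma"] = (double)n_g, _["n_phi"] = (double)n_p,
                      _["observables"] = obs);
}

// Mean normal-vector autocorrelation <n(0).n(s)> by lag, in n_blocks chain
// blocks (for block standard errors). Returns n_steps x n_blocks matrix.
// [[Rcpp::export]]
NumericMatrix cpp_normal_corr(NumericMatrix theta0, NumericVector sd,
                              int n_chains, int n_blocks) {
  const int n_steps = theta0.nrow();
  NumericMatrix acc(n_steps, n_blocks);
  std::vector<int> cnt(n_blocks, 0);
  for (int c = 0; c < n_chains; ++c) {
    int b = (int)(((double)c * n_blocks) / n_chains);
    if (b >= n_blocks) b = n_blocks - 1;
    ++cnt[b];
    mat3 R = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    double o[3] = {0, 0, 0};
    for (int s = 0; s < n_steps; ++s) {
      const double tilt = theta0(s, 0) + sd[0] * norm_rand();
      const double roll = theta0(s, 1) + sd[1] * norm_rand();
      const double twist = theta0(s, 2) + sd[2] * norm_rand();
      apply_step(R, o, tilt, roll, twist, theta0(s, 3), theta0(s, 4),
                 theta0(s, 5));
      if ((s & 63) == 63) reorthogonalize(R);
      acc(s, b) += R[2][2];
    }
    if ((c & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }
  for (int b = 0; b < n_blocks; ++b)
    if (cnt[b] > 0)
      for (int s = 0; s < n_steps; ++s) acc(s, b) /= cnt[b];
  return acc;
}

// ---------------------------------------------------------------------------
// EPBD lattice
// ---------------------------------------------------------------------------

static inline double morse(double D, double a, double y) {
  const double e = std::exp(-a * y) - 1.0;
  return D * e * e;
}

// Stacking energy of the bond between sites i and j (= neighbours).
static inline double bond_energy(double ui, double uj, double vi, double vj,
                                 double Ku, double Kv, double rho,
                                 double banh) {
  const double du = uj - ui, dv = vj - vi;
  const double yi = ui - vi, yj = uj - vj;
  double w = 0.5 * Ku * du * du + 0.5 * Kv * dv * dv;
  if (rho > 0.0) {
    const double q = std::sqrt(Ku) * du - std::sqrt(Kv) * dv;
    w += 0.25 * rho * std::exp(-banh * (yi + yj)) * q * q;
  }
  return w;
}

// [[Rcpp::export]]
double cpp_total_potential(NumericVector u, NumericVector v, NumericVector D,
                           NumericVector a, NumericVector Ku, NumericVector Kv,
                           double rho, double banh, bool periodic) {
  const int n = u.size();
  double V = 0.0;
  for (int i = 0; i < n; ++i) V += morse(D[i], a[i], u[i] - v[i]);
  const int nb = periodic ? n : (n - 1);
  for (int b = 0; b < nb; ++b) {
    const int j = (b + 1) % n;
    V += bond_energy(u[b], u[j], v[b], v[j], Ku[b], Kv[b], rho, banh);
  }
  return V;
}

// Local energy of site i: its Morse term plus the (at most two) bonds
// touching it. Used for incremental Metropolis updates.
static inline double local_energy(const std::vector<double> &u,
                                  const std::vector<double> &v,
                                  const NumericVector &D,
                                  const NumericVector &a,
                                  const NumericVector &Ku,
                                  const NumericVector &Kv, double rho,
                                  double banh, bool periodic, int i) {
  const int n = (int)u.size();
  double V = morse(D[i], a[i], u[i] - v[i]);
  // bond b connects sites b and (b+1)%n
  const int left = periodic ? ((i - 1 + n) % n) : (i - 1);
  if (left >= 0) {
    const int j = (left + 1) % n;
    V += bond_energy(u[left], u[j], v[left], v[j], Ku[left], Kv[left], rho,
                     banh);
  }
  const int nb = periodic ? n : (n - 1);
  if (i < nb) {
    const int j = (i + 1) % n;
    V += bond_energy(u[i], u[j], v[i], v[j], Ku[i], Kv[i], rho, banh);
  }
  return V;
}

// Metropolis MCMC over strand displacements. One sweep = one single-site
// proposal per site per strand (u sweep then v sweep). Opening statistics
// are collected every `thin` sweeps after `n_equil` equilibration sweeps.
// [[Rcpp::export]]
List cpp_epbd_mcmc(NumericVector u0, NumericVector v0, NumericVector D,
                   NumericVector a, NumericVector Ku, NumericVector Kv,
                   double rho, double banh, double kT, int n_equil,
                   int n_sweeps, int thin, double width, double threshold,
                   double y_max, bool periodic, int n_blocks) {
  const int n = u0.size();
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  long long proposed = 0, accepted = 0;
  NumericMatrix block_counts(n, n_blocks);
  std::vector<long long> counts(n, 0);
  int n_samples = 0;
  const int total_samples = (thin > 0) ? ((n_sweeps + thin - 1) / thin) : 0;

  for (int sweep = 0; sweep < n_equil + n_sweeps; ++sweep) {
    for (int strand = 0; strand < 2; ++strand) {
      std::vector<double> &x = (strand == 0) ? u : v;
      for (int i = 0; i < n; ++i) {
        const double delta = width * (2.0 * unif_rand() - 1.0);
        const double xi_old = x[i];
        const double y_new = (strand == 0)
                                 ? (u[i] + delta - v[i])
                                 : (u[i] - (v[i] + delta));
        ++proposed;
        if (y_new > y_max) continue;  // hard cap on the opening coordinate
        const double e_old =
            local_energy(u, v, D, a, Ku, Kv, rho, banh, periodic, i);
        x[i] = xi_old + delta;
        const double e_new =
            local_energy(u, v, D, a, Ku, Kv, rho, banh, periodic, i);
        const double dV = e_new - e_old;
        if (dV <= 0.0 || unif_rand() < std::exp(-dV / kT)) {
          ++accepted;
        } else {
          x[i] = xi_old;
        }
      }
    }
    if (sweep >= n_equil && thin > 0 && ((sweep - n_equil) % thin == 0)) {
      int b = total_samples > 0
                  ? (int)(((double)n_samples * n_blocks) / total_samples)
                  : 0;
      if (b >= n_blocks) b = n_blocks - 1;
      for (int i = 0; i < n; ++i)
        if (u[i] - v[i] > threshold) {
          ++counts[i];
          block_counts(i, b) += 1.0;
        }
      ++n_samples;
    }
    if ((sweep & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector p(n);
  for (int i = 0; i < n; ++i)
    p[i] = n_samples > 0 ? (double)counts[i] / n_samples : NA_REAL;
  // per-block sample counts for block-mean normalization
  NumericVector bn(n_blocks);
  for (int s = 0; s < n_samples; ++s) {
    int b = (int)(((double)s * n_blocks) / total_samples);
    if (b >= n_blocks) b = n_blocks - 1;
    bn[b] += 1.0;
  }
  return List::create(
      _["p"] = p, _["n_samples"] = n_samples,
      _["block_counts"] = block_counts, _["block_samples"] = bn,
      _["acceptance_rate"] = proposed > 0 ? (double)accepted / proposed : NA_REAL,
      _["u"] = NumericVector(u.begin(), u.end()),
      _["v"] = NumericVector(v.begin(), v.end()));
}
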