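// Bonded-energy, virtual-site, measurement and Metropolis-sampling kernels.
//
// Conventions (enforced by the R wrappers in R/topology.R and R/sampler.R):
//   * coordinates in nm, energies in kJ/mol, angles in RADIANS here;
//   * all particle indices 0-based;
//   * bonds matrix columns:      i, j, r0, k, constrained
//   * angles matrix columns:     i, j, k, form (0 harmonic / 1 quartic),
//                                theta0, kf, c0, c1, c2, c3, c4
//   * dihedrals matrix columns:  i, j, k, l, n, phi0, kphi
//     (one row per cosine term; several rows may share the same quad)
//   * virtual sites passed as parallel lists of constructor indices and
//     weights (weights sum to 1; equal weights encode the cog rule).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GEOM_EPS = 1e-12;

static inline double dist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// angle at j in radians; stops on degenerate geometry
static double angle3(const double* a, const double* b, const double* c) {
  double u[3] = {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
  double v[3] = {c[0] - b[0], c[1] - b[1], c[2] - b[2]};
  double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (nu < GEOM_EPS || nv < GEOM_EPS)
    stop("undefined geometry: coincident coordinates in an angle triple");
  double cs = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (nu * nv);
  if (cs > 1.0) cs = 1.0;
  if (cs < -1.0) cs = -1.0;
  return std::acos(cs);
}

// signed dihedral i-j-k-l in radians, (-pi, pi]
static double dihedral4(const double* a, const double* b,
                        const double* c, const double* d) {
  double b1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double b2[3] = {c[0] - b[0], c[1] - b[1], c[2] - b[2]};
  double b3[3] = {d[0] - c[0], d[1] - c[1], d[2] - c[2]};
  double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1],
                  b1[2] * b2[0] - b1[0] * b2[2],
                  b1[0] * b2[1] - b1[1] * b2[0]};
  double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1],
                  b2[2] * b3[0] - b2[0] * b3[2],
                  b2[0] * b3[1] - b2[1] * b3[0]};
  double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  double nn1 = std::sqrt(n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2]);
  double nn2 = std::sqrt(n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2]);
  if (nb2 < GEOM_EPS || nn1 < GEOM_EPS || nn2 < GEOM_EPS)
    stop("undefined geometry: degenerate dihedral quad");
  double m1[3] = {n1[1] * b2[2] - n1[2] * b2[1],
                  n1[2] * b2[0] - n1[0] * b2[2],
                  n1[0] * b2[1] - n1[1] * b2[0]};
  double x = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double y = (m1[0] * n2[0] + m1[1] * n2[1] + m1[2] * n2[2]) / nb2;
  return std::atan2(y, x);
}

struct Terms {
  NumericMatrix bonds, angles, dihedrals;
  Terms(NumericMatrix b, NumericMatrix a, NumericMatrix d)
      : bonds(b), angles(a), dihedrals(d) {}
};

static double eval_bond(const NumericMatrix& C, const NumericMatrix& B, int t) {
  if (B(t, 4) != 0.0) return 0.0;  // constrained: fixed length, no energy
  int i = (int)B(t, 0), j = (int)B(t, 1);
  double a[3] = {C(i, 0), C(i, 1), C(i, 2)};
  double b[3] = {C(j, 0), C(j, 1), C(j, 2)};
  double d = dist3(a, b) - B(t, 2);
  return 0.5 * B(t, 3) * d * d;
}

static double eval_angle(const NumericMatrix& C, const NumericMatrix& A, int t) {
  int i = (int)A(t, 0), j = (int)A(t, 1), k = (int)A(t, 2);
  double a[3] = {C(i, 0), C(i, 1), C(i, 2)};
  double b[3] = {C(j, 0), C(j, 1), C(j, 2)};
  double c[3] = {C(k, 0), C(k, 1), C(k, 2)};
  double dth = angle3(a, b, c) - A(t, 4);
  if (A(t, 3) == 0.0) return 0.5 * A(t, 5) * dth * dth;
  double e = 0.0, p = 1.0;
  for (int n = 0; n <= 4; ++n) { e += A(t, 6 + n) * p; p *= dth; }
  return e;
}

static double eval_dihedral(const NumericMatrix& C, const NumericMatrix& D, int t) {
  int i = (int)D(t, 0), j = (int)D(t, 1), k = (int)D(t, 2), l = (int)D(t, 3);
  double a[3] = {C(i, 0), C(i, 1), C(i, 2)};
  double b[3] = {C(j, 0), C(j, 1), C(j, 2)};
  double c[3] = {C(k, 0), C(k, 1), C(k, 2)};
  double d[3] = {C(l, 0), C(l, 1), C(l, 2)};
  double phi = dihedral4(a, b, c, d);
  return D(t, 6) * (1.0 + std::cos(D(t, 4) * phi - D(t, 5)));
}

static double total_energy(const NumericMatrix& C, const Terms& T) {
  double e = 0.0;
  for (int t = 0; t < T.bonds.nrow(); ++t) e += eval_bond(C, T.bonds, t);
  for (int t = 0; t < T.angles.nrow(); ++t) e += eval_angle(C, T.angles, t);
  for (int t = 0; t < T.dihedrals.nrow(); ++t) e += eval_dihedral(C, T.dihedrals, t);
  return e;
}

static void place_vsites(NumericMatrix& C, const List& cons, const List& wts,
                         const IntegerVector& sites) {
  for (int s = 0; s < sites.size(); ++s) {
    IntegerVector idx = cons[s];
    NumericVector w = wts[s];
    double x = 0, y = 0, z = 0;
    for (int m = 0; m < idx.size(); ++m) {
      x += w[m] * C(idx[m], 0);
      y += w[m] * C(idx[m], 1);
      z += w[m] * C(idx[m], 2);
    }
    C(sites[s], 0) = x; C(sites[s], 1) = y; C(sites[s], 2) = z;
  }
}

// [[Rcpp::export]]
List cpp_bonded_energy(NumericMatrix coords, NumericMatrix bonds,
                       NumericMatrix angles, NumericMatrix dihedrals) {
  Terms T(bonds, angles, dihedrals);
  NumericVector eb(bonds.nrow()), ea(angles.nrow()), ed(dihedrals.nrow());
  double tot = 0.0;
  for (int t = 0; t < bonds.nrow(); ++t)   { eb[t] = eval_bond(coords, bonds, t);        tot += eb[t]; }
  for (int t = 0; t < angles.nrow(); ++t)  { ea[t] = eval_angle(coords, angles, t);      tot += ea[t]; }
  for (int t = 0; t < dihedrals.nrow(); ++t){ ed[t] = eval_dihedral(coords, dihedrals, t); tot += ed[t]; }
  return List::create(_["total"] = tot, _["bonds"] = eb,
                      _["angles"] = ea, _["dihedrals"] = ed);
}

// [[Rcpp::export]]
NumericMatrix cpp_place_vsites(NumericMatrix coords, IntegerVector sites,
                               List constructors, List weights) {
  NumericMatrix C = clone(coords);
  place_vsites(C, constructors, weights, sites);
  return C;
}

// Per-frame bonded observables for a list of frames: bond lengths (nm),
// angles and dihedrals (radians).
// [[Rcpp::export]]
List cpp_measure(List frames, NumericMatrix bonds, NumericMatrix angles,
                 NumericMatrix dihedrals) {
  int nf = frames.size();
  NumericMatrix mb(nf, bonds.nrow()), ma(nf, angles.nrow()), md(nf, dihedrals.nrow());
  for (int f = 0; f < nf; ++f) {
    NumericMatrix C = frames[f];
    for (int t = 0; t < bonds.nrow(); ++t) {
      int i = (int)bonds(t, 0), j = (int)bonds(t, 1);
      double a[3] = {C(i, 0), C(i, 1), C(i, 2)};
      double b[3] = {C(j, 0), C(j, 1), C(j, 2)};
      mb(f, t) = dist3(a, b);
    }
    for (int t = 0; t < angles.nrow(); ++t) {
      int i = (int)angles(t, 0), j = (int)angles(t, 1), k = (int)angles(t, 2);
      double a[3] = {C(i, 0), C(i, 1), C(i, 2)};
      double b[3] = {C(j, 0), C(j, 1), C(j, 2)};
      double c[3] = {C(k, 0), C(k, 1), C(k, 2)};
      ma(f, t) = angle3(a, b, c);
    }
    for (int t = 0; t < dihedrals.nrow(); ++t) {
      int i = (int)dihedrals(t, 0), j = (int)dihedrals(t, 1);
      int k = (int)dihedrals(t, 2), l = (int)dihedrals(t, 3);
      double a[3] = {C(i, 0), C(i, 1), C(i, 2)};
      double b[3] = {C(j, 0), C(j, 1), C(j, 2)};
      double c[3] = {C(k, 0), C(k, 1), C(k, 2)};
      double d[3] = {C(l, 0), C(l, 1), C(l, 2)};
      md(f, t) = dihedral4(a, b, c, d);
    }
  }
  return List::create(_["bonds"] = mb, _["angles"] = ma, _["dihedrals"] = md);
}

// Single-bead-move Metropolis chain under the bonded potential.
// One "step" = one attempted move of one randomly chosen movable bead.
// cons_partner[i] >= 0 marks a pendant constrained bond: bead i is proposed
// on the sphere of radius cons_r0[i] around its partner (direction
// resampled, length fixed). Uses R's RNG (seed set by the caller).
// During the first `burn_in` steps the move size adapts toward 40%
// acceptance every 500 steps; it is frozen afterwards and burn-in frames
// are not recorded.
// [[Rcpp::export]]
List cpp_sample(NumericMatrix coords0, NumericMatrix bonds, NumericMatrix angles,
                NumericMatrix dihedrals, IntegerVector vs_sites,
                List vs_constructors, List vs_weights, IntegerVector movable,
                IntegerVector cons_partner, NumericVector cons_r0,
                int n_steps, int burn_in, int stride, double beta,
                double sigma0,
                NumericMatrix rot_ref, double rot_k, IntegerVector rot_group) {
  Terms T(bonds, angles, dihedrals);
  NumericMatrix C = clone(coords0);
  place_vsites(C, vs_constructors, vs_weights, vs_sites);

  const bool restrained = rot_group.size() > 0 && rot_k > 0.0;
  auto restraint = [&](const NumericMatrix& X) -> double {
    if (!restrained) return 0.0;
    double e = 0.0;
    for (int m = 0; m < rot_group.size(); ++m) {
      int i = rot_group[m];
      double dx = X(i, 0) - rot_ref(m, 0);
      double dy = X(i, 1) - rot_ref(m, 1);
      double dz = X(i, 2) - rot_ref(m, 2);
      e += dx * dx + dy * dy + dz * dz;
    }
    return 0.5 * rot_k * e;
  };

  double E = total_energy(C, T) + restraint(C);
  double sigma = sigma0;
  int n_frames = (n_steps >= stride) ? n_steps / stride : 0;
  List frames(n_frames);
  NumericVector frame_E(n_frames);
  int frame_at = 0;

  long accepted = 0, attempted = 0;
  int adapt_acc = 0, adapt_att = 0;
  int consec_rej = 0;
  NumericMatrix P(C.nrow(), 3);

  int total_steps = burn_in + n_steps;
  for (int s = 0; s < total_steps; ++s) {
    int b = movable[(int)(unif_rand() * movable.size()) % movable.size()];
    for (int i = 0; i < C.nrow(); ++i)
      for (int d = 0; d < 3; ++d) P(i, d) = C(i, d);
    if (cons_partner[b] >= 0) {
      int p = cons_partner[b];
      double u[3] = {C(b, 0) - C(p, 0), C(b, 1) - C(p, 1), C(b, 2) - C(p, 2)};
      double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      if (nu < GEOM_EPS) { u[0] = 1; u[1] = 0; u[2] = 0; nu = 1; }
      for (int d = 0; d < 3; ++d) u[d] = u[d] / nu + sigma * norm_rand();
      nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      for (int d = 0; d < 3; ++d) P(b, d) = C(p, d) + cons_r0[b] * u[d] / nu;
    } else {
      for (int d = 0; d < 3; ++d) P(b, d) = C(b, d) + sigma * norm_rand();
    }
    place_vsites(P, vs_constructors, vs_weights, vs_sites);
    double Ep = total_energy(P, T) + restraint(P);
    bool accept = (Ep <= E) || (unif_rand() < std::exp(-beta * (Ep - E)));
    attempted++; adapt_att++;
    if (accept) {
      for (int i = 0; i < C.nrow(); ++i)
        for (int d = 0; d < 3; ++d) C(i, d) = P(i, d);
      E = Ep;
      accepted++; adapt_acc++;
      consec_rej = 0;
    } else if (++consec_rej >= 10000) {
      stop("stuck chain: 10000 consecutive rejections (energy %f, move sigma %f)",
           E, sigma);
    }
    if (s < burn_in) {
      if (adapt_att >= 500) {
        double r = (double)adapt_acc / adapt_att;
        if (r < 0.30) sigma *= 0.8;
        else if (r > 0.50) sigma *= 1.25;
        adapt_acc = 0; adapt_att = 0;
      }
    } else {
      int prod = s - burn_in + 1;
      if (prod % stride == 0 && frame_at < n_frames) {
        frame_E[frame_at] = E;
        frames[frame_at++] = clone(C);
      }
    }
  }
  return List::create(_["frames"] = frames, _["final"] = C,
                      _["frame_energies"] = frame_E,
                      _["energy"] = E,
                      _["acceptance"] = (double)accepted / attempted,
                      _["sigma"] = sigma);
}

// Rotate vector v about unit axis a by angle th (Rodrigues).
static void rodrigues(const double* v, const double* a, double th, double* out) {
  double c = std::cos(th), s = std::sin(th);
  double ad = a[0] * v[0] + a[1] * v[1] + a[2] * v[2];
  double cr[3] = {a[1] * v[2] - a[2] * v[1],
                  a[2] * v[0] - a[0] * v[2],
                  a[0] * v[1] - a[1] * v[0]};
  for (int d = 0; d < 3; ++d)
    out[d] = v[d] * c + cr[d] * s + a[d] * ad * (1.0 - c);
}

// Enforced rotation: a pivot-free isotropic harmonic restraint couples the
// rotor beads to reference positions that rotate rigidly about the axle
// direction at a fixed rate, centred on the rotor's instantaneous centroid
// (no mass weighting). Time advances by `timestep` per MC sweep (one
// attempted move per movable bead). Returns the trajectory plus a trace of
// (time ps, reference angle deg, rotor angle deg), both cumulative.
// [[Rcpp::export]]
List cpp_enforced_rotation(NumericMatrix coords0, NumericMatrix bonds,
                           NumericMatrix angles, NumericMatrix dihedrals,
                           IntegerVector vs_sites, List vs_constructors,
                           List vs_weights, IntegerVector movable,
                           IntegerVector cons_partner, NumericVector cons_r0,
                           IntegerVector rot_group, int axis_i, int axis_j,
                           double rate_deg_ps, double k_rot, double timestep,
                           double duration, double beta, double sigma,
                           int stride) {
  Terms T(bonds, angles, dihedrals);
  NumericMatrix C = clone(coords0);
  place_vsites(C, vs_constructors, vs_weights, vs_sites);
  int n_sweeps = (int)std::ceil(duration / timestep);
  int ng = rot_group.size();

  // axle direction (fixed from the initial frame)
  double ax[3] = {C(axis_j, 0) - C(axis_i, 0), C(axis_j, 1) - C(axis_i, 1),
                  C(axis_j, 2) - C(axis_i, 2)};
  double na = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
  if (na < GEOM_EPS) stop("degenerate axis: coincident axle beads");
  for (int d = 0; d < 3; ++d) ax[d] /= na;

  // rotor offsets from the rotor centroid at t = 0
  std::vector<double> off(3 * ng);
  double c0[3] = {0, 0, 0};
  for (int m = 0; m < ng; ++m)
    for (int d = 0; d < 3; ++d) c0[d] += C(rot_group[m], d) / ng;
  for (int m = 0; m < ng; ++m)
    for (int d = 0; d < 3; ++d) off[3 * m + d] = C(rot_group[m], d) - c0[d];

  // in-plane reference direction for measuring the rotor angle: projection
  // of the first rotor bead's offset onto the plane normal to the axle
  double e1[3], e2[3];
  {
    double ad = off[0] * ax[0] + off[1] * ax[1] + off[2] * ax[2];
    for (int d = 0; d < 3; ++d) e1[d] = off[d] - ad * ax[d];
    double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
    if (n1 < GEOM_EPS) stop("first rotor bead lies on the axle; cannot trace angle");
    for (int d = 0; d < 3; ++d) e1[d] /= n1;
    e2[0] = ax[1] * e1[2] - ax[2] * e1[1];
    e2[1] = ax[2] * e1[0] - ax[0] * e1[2];
    e2[2] = ax[0] * e1[1] - ax[1] * e1[0];
  }

  NumericMatrix ref(ng, 3);
  double E = 0.0;  // set below once ref is initialized
  double prev_raw = 0.0, cum = 0.0;
  int n_rec = n_sweeps / stride + 1;
  NumericMatrix trace(n_rec, 3);
  List frames(n_rec);
  int rec = 0;

  auto update_ref = [&](double t_ps) {
    double th = rate_deg_ps * t_ps * M_PI / 180.0;
    double cen[3] = {0, 0, 0};
    for (int m = 0; m < ng; ++m)
      for (int d = 0; d < 3; ++d) cen[d] += C(rot_group[m], d) / ng;
    for (int m = 0; m < ng; ++m) {
      double out[3];
      rodrigues(&off[3 * m], ax, th, out);
      for (int d = 0; d < 3; ++d) ref(m, d) = cen[d] + out[d];
    }
  };
  auto restraint = [&](const NumericMatrix& X) {
    double e = 0.0;
    for (int m = 0; m < ng; ++m) {
      for (int d = 0; d < 3; ++d) {
        double dd = X(rot_group[m], d) - ref(m, d);
        e += dd * dd;
      }
    }
    return 0.5 * k_rot * e;
  };
  auto rotor_angle_raw = [&]() {
    double cen[3] = {0, 0, 0};
    for (int m = 0; m < ng; ++m)
      for (int d = 0; d < 3; ++d) cen[d] += C(rot_group[m], d) / ng;
    double v[3] = {C(rot_group[0], 0) - cen[0], C(rot_group[0], 1) - cen[1],
                   C(rot_group[0], 2) - cen[2]};
    double x = v[0] * e1[0] + v[1] * e1[1] + v[2] * e1[2];
    double y = v[0] * e2[0] + v[1] * e2[1] + v[2] * e2[2];
    return std::atan2(y, x) * 180.0 / M_PI;
  };

  update_ref(0.0);
  E = total_energy(C, T) + restraint(C);
  NumericMatrix P(C.nrow(), 3);
  trace(rec, 0) = 0.0; trace(rec, 1) = 0.0; trace(rec, 2) = 0.0;
  frames[rec++] = clone(C);

  for (int s = 1; s <= n_sweeps; ++s) {
    double t_ps = s * timestep;
    update_ref(t_ps);
    E = total_energy(C, T) + restraint(C);  // ref moved under the chain
    for (int mv = 0; mv < movable.size(); ++mv) {
      int b = movable[mv];
      for (int i = 0; i < C.nrow(); ++i)
        for (int d = 0; d < 3; ++d) P(i, d) = C(i, d);
      if (cons_partner[b] >= 0) {
        int p = cons_partner[b];
        double u[3] = {C(b, 0) - C(p, 0), C(b, 1) - C(p, 1), C(b, 2) - C(p, 2)};
        double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
        if (nu < GEOM_EPS) { u[0] = 1; u[1] = 0; u[2] = 0; nu = 1; }
        for (int d = 0; d < 3; ++d) u[d] = u[d] / nu + sigma * norm_rand();
        nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
        for (int d = 0; d < 3; ++d) P(b, d) = C(p, d) + cons_r0[b] * u[d] / nu;
      } else {
        for (int d = 0; d < 3; ++d) P(b, d) = C(b, d) + sigma * norm_rand();
      }
      place_vsites(P, vs_constructors, vs_weights, vs_sites);
      double Ep = total_energy(P, T) + restraint(P);
      if (Ep <= E || unif_rand() < std::exp(-beta * (Ep - E))) {
        for (int i = 0; i < C.nrow(); ++i)
          for (int d = 0; d < 3; ++d) C(i, d) = P(i, d);
        E = Ep;
      }
    }
    double raw = rotor_angle_raw();
    double d = raw - prev_raw;
    if (d > 180.0) d -= 360.0;
    if (d < -180.0) d += 360.0;
    cum += d;
    prev_raw = raw;
    if (s % stride == 0 && rec < n_rec) {
      trace(rec, 0) = t_ps;
      trace(rec, 1) = rate_deg_ps * t_ps;
      trace(rec, 2) = cum;
      frames[rec++] = clone(C);
    }
  }
  if (rec < n_rec) {
    // trim unused rows (duration not a multiple of stride*timestep)
    trace = NumericMatrix(trace(Range(0, rec - 1), Range(0, 2)));
    List trimmed(rec);
    for (int r = 0; r < rec; ++r) trimmed[r] = frames[r];
    frames = trimmed;
  }
  colnames(trace) = CharacterVector::create("time_ps", "ref_angle", "rotor_angle");
  return List::create(_["frames"] = frames, _["trace"] = trace, _["final"] = C);
}
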