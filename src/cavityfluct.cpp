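// Stillinger-Weber (mW) energy kernels and the NPT Metropolis engine with a
// mobile passive cavity and harmonic occupancy umbrella.
//
// Conventions: lengths A, energies kJ/mol, orthorhombic box, minimum image.
// Solvent model codes: 0 = ideal gas, 1 = hard sphere, 2 = mW (SW).
// Parameter vector layout (model 2): epsilon, sigma, a_cut, A, B, p, q,
// lambda3, gamma3, cos_theta0.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

struct SWParams {
  double eps, sigma, a, A, B, p, q, lambda, gamma, cos0, rc;
  explicit SWParams(const NumericVector &v) {
    eps = v[0]; sigma = v[1]; a = v[2]; A = v[3]; B = v[4];
    p = v[5]; q = v[6]; lambda = v[7]; gamma = v[8]; cos0 = v[9];
    rc = a * sigma;
  }
};

// Deterministic uniform doubles from mt19937_64 (independent of stdlib
// distribution implementations).
struct RngStream {
  std::mt19937_64 eng;
  explicit RngStream(std::uint64_t seed) : eng(seed) {}
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
};

static inline double sw_pair(double r, const SWParams &P) {
  if (r >= P.rc) return 0.0;
  double sr = P.sigma / r;
  double core = P.B * std::pow(sr, P.p) - std::pow(sr, P.q);
  return P.A * P.eps * core * std::exp(P.sigma / (r - P.rc));
}

// Angular term for triplet (j, i, k) with center i; dij, dik are the
// minimum-image displacement vectors from the center to each neighbor.
static inline double sw_triplet(const double *dij, const double *dik,
                                const SWParams &P) {
  double rij = std::sqrt(dij[0] * dij[0] + dij[1] * dij[1] + dij[2] * dij[2]);
  double rik = std::sqrt(dik[0] * dik[0] + dik[1] * dik[1] + dik[2] * dik[2]);
  if (rij >= P.rc || rik >= P.rc) return 0.0;
  double ct = (dij[0] * dik[0] + dij[1] * dik[1] + dij[2] * dik[2]) /
              (rij * rik);
  double dc = ct - P.cos0;
  return P.lambda * P.eps * dc * dc *
         std::exp(P.gamma * P.sigma / (rij - P.rc)) *
         std::exp(P.gamma * P.sigma / (rik - P.rc));
}

static inline void min_image(double dx[3], const double L[3]) {
  for (int d = 0; d < 3; ++d) dx[d] -= L[d] * std::nearbyint(dx[d] / L[d]);
}

struct Sys {
  std::vector<double> x;  // 3N, interleaved
  int N;
  double L[3];
  double cav[3];
  void disp(int i, const double *pt, double out[3]) const {
    out[0] = pt[0] - x[3 * i];
    out[1] = pt[1] - x[3 * i + 1];
    out[2] = pt[2] - x[3 * i + 2];
    min_image(out, L);
  }
};

// Energy of one particle (existing index `self`, or a trial insertion when
// self < 0) located at `pt`: all pair terms with it, triplets with it as
// center, and triplets centered on each neighbor that include it.
static double particle_energy(const Sys &S, const double pt[3], int self,
                              int model, double hs_d, const SWParams *P) {
  if (model == 0) return 0.0;
  if (model == 1) {
    double d2min = hs_d * hs_d;
    for (int j = 0; j < S.N; ++j) {
      if (j == self) continue;
      double dv[3];
      S.disp(j, pt, dv);
      double d2 = dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2];
      if (d2 < d2min) return R_PosInf;
    }
    return 0.0;
  }
  const double rc = P->rc, rc2 = rc * rc;
  double e = 0.0;
  std::vector<int> nb;
  std::vector<double> nbv;  // displacement center->neighbor (pt -> j)
  nb.reserve(32);
  nbv.reserve(96);
  for (int j = 0; j < S.N; ++j) {
    if (j == self) continue;
    double dv[3] = {S.x[3 * j] - pt[0], S.x[3 * j + 1] - pt[1],
                    S.x[3 * j + 2] - pt[2]};
    min_image(dv, S.L);
    double d2 = dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2];
    if (d2 < rc2) {
      double r = std::sqrt(d2);
      if (r <= 0) return R_PosInf;  // coincident particles
      e += sw_pair(r, *P);
      nb.push_back(j);
      nbv.push_back(dv[0]); nbv.push_back(dv[1]); nbv.push_back(dv[2]);
    }
  }
  const int m = (int)nb.size();
  // particle as triplet center
  for (int aa = 0; aa < m; ++aa)
    for (int bb = aa + 1; bb < m; ++bb)
      e += sw_triplet(&nbv[3 * aa], &nbv[3 * bb], *P);
  // neighbor j as center, triplet (particle, j, k)
  for (int aa = 0; aa < m; ++aa) {
    int j = nb[aa];
    double dji[3] = {-nbv[3 * aa], -nbv[3 * aa + 1], -nbv[3 * aa + 2]};
    for (int k = 0; k < S.N; ++k) {
      if (k == j || k == self) continue;
      double djk[3];
      S.disp(j, &S.x[3 * k], djk);  // j -> k
      double d2 = djk[0] * djk[0] + djk[1] * djk[1] + djk[2] * djk[2];
      if (d2 < rc2) e += sw_triplet(dji, djk, *P);
    }
  }
  return e;
}

static double total_energy_sys(const Sys &S, int model, double hs_d,
                               const SWParams *P) {
  if (model == 0) return 0.0;
  if (model == 1) {
    double d2min = hs_d * hs_d;
    for (int i = 0; i < S.N; ++i)
      for (int j = i + 1; j < S.N; ++j) {
        double dv[3];
        S.disp(i, &S.x[3 * j], dv);
        double d2 = dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2];
        if (d2 < d2min) return R_PosInf;
      }
    return 0.0;
  }
  const double rc2 = P->rc * P->rc;
  double e = 0.0;
  for (int i = 0; i < S.N; ++i) {
    std::vector<double> nbv;
    nbv.reserve(96);
    for (int j = 0; j < S.N; ++j) {
      if (j == i) continue;
      double dv[3];
      S.disp(i, &S.x[3 * j], dv);
      double d2 = dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2];
      if (d2 < rc2) {
        if (j > i) e += sw_pair(std::sqrt(d2), *P);
        nbv.push_back(dv[0]); nbv.push_back(dv[1]); nbv.push_back(dv[2]);
      }
    }
    int m = (int)nbv.size() / 3;
    for (int aa = 0; aa < m; ++aa)
      for (int bb = aa + 1; bb < m; ++bb)
        e += sw_triplet(&nbv[3 * aa], &nbv[3 * bb], *P);
  }
  return e;
}

static Sys make_sys(const NumericMatrix &pos, const NumericVector &box,
                    const NumericVector &cav) {
  Sys S;
  S.N = pos.nrow();
  S.x.resize(3 * S.N);
  for (int i = 0; i < S.N; ++i)
    for (int d = 0; d < 3; ++d) S.x[3 * i + d] = pos(i, d);
  for (int d = 0; d < 3; ++d) {
    S.L[d] = box[d];
    S.cav[d] = cav.size() == 3 ? cav[d] : box[d] / 2.0;
  }
  return S;
}

// [[Rcpp::export]]
double cpp_pair_energy(double r, NumericVector params) {
  if (r <= 0) stop("pair separation must be positive");
  SWParams P(params);
  return sw_pair(r, P);
}

// [[Rcpp::export]]
double cpp_triplet_energy(NumericVector r_ij, NumericVector r_ik,
                          NumericVector params) {
  SWParams P(params);
  double a[3] = {r_ij[0], r_ij[1], r_ij[2]};
  double b[3] = {r_ik[0], r_ik[1], r_ik[2]};
  return sw_triplet(a, b, P);
}

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, NumericVector box,
                        NumericVector params, int model, double hs_d) {
  Sys S = make_sys(pos, box, NumericVector::create());
  SWParams P(params);
  return total_energy_sys(S, model, hs_d, model == 2 ? &P : nullptr);
}

// [[Rcpp::export]]
double cpp_delta_energy(NumericMatrix pos, int moved_index,
                        NumericVector new_pos, NumericVector box,
                        NumericVector params, int model, double hs_d) {
  Sys S = make_sys(pos, box, NumericVector::create());
  SWParams P(params);
  const SWParams *Pp = model == 2 ? &P : nullptr;
  double oldpt[3] = {S.x[3 * moved_index], S.x[3 * moved_index + 1],
                     S.x[3 * moved_index + 2]};
  double newpt[3] = {new_pos[0], new_pos[1], new_pos[2]};
  double e_old = particle_energy(S, oldpt, moved_index, model, hs_d, Pp);
  double e_new = particle_energy(S, newpt, moved_index, model, hs_d, Pp);
  if (!R_finite(e_new)) return R_PosInf;
  if (!R_finite(e_old)) return R_NegInf;
  return e_new - e_old;
}

// Mean Boltzmann factor of random trial insertions in one frame.
// mode 0: a solvent test particle; mode 1: a hard-sphere test particle of
// radius test_radius (Boltzmann factor 1 iff no solvent center is within).
// [[Rcpp::export]]
List cpp_widom_frame(NumericMatrix pos, NumericVector box,
                     NumericVector params, int model, double hs_d,
                     int mode, double test_radius, int n_insert,
                     double temperature, int seed) {
  Sys S = make_sys(pos, box, NumericVector::create());
  SWParams P(params);
  const SWParams *Pp = model == 2 ? &P : nullptr;
  RngStream rng((std::uint64_t)seed);
  const double kB = 0.008314462618;
  double beta = 1.0 / (kB * temperature);
  double sum = 0.0;
  for (int t = 0; t < n_insert; ++t) {
    double pt[3];
    for (int d = 0; d < 3; ++d) pt[d] = rng.unif() * S.L[d];
    double b;
    if (mode == 1) {
      b = 1.0;
      if (test_radius > 0) {
        double r2 = test_radius * test_radius;
        for (int j = 0; j < S.N; ++j) {
          double dv[3];
          S.disp(j, pt, dv);
          if (dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2] < r2) {
            b = 0.0;
            break;
          }
        }
      }
    } else {
      double du = particle_energy(S, pt, -1, model, hs_d, Pp);
      b = R_finite(du) ? std::exp(-beta * du) : 0.0;
    }
    sum += b;
  }
  return List::create(_["mean_boltzmann"] = sum / n_insert,
                      _["n_insert"] = n_insert);
}

struct MoveStats {
  long att = 0, acc = 0;
  double rate() const { return att > 0 ? (double)acc / att : NA_REAL; }
  void reset() { att = acc = 0; }
};

static inline int count_occupancy(const Sys &S, double R) {
  int n = 0;
  double R2 = R * R;
  for (int i = 0; i < S.N; ++i) {
    double dv[3] = {S.x[3 * i] - S.cav[0], S.x[3 * i + 1] - S.cav[1],
                    S.x[3 * i + 2] - S.cav[2]};
    min_image(dv, S.L);
    if (dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2] < R2) ++n;  // strict <R
  }
  return n;
}

static inline bool inside_cavity(const Sys &S, const double pt[3], double R) {
  double dv[3] = {pt[0] - S.cav[0], pt[1] - S.cav[1], pt[2] - S.cav[2]};
  min_image(dv, S.L);
  return dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2] < R * R;
}

// NPT Metropolis with displacement, cavity and volume moves.  Move sizes are
// tuned toward target_acc during equilibration only and frozen afterwards.
// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix pos0, NumericVector box0, NumericVector cav0,
                double R, double k0, double n0, NumericVector params,
                int model, double hs_d, double temperature,
                double pressure_kj, int seed, int passes_eq, int passes_prod,
                int vol_every, double target_acc, int tune_every,
                double step_trans0, double step_cav0, double step_vol_frac0,
                int sample_every, int frame_every, bool move_cavity) {
  Sys S = make_sys(pos0, box0, cav0);
  SWParams P(params);
  const SWParams *Pp = model == 2 ? &P : nullptr;
  const double kB = 0.008314462618;
  const double beta = 1.0 / (kB * temperature);
  const double rc = model == 2 ? P.rc : (model == 1 ? hs_d : 0.0);
  RngStream rng((std::uint64_t)seed);

  double U = total_energy_sys(S, model, hs_d, Pp);
  if (!R_finite(U)) stop("initial configuration has infinite energy");
  int n = count_occupancy(S, R);

  double step_trans = step_trans0, step_cav = step_cav0,
         step_vol_frac = step_vol_frac0;
  MoveStats st_t, st_c, st_v;

  auto umb = [&](int nn) {
    double d = nn - n0;
    return 0.5 * k0 * d * d;
  };

  std::vector<int> n_series;
  std::vector<double> V_series, U_series;
  std::vector<long> hist;
  List frames;
  std::vector<double> frame_L, frame_cav;
  std::vector<int> frame_n;

  long total_passes = (long)passes_eq + passes_prod;
  for (long pass = 1; pass <= total_passes; ++pass) {
    bool in_prod = pass > passes_eq;
    // one attempted displacement per particle
    for (int i = 0; i < S.N; ++i) {
      double oldpt[3] = {S.x[3 * i], S.x[3 * i + 1], S.x[3 * i + 2]};
      double newpt[3];
      for (int d = 0; d < 3; ++d) {
        newpt[d] = oldpt[d] + (2.0 * rng.unif() - 1.0) * step_trans;
        newpt[d] -= S.L[d] * std::floor(newpt[d] / S.L[d]);
      }
      ++st_t.att;
      double dU;
      if (model == 0) {
        dU = 0.0;
      } else {
        double e_new = particle_energy(S, newpt, i, model, hs_d, Pp);
        if (!R_finite(e_new)) continue;  // reject
        double e_old = particle_energy(S, oldpt, i, model, hs_d, Pp);
        dU = e_new - e_old;
      }
      int dn = (inside_cavity(S, newpt, R) ? 1 : 0) -
               (inside_cavity(S, oldpt, R) ? 1 : 0);
      double dB = umb(n + dn) - umb(n);
      double arg = -beta * (dU + dB);
      if (arg >= 0 || rng.unif() < std::exp(arg)) {
        S.x[3 * i] = newpt[0]; S.x[3 * i + 1] = newpt[1];
        S.x[3 * i + 2] = newpt[2];
        U += dU;
        n += dn;
        ++st_t.acc;
      }
    }
    // cavity move (umbrella energy only; the cavity is a passive probe)
    if (move_cavity) {
      double oldc[3] = {S.cav[0], S.cav[1], S.cav[2]};
      int nold = n;
      for (int d = 0; d < 3; ++d) {
        S.cav[d] += (2.0 * rng.unif() - 1.0) * step_cav;
        S.cav[d] -= S.L[d] * std::floor(S.cav[d] / S.L[d]);
      }
      ++st_c.att;
      int nnew = count_occupancy(S, R);
      double arg = -beta * (umb(nnew) - umb(nold));
      if (arg >= 0 || rng.unif() < std::exp(arg)) {
        n = nnew;
        ++st_c.acc;
      } else {
        for (int d = 0; d < 3; ++d) S.cav[d] = oldc[d];
      }
    }
    // volume move, symmetric in ln V (acceptance carries N+1 in the
    // Jacobian-corrected entropy term)
    if (vol_every > 0 && pass % vol_every == 0) {
      ++st_v.att;
      double V = S.L[0] * S.L[1] * S.L[2];
      double dlnV = (2.0 * rng.unif() - 1.0) * step_vol_frac;
      double Vnew = V * std::exp(dlnV);
      {
        double s = std::cbrt(Vnew / V);
        bool ok = true;
        if (rc > 0)
          for (int d = 0; d < 3; ++d)
            if (S.L[d] * s < 2 * rc) ok = false;
        if (ok) {
          Sys T = S;
          for (int d = 0; d < 3; ++d) {
            T.L[d] = S.L[d] * s;
            T.cav[d] = S.cav[d] * s;
          }
          for (int i = 0; i < 3 * S.N; ++i) T.x[i] = S.x[i] * s;
          double Unew = total_energy_sys(T, model, hs_d, Pp);
          if (R_finite(Unew)) {
            int nnew = count_occupancy(T, R);
            double arg = (S.N + 1) * dlnV -
                         beta * pressure_kj * (Vnew - V) -
                         beta * (Unew - U) - beta * (umb(nnew) - umb(n));
            if (arg >= 0 || rng.unif() < std::exp(arg)) {
              S = T;
              U = Unew;
              n = nnew;
              ++st_v.acc;
            }
          }
        }
      }
    }
    // equilibration-only step-size tuning
    if (!in_prod && tune_every > 0 && pass % tune_every == 0) {
      if (st_t.att > 0)
        step_trans *= (st_t.rate() > target_acc) ? 1.1 : 0.9;
      double lmin = std::min(S.L[0], std::min(S.L[1], S.L[2]));
      if (step_trans > lmin / 2) step_trans = lmin / 2;
      if (step_trans < 1e-4) step_trans = 1e-4;
      if (move_cavity && st_c.att > 0)
        step_cav *= (st_c.rate() > target_acc) ? 1.1 : 0.9;
      if (step_cav > lmin / 2) step_cav = lmin / 2;
      if (step_cav < 1e-4) step_cav = 1e-4;
      if (st_v.att > 0)
        step_vol_frac *= (st_v.rate() > target_acc) ? 1.1 : 0.9;
      if (step_vol_frac > 0.5) step_vol_frac = 0.5;
      if (step_vol_frac < 1e-6) step_vol_frac = 1e-6;
      st_t.reset(); st_c.reset(); st_v.reset();
    }
    if (pass == passes_eq) {  // freeze tuning, restart counters for prod
      st_t.reset(); st_c.reset(); st_v.reset();
      if (model == 2) U = total_energy_sys(S, model, hs_d, Pp);
    }
    if (in_prod) {
      long ppass = pass - passes_eq;
      if (model == 2 && ppass % 200 == 0)
        U = total_energy_sys(S, model, hs_d, Pp);  // kill accumulation drift
      if (sample_every > 0 && ppass % sample_every == 0) {
        n_series.push_back(n);
        V_series.push_back(S.L[0] * S.L[1] * S.L[2]);
        U_series.push_back(U);
        if ((size_t)n >= hist.size()) hist.resize(n + 1, 0);
        ++hist[n];
      }
      if (frame_every > 0 && ppass % frame_every == 0) {
        NumericMatrix fp(S.N, 3);
        for (int i = 0; i < S.N; ++i)
          for (int d = 0; d < 3; ++d) fp(i, d) = S.x[3 * i + d];
        frames.push_back(fp);
        for (int d = 0; d < 3; ++d) {
          frame_L.push_back(S.L[d]);
          frame_cav.push_back(S.cav[d]);
        }
        frame_n.push_back(n);
      }
    }
  }

  NumericMatrix posf(S.N, 3);
  for (int i = 0; i < S.N; ++i)
    for (int d = 0; d < 3; ++d) posf(i, d) = S.x[3 * i + d];
  return List::create(
      _["hist_counts"] = IntegerVector(hist.begin(), hist.end()),
      _["n_series"] = IntegerVector(n_series.begin(), n_series.end()),
      _["V_series"] = NumericVector(V_series.begin(), V_series.end()),
      _["U_series"] = NumericVector(U_series.begin(), U_series.end()),
      _["frames"] = frames,
      _["frame_box"] = NumericVector(frame_L.begin(), frame_L.end()),
      _["frame_cavity"] = NumericVector(frame_cav.begin(), frame_cav.end()),
      _["frame_n"] = IntegerVector(frame_n.begin(), frame_n.end()),
      _["acc_trans"] = st_t.rate(), _["acc_cavity"] = st_c.rate(),
      _["acc_volume"] = st_v.rate(),
      _["step_trans"] = step_trans, _["step_cavity"] = step_cav,
      _["step_vol_frac"] = step_vol_frac,
      _["final_positions"] = posf,
      _["final_box"] = NumericVector::create(S.L[0], S.L[1], S.L[2]),
      _["final_cavity"] = NumericVector::create(S.cav[0], S.cav[1], S.cav[2]),
      _["final_energy"] = U, _["final_n"] = n);
}
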