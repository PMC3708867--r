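// Kinetic Monte Carlo core of the population-balance solver.
//
// State lives in plain std::vectors; the waiting time between events is
// exponential in the summed propensity (switch channels + division),
// propensities are frozen over each quiescence interval and refreshed after
// every event. Protein pools follow the closed-form ODE solution and are
// updated lazily (only when a cell is touched or a snapshot is taken);
// with transcriptional noise enabled every cell is stepped by
// Euler-Maruyama across each interval instead. Uses R's RNG throughout so
// set.seed() makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Pop {
  std::vector<double> n1, n2, r1, r2, v, t_mol, t_birth;
  std::vector<int> type, id;
  size_t size() const { return type.size(); }
};

// division hazard lookup table: Gamma(v) on a uniform grid, capped
struct HazardTable {
  double vmax, step, cap;
  std::vector<double> h;
  void build(double mu, double sigma, double t_d, double cap_, int nn) {
    cap = cap_;
    vmax = mu + 10.0 * sigma;
    step = vmax / (nn - 1);
    h.resize(nn);
    const double r = M_LN2 / t_d;
    for (int i = 0; i < nn; ++i) {
      double vv = i * step;
      double surv = R::pnorm(vv, mu, sigma, 0, 0);
      double val;
      if (surv <= 0.0 || vv <= 0.0) {
        val = (vv <= 0.0) ? 0.0 : cap;
      } else {
        val = r * vv * R::dnorm(vv, mu, sigma, 0) / surv;
      }
      h[i] = std::min(val, cap);
    }
  }
  double operator()(double vv) const {
    if (vv <= 0.0) return 0.0;
    if (vv >= vmax) return cap;
    double x = vv / step;
    int i = (int)x;
    double f = x - i;
    return h[i] * (1.0 - f) + h[i + 1] * f;
  }
};

} // namespace

// [[Rcpp::export]]
List pbe_engine_cpp(NumericVector n1, NumericVector n2,
                    NumericVector r1, NumericVector r2,
                    NumericVector v, IntegerVector type,
                    IntegerVector cell_id, int next_id,
                    NumericMatrix kmat, double t_d,
                    double s_on, double s_off,
                    double gamma_n, double gamma_r,
                    double eta, double dt_sde, bool noise_production,
                    bool rep1, bool rep2, bool production_off,
                    bool division_off, bool allele1_deleted,
                    bool size_hazard,
                    double mu, double sigma, double q, double hazard_cap,
                    int n_cap, double t0, double t_end,
                    NumericVector snapshot_times) {
  const int n0 = n1.size();
  if (n0 < 1) stop("population is extinct (no cells)");

  Pop P;
  P.n1.assign(n1.begin(), n1.end());
  P.n2.assign(n2.begin(), n2.end());
  P.r1.assign(r1.begin(), r1.end());
  P.r2.assign(r2.begin(), r2.end());
  P.v.assign(v.begin(), v.end());
  P.type.assign(type.begin(), type.end());
  P.id.assign(cell_id.begin(), cell_id.end());
  P.t_mol.assign(n0, t0);
  P.t_birth.assign(n0, t0);
  P.n1.reserve(n_cap + 1); P.n2.reserve(n_cap + 1);
  P.r1.reserve(n_cap + 1); P.r2.reserve(n_cap + 1);
  P.v.reserve(n_cap + 1); P.t_mol.reserve(n_cap + 1);
  P.type.reserve(n_cap + 1); P.id.reserve(n_cap + 1);

  const double lam = M_LN2 / t_d;
  const bool sde = eta > 0.0;

  HazardTable H;
  if (size_hazard) H.build(mu, sigma, t_d, hazard_cap, 4096);

  // production rate of an allele given cell type; allele 1 active in types
  // 1,2; allele 2 active in types 1,3 (all off under shutoff). A deleted
  // allele 1 stays at the off-state value whatever its chromatin state.
  auto s_allele1 = [&](int ty) {
    return (!production_off && !allele1_deleted && (ty == 1 || ty == 2))
        ? s_on : s_off;
  };
  auto s_allele2 = [&](int ty) {
    return (!production_off && (ty == 1 || ty == 3)) ? s_on : s_off;
  };

  // bring cell i's protein pools from t_mol[i] to t (closed form)
  auto update_mol = [&](size_t i, double t) {
    double dt = t - P.t_mol[i];
    if (dt <= 0.0) { P.t_mol[i] = t; return; }
    double e_n = std::exp(-gamma_n * dt);
    double ss1 = s_allele1(P.type[i]) / gamma_n;
    double ss2 = s_allele2(P.type[i]) / gamma_n;
    P.n1[i] = ss1 + (P.n1[i] - ss1) * e_n;
    P.n2[i] = ss2 + (P.n2[i] - ss2) * e_n;
    if (rep1 || rep2) {
      double e_r = std::exp(-gamma_r * dt);
      if (rep1) {
        double sr1 = s_allele1(P.type[i]) / gamma_r;
        P.r1[i] = sr1 + (P.r1[i] - sr1) * e_r;
      }
      if (rep2) {
        double sr2 = s_allele2(P.type[i]) / gamma_r;
        P.r2[i] = sr2 + (P.r2[i] - sr2) * e_r;
      }
    }
    P.t_mol[i] = t;
  };

  // Euler-Maruyama step for all cells across [t, t + h]
  auto step_sde = [&](double t, double h) {
    int nsub = (int)std::ceil(h / dt_sde);
    if (nsub < 1) nsub = 1;
    double hs = h / nsub;
    double sq = std::sqrt(hs);
    for (int s = 0; s < nsub; ++s) {
      for (size_t i = 0; i < P.size(); ++i) {
        double sa1 = s_allele1(P.type[i]), sa2 = s_allele2(P.type[i]);
        double a1 = noise_production ? eta * sa1 : eta * P.n1[i];
        double a2 = noise_production ? eta * sa2 : eta * P.n2[i];
        P.n1[i] += (sa1 - gamma_n * P.n1[i]) * hs + a1 * sq * norm_rand();
        P.n2[i] += (sa2 - gamma_n * P.n2[i]) * hs + a2 * sq * norm_rand();
        if (P.n1[i] < 0) P.n1[i] = 0;
        if (P.n2[i] < 0) P.n2[i] = 0;
        if (rep1) {
          double b1 = noise_production ? eta * sa1 : eta * P.r1[i];
          P.r1[i] += (sa1 - gamma_r * P.r1[i]) * hs + b1 * sq * norm_rand();
          if (P.r1[i] < 0) P.r1[i] = 0;
        }
        if (rep2) {
          double b2 = noise_production ? eta * sa2 : eta * P.r2[i];
          P.r2[i] += (sa2 - gamma_r * P.r2[i]) * hs + b2 * sq * norm_rand();
          if (P.r2[i] < 0) P.r2[i] = 0;
        }
      }
    }
    for (size_t i = 0; i < P.size(); ++i) P.t_mol[i] = t + h;
  };

  auto advance = [&](double t_from, double t_to) {
    double dt = t_to - t_from;
    if (dt <= 0.0) return;
    double g = std::exp(lam * dt);
    for (size_t i = 0; i < P.size(); ++i) P.v[i] *= g;
    if (sde) step_sde(t_from, dt);
  };

  // per-cell switch-rate sums by type, and channel rates
  double swsum[5];
  for (int i = 1; i <= 4; ++i) {
    swsum[i] = 0.0;
    for (int j = 1; j <= 4; ++j)
      if (j != i) swsum[i] += kmat(i - 1, j - 1);
  }

  std::vector<double> divrate;
  auto total_rate = [&]() {
    size_t n = P.size();
    divrate.resize(n);
    double tot = 0.0;
    for (size_t i = 0; i < n; ++i) {
      divrate[i] = division_off ? 0.0 : (size_hazard ? H(P.v[i]) : lam);
      tot += divrate[i] + swsum[P.type[i]];
    }
    return tot;
  };

  List snapshots;
  auto record = [&](double t) {
    size_t n = P.size();
    if (!sde) for (size_t i = 0; i < n; ++i) update_mol(i, t);
    snapshots.push_back(List::create(
        _["time"] = t,
        _["cell_id"] = IntegerVector(P.id.begin(), P.id.end()),
        _["type"] = IntegerVector(P.type.begin(), P.type.end()),
        _["n1"] = NumericVector(P.n1.begin(), P.n1.end()),
        _["n2"] = NumericVector(P.n2.begin(), P.n2.end()),
        _["r1"] = NumericVector(P.r1.begin(), P.r1.end()),
        _["r2"] = NumericVector(P.r2.begin(), P.r2.end()),
        _["v"] = NumericVector(P.v.begin(), P.v.end())));
  };

  long divisions = 0;
  double interval_sum = 0.0; // completed birth-to-division intervals
  IntegerMatrix switches(4, 4);

  double t = t0;
  int snap_idx = 0;
  const int n_snap = snapshot_times.size();

  while (true) {
    // emit any snapshots due at the current time
    while (snap_idx < n_snap && snapshot_times[snap_idx] <= t + 1e-9) {
      record(snapshot_times[snap_idx]);
      ++snap_idx;
    }
    if (t >= t_end - 1e-9) break;

    double tot = total_rate();
    double t_next = (tot > 0.0) ? t + exp_rand() / tot : R_PosInf;
    double t_barrier = (snap_idx < n_snap) ?
        std::min((double)snapshot_times[snap_idx], t_end) : t_end;

    if (t_next >= t_barrier) {
      // no event before the next snapshot/horizon: advance and continue
      advance(t, t_barrier);
      t = t_barrier;
      continue;
    }

    advance(t, t_next);
    t = t_next;

    // select the cell and channel by inverse CDF over the event matrix
    double x = unif_rand() * tot;
    size_t k = 0;
    double acc = 0.0;
    size_t n = P.size();
    for (; k < n; ++k) {
      double row = swsum[P.type[k]] + divrate[k];
      if (acc + row >= x) break;
      acc += row;
    }
    if (k >= n) k = n - 1;
    double within = x - acc;
    int ev = -1; // destination state for a switch, 0 for division
    int ty = P.type[k];
    for (int l = 1; l <= 4; ++l) {
      if (l == ty) continue;
      double rr = kmat(ty - 1, l - 1);
      if (within < rr) { ev = l; break; }
      within -= rr;
    }
    if (ev < 0) ev = 0; // division channel (the last entry of the row)

    if (ev == 0) {
      // division: partition every state component independently
      if (!sde) update_mol(k, t);
      ++divisions;
      interval_sum += t - P.t_birth[k];
      double fn1 = R::rbeta(q, q), fn2 = R::rbeta(q, q);
      double fr1 = R::rbeta(q, q), fr2 = R::rbeta(q, q);
      double fv = R::rbeta(q, q);
      double bn1 = P.n1[k] * (1 - fn1), bn2 = P.n2[k] * (1 - fn2);
      double br1 = P.r1[k] * (1 - fr1), br2 = P.r2[k] * (1 - fr2);
      double bv = P.v[k] * (1 - fv);
      int bty = P.type[k];
      // daughter A replaces the mother in place
      P.n1[k] *= fn1; P.n2[k] *= fn2;
      P.r1[k] *= fr1; P.r2[k] *= fr2;
      P.v[k] *= fv;
      P.id[k] = next_id++;
      P.t_mol[k] = t;
      P.t_birth[k] = t;
      if ((int)n < n_cap) {
        // constant-volume phase: append daughter B
        P.n1.push_back(bn1); P.n2.push_back(bn2);
        P.r1.push_back(br1); P.r2.push_back(br2);
        P.v.push_back(bv); P.type.push_back(bty);
        P.id.push_back(next_id++); P.t_mol.push_back(t);
        P.t_birth.push_back(t);
      } else {
        // constant-number phase: daughter B overwrites a random other cell
        size_t j = (size_t)(unif_rand() * (n - 1));
        if (j >= k) ++j;
        if (j >= n) j = n - 1;
        P.n1[j] = bn1; P.n2[j] = bn2;
        P.r1[j] = br1; P.r2[j] = br2;
        P.v[j] = bv; P.type[j] = bty;
        P.id[j] = next_id++; P.t_mol[j] = t;
        P.t_birth[j] = t;
      }
    } else {
      // allelic switch: production constants change from this instant
      if (!sde) update_mol(k, t);
      switches(ty - 1, ev - 1)++;
      P.type[k] = ev;
    }
  }

  size_t n = P.size();
  if (!sde) for (size_t i = 0; i < n; ++i) update_mol(i, t);

  List final_state = List::create(
      _["time"] = t,
      _["cell_id"] = IntegerVector(P.id.begin(), P.id.end()),
      _["type"] = IntegerVector(P.type.begin(), P.type.end()),
      _["n1"] = NumericVector(P.n1.begin(), P.n1.end()),
      _["n2"] = NumericVector(P.n2.begin(), P.n2.end()),
      _["r1"] = NumericVector(P.r1.begin(), P.r1.end()),
      _["r2"] = NumericVector(P.r2.begin(), P.r2.end()),
      _["v"] = NumericVector(P.v.begin(), P.v.end()));

  return List::create(
      _["snapshots"] = snapshots,
      _["final_state"] = final_state,
      _["event_counts"] = List::create(
          _["divisions"] = (double)divisions,
          _["division_interval_mean"] =
              divisions > 0 ? interval_sum / divisions : NA_REAL,
          _["switches"] = switches));
}
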