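// Hourly event loop of the lattice model: SMC division with monocyte-
// augmented matrix bursts, scheduled 24/48-h matrix production, apoptosis
// with nearest-ECM degradation, Poisson monocyte influx, and adjacent-
// column redistribution. All randomness goes through R's RNG so runs are
// reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int K_SMC = 1, K_ECM = 2, K_MONO = 3;

struct Kin {
  double A, Bd, Dmm, E, Fd, Hmm, J, Kd, TB, TD, w, Tc, es_mm;
  int form;  // 0 = exponential exp(-tau*), 1 = inverse 1/tau*
  double M_B, divh_B, bmax_B, M_D, divh_D, bmax_D;

  void init_geometry() {
    geom(TB, M_B, divh_B, bmax_B);
    geom(TD, M_D, divh_D, bmax_D);
  }
  void geom(double Th, double &M, double &divh, double &bmax) const {
    double Sd = Tc / 3.0;
    double upper = std::min(2.0 * Sd + w, Tc);
    divh = std::min(Th, Tc);
    double lab_div = std::max(0.0, std::min(upper, Th) - Sd);
    double lab_undiv = std::max(0.0, upper - std::max(Th, Sd));
    M = 2.0 * lab_div + lab_undiv;
    bmax = 100.0 * M / (Tc + divh);
  }
  double S(double ts) const { return form == 0 ? std::exp(-ts) : 1.0 / ts; }
  double invert(double b, double M, double divh, double bmax) const {
    if (b <= 0) return 0.0;
    double bh = std::min(b, bmax) / 100.0;
    double p = bh / (M - bh * divh);
    return std::min(p, 1.0 / Tc);
  }
  double brdu(double ts, double td) const { return A * S(ts) * std::exp(-Bd * td); }
  double tunel(double ts, double td) const { return E * S(ts) * std::exp(-Fd * td); }
  double pdiv_mean(double ts, double td) const { return invert(brdu(ts, td), M_B, divh_B, bmax_B); }
  double papop_mean(double ts, double td) const { return invert(tunel(ts, td), M_D, divh_D, bmax_D); }
  double influx(double ts, double td) const { return J * S(ts) * std::exp(-Kd * td); }
  static double normalizer(double mean_p, double IT, double decay) {
    double z = decay * IT;
    if (z < 1e-8) return mean_p * (1.0 + z / 2.0);
    return mean_p * z / (-std::expm1(-z));
  }
};

struct Col {
  std::vector<int> kind;
  std::vector<double> last_div;  // hours; -1 = never divided / not SMC
  std::vector<int> ecm_n;        // scheduled ECM since last division
  std::vector<int> id;
  int h() const { return (int)kind.size(); }
  void insert(int pos, int k, double ld, int en, int eid) {
    kind.insert(kind.begin() + pos, k);
    last_div.insert(last_div.begin() + pos, ld);
    ecm_n.insert(ecm_n.begin() + pos, en);
    id.insert(id.begin() + pos, eid);
  }
  void erase(int pos) {
    kind.erase(kind.begin() + pos);
    last_div.erase(last_div.begin() + pos);
    ecm_n.erase(ecm_n.begin() + pos);
    id.erase(id.begin() + pos);
  }
  int find_id(int eid) const {
    for (int r = h() - 1; r >= 0; --r)
      if (id[r] == eid) return r;
    return -1;
  }
};

struct Counts {
  long divisions = 0, apoptoses = 0, influx = 0;
  long ecm_sched = 0, ecm_burst = 0, ecm_degraded = 0;
  long insertions = 0, removals = 0, clip_events = 0, redist_moves = 0;
};

static int runif_int(int n) {  // uniform on 0..n-1
  int k = (int)std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Insert a new element adjacent to (c, r), displacing lumen-ward.
// Directions: outer (same column at r), lumen (r + 1), and in 2-D the two
// lateral columns at the matching depth (capped at the neighbor's top).
static void insert_adjacent(std::vector<Col> &g, int c, int r, bool mode1d,
                            int k, double ld, int en, int &next_id) {
  int n = (int)g.size();
  int tc[4], tp[4], nv = 0;
  tc[nv] = c; tp[nv] = r; ++nv;         // outward side
  tc[nv] = c; tp[nv] = r + 1; ++nv;     // luminal side
  if (!mode1d) {
    if (c > 0)     { tc[nv] = c - 1; tp[nv] = std::min(r, g[c - 1].h()); ++nv; }
    if (c < n - 1) { tc[nv] = c + 1; tp[nv] = std::min(r, g[c + 1].h()); ++nv; }
  }
  int pick = runif_int(nv);
  g[tc[pick]].insert(tp[pick], k, ld, en, next_id++);
}

static void redistribute_sweeps(std::vector<Col> &g, Counts &ct, bool mode1d) {
  int n = (int)g.size();
  if (mode1d || n < 2) return;
  auto move_top = [&](int from, int to) {
    int r = g[from].h() - 1;
    g[to].insert(g[to].h(), g[from].kind[r], g[from].last_div[r],
                 g[from].ecm_n[r], g[from].id[r]);
    g[from].erase(r);
    ct.redist_moves++;
  };
  long before;
  do {
    before = ct.redist_moves;
    for (int i = 0; i < n - 1; ++i)
      while (std::abs(g[i].h() - g[i + 1].h()) > 2)
        (g[i].h() > g[i + 1].h()) ? move_top(i, i + 1) : move_top(i + 1, i);
    for (int i = n - 2; i >= 0; --i)
      while (std::abs(g[i].h() - g[i + 1].h()) > 2)
        (g[i].h() > g[i + 1].h()) ? move_top(i, i + 1) : move_top(i + 1, i);
  } while (ct.redist_moves != before);
}

struct EcmTarget { double d2, tie; int c, r; };

// Up to `count` ECM nearest (grid-index Euclidean) to (c0, r0); ties random.
static std::vector<EcmTarget> nearest_ecm(const std::vector<Col> &g, int c0,
                                          int r0, int count) {
  std::vector<EcmTarget> cand;
  for (int c = 0; c < (int)g.size(); ++c)
    for (int r = 0; r < g[c].h(); ++r)
      if (g[c].kind[r] == K_ECM) {
        double dc = c - c0, dr = r - r0;
        cand.push_back({dc * dc + dr * dr, unif_rand(), c, r});
      }
  auto cmp = [](const EcmTarget &a, const EcmTarget &b) {
    return a.d2 != b.d2 ? a.d2 < b.d2 : a.tie < b.tie;
  };
  if ((int)cand.size() > count) {
    std::partial_sort(cand.begin(), cand.begin() + count, cand.end(), cmp);
    cand.resize(count);
  } else {
    std::sort(cand.begin(), cand.end(), cmp);
  }
  return cand;
}

static Kin kin_from_list(const List &par) {
  Kin k;
  k.A = par["A"]; k.Bd = par["B"]; k.Dmm = par["D"];
  k.E = par["E"]; k.Fd = par["F"]; k.Hmm = par["H"];
  k.J = par["J"]; k.Kd = par["K"];
  k.TB = par["T_B"]; k.TD = par["T_D"];
  k.w = par["brdu_window"]; k.Tc = par["cell_cycle"];
  k.es_mm = as<double>(par["element_size"]) / 1000.0;
  k.form = as<std::string>(par["shear_response"]) == "inverse" ? 1 : 0;
  k.init_geometry();
  return k;
}

// [[Rcpp::export]]
List cpp_run(List cfg) {
  RNGScope rng;
  Kin kin = kin_from_list(cfg["params"]);

  const int n_steps = cfg["n_steps"];
  const double dt = cfg["dt_h"];
  const double start_h = cfg["start_h"];
  const bool mode1d = cfg["mode1d"];
  const bool mono_on = cfg["monocyte_on"];
  const bool mono_baseline_norm = cfg["mono_norm_baseline"];
  const bool macro_plus_one = cfg["macro_plus_one"];
  const bool influx_surface = cfg["influx_surface"];
  NumericMatrix tau_mat = cfg["tau_star_mat"];  // n_update_blocks x n_columns
  const int update_steps = cfg["update_steps"];
  NumericVector ov_div = cfg["override_div"];   // per-step; -1 = none
  NumericVector ov_apop = cfg["override_apop"];
  IntegerVector record_at = cfg["record_heights_at"];

  List init = cfg["init"];
  List ik = init["kind"], ild = init["last_div"], ien = init["ecm_n"];
  const int n_col = ik.size();
  std::vector<Col> g(n_col);
  int next_id = 1;
  for (int c = 0; c < n_col; ++c) {
    IntegerVector kk = ik[c]; NumericVector ld = ild[c]; IntegerVector en = ien[c];
    for (int r = 0; r < kk.size(); ++r) {
      double l = (kk[r] == K_SMC && R_finite(ld[r])) ? ld[r] : -1.0;
      int e = (kk[r] == K_SMC && en[r] != NA_INTEGER) ? en[r] : 0;
      g[c].insert(g[c].h(), kk[r], l, e, next_id++);
    }
  }

  Counts ct;
  const int n_metrics = 14;
  NumericMatrix traj(n_steps + 1, n_metrics);
  NumericMatrix hsnap(record_at.size(), n_col);
  int snap_i = 0;

  auto record = [&](int row) {
    long ns = 0, ne = 0, nm = 0, sh = 0;
    for (int c = 0; c < n_col; ++c) {
      sh += g[c].h();
      for (int r = 0; r < g[c].h(); ++r) {
        if (g[c].kind[r] == K_SMC) ++ns;
        else if (g[c].kind[r] == K_ECM) ++ne;
        else ++nm;
      }
    }
    traj(row, 0) = start_h + row * dt;
    traj(row, 1) = ns; traj(row, 2) = ne; traj(row, 3) = nm;
    traj(row, 4) = ns + ne + nm; traj(row, 5) = (double)sh / n_col;
    traj(row, 6) = ct.divisions; traj(row, 7) = ct.apoptoses;
    traj(row, 8) = ct.influx; traj(row, 9) = ct.ecm_sched;
    traj(row, 10) = ct.ecm_burst; traj(row, 11) = ct.ecm_degraded;
    traj(row, 12) = ct.insertions; traj(row, 13) = ct.removals;
    if (snap_i < record_at.size() && record_at[snap_i] == row) {
      for (int c = 0; c < n_col; ++c) hsnap(snap_i, c) = g[c].h();
      ++snap_i;
    }
  };
  record(0);

  std::vector<std::pair<int, int>> events;  // (column, element id)

  for (int step = 1; step <= n_steps; ++step) {
    const double t0 = start_h + (step - 1) * dt;  // probabilities use interval start
    const double t1 = t0 + dt;
    const double td = t0 / 24.0;
    const int ublock = std::min((int)((step - 1) / update_steps),
                                (int)tau_mat.nrow() - 1);
    const double ovd = ov_div.size() ? ov_div[step - 1] : -1.0;
    const double ova = ov_apop.size() ? ov_apop[step - 1] : -1.0;

    // --- division draws on the pre-step grid, top-down per column ---
    events.clear();
    for (int c = 0; c < n_col; ++c) {
      int h = g[c].h();
      if (!h) continue;
      double ts = tau_mat(ublock, c);
      double IT = h * kin.es_mm;
      double cstar = Kin::normalizer(kin.pdiv_mean(ts, td), IT, kin.Dmm);
      for (int r = h - 1; r >= 0; --r) {
        if (g[c].kind[r] != K_SMC) continue;
        double pstep;
        if (ovd >= 0) {
          pstep = ovd;
        } else {
          double dl = (h - 1 - r + 0.5) * kin.es_mm;
          double p = cstar * std::exp(-kin.Dmm * dl);
          if (p > 1.0) { p = 1.0; ct.clip_events++; }
          pstep = dt == 1.0 ? p : 1.0 - std::pow(1.0 - p, dt);
        }
        if (unif_rand() < pstep) events.push_back({c, g[c].id[r]});
      }
    }
    for (auto &ev : events) {
      int c = ev.first, r = g[c].find_id(ev.second);
      if (r < 0) continue;
      g[c].last_div[r] = t1; g[c].ecm_n[r] = 0;  // parent becomes daughter 1
      int did = next_id;
      insert_adjacent(g, c, r, mode1d, K_SMC, t1, 0, next_id);
      ct.divisions++; ct.insertions++;
      int nm = 0;
      if (mono_on) {
        if (macro_plus_one) {
          nm = 1;
        } else {
          // normalized to the maximal entry rate J (unit shear factor) at
          // t = 0; the "same_time" option cancels the time decay
          double ts = tau_mat(ublock, c);
          double mnorm = kin.S(ts) *
                         (mono_baseline_norm ? std::exp(-kin.Kd * td) : 1.0);
          nm = (int)std::floor(2.0 * mnorm + 0.5);
        }
      }
      int daughters[2] = {ev.second, did};
      for (int dgt = 0; dgt < 2; ++dgt) {
        for (int k = 0; k < nm; ++k) {
          int cc = -1, rr = -1;
          for (int c2 = std::max(0, c - 1); c2 <= std::min(n_col - 1, c + 1) && cc < 0; ++c2) {
            int r2 = g[c2].find_id(daughters[dgt]);
            if (r2 >= 0) { cc = c2; rr = r2; }
          }
          if (cc < 0) { cc = c; rr = g[c].find_id(ev.second); }
          insert_adjacent(g, cc, rr, mode1d, K_ECM, -1.0, 0, next_id);
          ct.ecm_burst++; ct.insertions++;
        }
      }
    }

    // --- scheduled matrix production at 24 h and 48 h post-division ---
    events.clear();
    for (int c = 0; c < n_col; ++c)
      for (int r = g[c].h() - 1; r >= 0; --r) {
        if (g[c].kind[r] != K_SMC || g[c].last_div[r] < 0) continue;
        double el = t1 - g[c].last_div[r];
        if ((std::fabs(el - 24.0) < 1e-9 && g[c].ecm_n[r] == 0) ||
            (std::fabs(el - 48.0) < 1e-9 && g[c].ecm_n[r] == 1))
          events.push_back({c, g[c].id[r]});
      }
    for (auto &ev : events) {
      int c = ev.first, r = g[c].find_id(ev.second);
      if (r < 0) continue;
      g[c].ecm_n[r]++;
      insert_adjacent(g, c, r, mode1d, K_ECM, -1.0, 0, next_id);
      ct.ecm_sched++; ct.insertions++;
    }

    // --- apoptosis draws; each death degrades the 4 nearest ECM ---
    events.clear();
    for (int c = 0; c < n_col; ++c) {
      int h = g[c].h();
      if (!h) continue;
      double ts = tau_mat(ublock, c);
      double IT = h * kin.es_mm;
      double gstar = Kin::normalizer(kin.papop_mean(ts, td), IT, kin.Hmm);
      for (int r = h - 1; r >= 0; --r) {
        if (g[c].kind[r] != K_SMC) continue;
        if (g[c].last_div[r] == t1) continue;  // divided/born this step
        double pstep;
        if (ova >= 0) {
          pstep = ova;
        } else {
          double dout = (r + 0.5) * kin.es_mm;
          double p = gstar * std::exp(-kin.Hmm * dout);
          if (p > 1.0) { p = 1.0; ct.clip_events++; }
          pstep = dt == 1.0 ? p : 1.0 - std::pow(1.0 - p, dt);
        }
        if (unif_rand() < pstep) events.push_back({c, g[c].id[r]});
      }
    }
    for (auto &ev : events) {
      int c = ev.first, r = g[c].find_id(ev.second);
      if (r < 0) continue;
      std::vector<EcmTarget> doomed = nearest_ecm(g, c, r, 4);
      std::vector<std::pair<int, int>> pos;
      pos.push_back({c, r});
      for (auto &d : doomed) pos.push_back({d.c, d.r});
      std::sort(pos.begin(), pos.end(), [](const std::pair<int, int> &a,
                                           const std::pair<int, int> &b) {
        return a.first != b.first ? a.first < b.first : a.second > b.second;
      });
      for (auto &p : pos) g[p.first].erase(p.second);
      ct.apoptoses++; ct.ecm_degraded += (long)doomed.size();
      ct.removals += 1 + (long)doomed.size();
    }

    // --- monocyte influx: Poisson per column on intimal area ---
    if (mono_on) {
      for (int c = 0; c < n_col; ++c) {
        int h = g[c].h();
        if (!h) continue;
        double ts = tau_mat(ublock, c);
        // entry flux through the column's luminal surface patch (es^2 mm^2);
        // optionally through the growing cross-section (h * es^2)
        double base_area = kin.es_mm * kin.es_mm * (influx_surface ? 1.0 : h);
        double lam = kin.influx(ts, td) * base_area * dt;
        int k = (int)R::rpois(lam);
        for (int i = 0; i < k; ++i) {
          int pos = runif_int(g[c].h() + 1);
          g[c].insert(pos, K_MONO, -1.0, 0, next_id++);
          ct.influx++; ct.insertions++;
        }
      }
    }

    redistribute_sweeps(g, ct, mode1d);
    record(step);
  }

  List fk(n_col), fld(n_col), fen(n_col);
  for (int c = 0; c < n_col; ++c) {
    fk[c] = IntegerVector(g[c].kind.begin(), g[c].kind.end());
    NumericVector ld(g[c].h());
    IntegerVector en(g[c].h());
    for (int r = 0; r < g[c].h(); ++r) {
      ld[r] = (g[c].kind[r] == K_SMC && g[c].last_div[r] >= 0)
                  ? g[c].last_div[r] : NA_REAL;
      en[r] = g[c].kind[r] == K_SMC ? g[c].ecm_n[r] : NA_INTEGER;
    }
    fld[c] = ld; fen[c] = en;
  }
  return List::create(
      _["trajectory"] = traj, _["heights"] = hsnap,
      _["final"] = List::create(_["kind"] = fk, _["last_div"] = fld,
                                _["ecm_n"] = fen),
      _["clip_events"] = (double)ct.clip_events,
      _["redist_moves"] = (double)ct.redist_moves);
}

// Kinetic quantities as computed by the simulation core, for cross-checks
// against the R implementations.
// [[Rcpp::export]]
NumericVector cpp_kinetics_check(double tau_star, double t_days, double IT_mm,
                                 List params) {
  Kin kin = kin_from_list(params);
  double pd = kin.pdiv_mean(tau_star, t_days);
  double pa = kin.papop_mean(tau_star, t_days);
  return NumericVector::create(
      _["brdu"] = kin.brdu(tau_star, t_days),
      _["tunel"] = kin.tunel(tau_star, t_days),
      _["p_div_mean"] = pd, _["p_apop_mean"] = pa,
      _["cstar"] = Kin::normalizer(pd, IT_mm, kin.Dmm),
      _["gstar"] = Kin::normalizer(pa, IT_mm, kin.Hmm),
      _["influx"] = kin.influx(tau_star, t_days));
}

// Height-only redistribution, for cross-checks against the R version.
// [[Rcpp::export]]
IntegerVector cpp_redistribute_heights(IntegerVector heights) {
  std::vector<Col> g(heights.size());
  int next_id = 1;
  for (int c = 0; c < heights.size(); ++c)
    for (int i = 0; i < heights[c]; ++i)
      g[c].insert(g[c].h(), K_ECM, -1.0, 0, next_id++);
  Counts ct;
  redistribute_sweeps(g, ct, false);
  IntegerVector out(heights.size());
  for (int c = 0; c < heights.size(); ++c) out[c] = g[c].h();
  return out;
}

// Squared grid-index distances of the `count` ECM elements the core would
// degrade around (column, row); 1-based inputs from R.
// [[Rcpp::export]]
NumericVector cpp_nearest_ecm_distances(List kind_cols, int column, int row,
                                        int count) {
  RNGScope rng;
  std::vector<Col> g(kind_cols.size());
  int next_id = 1;
  for (int c = 0; c < kind_cols.size(); ++c) {
    IntegerVector kk = kind_cols[c];
    for (int r = 0; r < kk.size(); ++r)
      g[c].insert(g[c].h(), kk[r], -1.0, 0, next_id++);
  }
  std::vector<EcmTarget> sel = nearest_ecm(g, column - 1, row - 1, count);
  NumericVector out(sel.size());
  for (size_t i = 0; i < sel.size(); ++i) out[i] = sel[i].d2;
  return out;
}
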