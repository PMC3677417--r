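// Exact event-driven (Gillespie) simulators for protofilament growth,
// GTP hydrolysis and catastrophe. Uses the R RNG so set.seed() governs
// reproducibility. Lattice state: 1 = GTP, 0 = GDP; index 0 is the subunit
// just above the stable (non-hydrolyzable, non-dissociating) seed; the last
// element is the terminal (tip) subunit.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// mechanism codes
enum { MECH_COUPLED = 0, MECH_VECTORIAL = 1, MECH_RANDOM = 2, MECH_COUPLED_RANDOM = 3 };
// catastrophe-rule codes
enum { RULE_TERMINAL_GDP = 0, RULE_N_TERMINAL_GDP = 1, RULE_TOTAL_DEPOL = 2,
       RULE_CAP_LOSS = 3, RULE_NONE = 4 };
// event codes (exported in trajectories)
enum { EV_ADD = 1, EV_DISS = 2, EV_HYD = 3, EV_CASCADE = 4 };
// termination codes
enum { TERM_CATASTROPHE = 0, TERM_CENSORED_TIME = 1, TERM_CENSORED_LENGTH = 2 };

static inline bool rule_fires(int rule, int rule_N, const std::vector<char>& st) {
  const int len = (int) st.size();
  switch (rule) {
  case RULE_TERMINAL_GDP:
    return len >= 1 && st[len - 1] == 0;
  case RULE_N_TERMINAL_GDP: {
    if (len < rule_N) return false;
    for (int i = len - rule_N; i < len; ++i) if (st[i] != 0) return false;
    return true;
  }
  case RULE_TOTAL_DEPOL:
    return len == 0;           // back to the seed (checked after events only)
  case RULE_CAP_LOSS:
    return len == 0 || st[len - 1] == 0;  // terminal GTP run has length 0
  default:
    return false;
  }
}

// [[Rcpp::export]]
List cpp_sim_filament(double r, double kT, double kD, bool kD_inf, double h,
                      int mech, int rule, int rule_N,
                      double t_max, int length_max, bool record) {
  std::vector<char> st;            // lattice above the seed
  st.reserve(1024);
  int g = 0;                       // number of GTP subunits
  int front = 0;                   // vectorial: all below 'front' are GDP
  double t = 0.0;
  int status = TERM_CENSORED_TIME;

  std::vector<double> rec_t;
  std::vector<int> rec_len, rec_ev, rec_tip;
  if (record) { rec_t.reserve(1024); rec_len.reserve(1024);
                rec_ev.reserve(1024); rec_tip.reserve(1024); }
  auto rec = [&](int ev) {
    if (!record) return;
    rec_t.push_back(t);
    rec_len.push_back((int) st.size());
    rec_ev.push_back(ev);
    rec_tip.push_back(st.empty() ? -1 : (int) st.back());
  };

  bool done = false;
  while (!done) {
    const int len = (int) st.size();
    // event rates
    double rate_add = r;
    double rate_diss = 0.0;
    if (len >= 1) rate_diss = (st[len - 1] == 1) ? kT : (kD_inf ? 0.0 : kD);
    double rate_hyd = 0.0;
    switch (mech) {
    case MECH_COUPLED: break;
    case MECH_VECTORIAL: rate_hyd = (front < len) ? h : 0.0; break;
    case MECH_RANDOM: rate_hyd = h * g; break;
    case MECH_COUPLED_RANDOM: {
      int elig = g - ((len >= 1 && st[len - 1] == 1) ? 1 : 0);
      rate_hyd = h * elig; break;
    }
    }
    const double total = rate_add + rate_diss + rate_hyd;
    if (total <= 0.0) { t = t_max; status = TERM_CENSORED_TIME; break; }
    t += R::exp_rand() / total;
    if (t >= t_max) { t = t_max; status = TERM_CENSORED_TIME; break; }

    const double u = R::unif_rand() * total;
    if (u < rate_add) {
      if (mech == MECH_COUPLED && len >= 1 && st[len - 1] == 1) {
        st[len - 1] = 0; --g;      // burial hydrolyzes the previous terminal
      }
      st.push_back(1); ++g;
      rec(EV_ADD);
    } else if (u < rate_add + rate_diss) {
      if (st[len - 1] == 1) --g;
      st.pop_back();
      if (front > (int) st.size()) front = (int) st.size();
      rec(EV_DISS);
    } else {
      // hydrolysis
      if (mech == MECH_VECTORIAL) {
        st[front] = 0; --g; ++front;
      } else {
        // pick a GTP subunit uniformly (coupled_random: excluding terminal)
        int elig = g;
        int start = len - 1;
        if (mech == MECH_COUPLED_RANDOM) {
          if (st[len - 1] == 1) --elig;
          start = len - 2;
        }
        int j = (int) (R::unif_rand() * elig);
        if (j >= elig) j = elig - 1;
        for (int i = start; i >= 0; --i) {
          if (st[i] == 1) {
            if (j == 0) { st[i] = 0; --g; break; }
            --j;
          }
        }
      }
      rec(EV_HYD);
    }

    // rule check, then instantaneous GDP-terminal removal cascade (kD -> Inf)
    if (rule_fires(rule, rule_N, st)) { status = TERM_CATASTROPHE; break; }
    if (kD_inf) {
      while (!st.empty() && st.back() == 0) {
        st.pop_back();
        if (front > (int) st.size()) front = (int) st.size();
        rec(EV_CASCADE);
        if (rule_fires(rule, rule_N, st)) { status = TERM_CATASTROPHE; done = true; break; }
      }
      if (done) break;
    }
    if ((int) st.size() >= length_max) { status = TERM_CENSORED_LENGTH; break; }
  }

  // final lattice state, tip first
  IntegerVector state((int) st.size());
  for (int i = 0; i < (int) st.size(); ++i) state[i] = st[(int) st.size() - 1 - i];

  return List::create(
    _["t_end"] = t, _["status"] = status, _["length_end"] = (int) st.size(),
    _["state"] = state,
    _["times"] = rec_t, _["lengths"] = rec_len,
    _["events"] = rec_ev, _["tip_gtp"] = rec_tip);
}

// Mechanistic multi-protofilament lifetime simulator: n_pf independent
// coupled-random protofilaments; a protofilament destabilizes permanently
// (and is frozen) the first time its terminal subunit dissociates while the
// subterminal subunit is GDP; the lifetime is the time of the n_steps-th
// destabilization. An optional growth phase (rate r_grow for t_grow, with
// destabilization suppressed) prepares a stationary lattice before the clock
// starts, for dilution experiments; m_init destabilizations may be carried in.
// [[Rcpp::export]]
List cpp_sim_multipf(double r_pf, double k_pf, double kD_pf, bool kD_inf,
                     double h, int n_pf, int n_steps, double t_max,
                     double r_grow, double t_grow, int m_init) {
  const int n_active0 = n_pf - m_init;
  std::vector< std::vector<char> > pf(n_active0);
  std::vector<int> g(n_active0, 0);       // GTP count per protofilament
  std::vector<bool> active(n_active0, true);
  for (int q = 0; q < n_active0; ++q) pf[q].reserve(512);

  int n_destab = m_init;
  double t = 0.0;
  bool grow_phase = t_grow > 0.0;
  double r_cur = grow_phase ? r_grow : r_pf;
  double lifetime = NA_REAL;
  bool censored = false;

  auto strip_gdp_tip = [&](int q) {
    // remove a GDP terminal run (suppressed-phase bookkeeping / kD infinite)
    while (!pf[q].empty() && pf[q].back() == 0) pf[q].pop_back();
  };

  std::vector<double> rq(n_active0, 0.0);
  while (true) {
    // per-protofilament rates
    double total = 0.0;
    for (int q = 0; q < n_active0; ++q) {
      rq[q] = 0.0;
      if (!active[q]) continue;
      const int len = (int) pf[q].size();
      double diss = 0.0;
      if (len >= 1) diss = (pf[q][len - 1] == 1) ? k_pf : (kD_inf ? 0.0 : kD_pf);
      int elig = g[q] - ((len >= 1 && pf[q][len - 1] == 1) ? 1 : 0);
      rq[q] = r_cur + diss + h * elig;
      total += rq[q];
    }
    if (total <= 0.0) { censored = !grow_phase; break; }
    const double dt = R::exp_rand() / total;

    if (grow_phase && t + dt >= t_grow) {
      // growth phase over: reset the clock, switch to post rates, and clean
      // any transient GDP terminals so phase-B terminals are GTP
      grow_phase = false;
      r_cur = r_pf;
      t = 0.0;
      for (int q = 0; q < n_active0; ++q) if (active[q]) {
        int before = (int) pf[q].size();
        strip_gdp_tip(q);
        (void) before;
        // recount GTP (strip removed only GDP, g unchanged)
      }
      continue;
    }
    t += dt;
    if (!grow_phase && t >= t_max) { censored = true; break; }

    // choose protofilament, then event
    double u = R::unif_rand() * total;
    int q = 0;
    for (; q < n_active0; ++q) {
      if (!active[q]) continue;
      if (u < rq[q]) break;
      u -= rq[q];
    }
    if (q >= n_active0) q = n_active0 - 1;  // numeric guard

    std::vector<char>& s = pf[q];
    const int len = (int) s.size();
    double diss = 0.0;
    if (len >= 1) diss = (s[len - 1] == 1) ? k_pf : (kD_inf ? 0.0 : kD_pf);

    if (u < r_cur) {
      s.push_back(1); ++g[q];
    } else if (u < r_cur + diss) {
      const bool tip_gtp = s[len - 1] == 1;
      const bool sub_gdp = (len >= 2) && (s[len - 2] == 0);
      if (tip_gtp) --g[q];
      s.pop_back();
      if (!grow_phase && tip_gtp && sub_gdp) {
        // destabilizing event: freeze this protofilament
        active[q] = false;
        if (++n_destab >= n_steps) { lifetime = t; break; }
      } else if (grow_phase && sub_gdp) {
        // suppressed: shed the exposed GDP run, keep the lattice growing
        while (!s.empty() && s.back() == 0) s.pop_back();
      } else if (!grow_phase && !tip_gtp) {
        // GDP terminal (finite kD path): plain removal, then cascade if inf
        if (kD_inf) strip_gdp_tip(q);
      }
    } else {
      // hydrolysis of a uniformly chosen non-terminal GTP subunit
      int elig = g[q] - ((len >= 1 && s[len - 1] == 1) ? 1 : 0);
      if (elig > 0) {
        int j = (int) (R::unif_rand() * elig);
        if (j >= elig) j = elig - 1;
        for (int i = len - 2; i >= 0; --i) {
          if (s[i] == 1) {
            if (j == 0) { s[i] = 0; --g[q]; break; }
            --j;
          }
        }
      }
    }
  }

  return List::create(_["lifetime"] = lifetime, _["censored"] = censored,
                      _["n_destab"] = n_destab);
}

// Time-weighted probability that the subterminal subunit of a single
// coupled-random protofilament is GDP, over a long simulated run. A filament
// that shrinks back to the seed keeps growing from a fresh GTP seed
// (restart counted). Subunits below length 2 sit on the stable seed and
// count as non-GDP.
// [[Rcpp::export]]
List cpp_subterminal_occupancy(double r, double k, double kD, bool kD_inf,
                               double h, double t_total, int init_len) {
  std::vector<char> st; st.reserve(1024);
  for (int i = 0; i < init_len; ++i) st.push_back(1);
  int g = init_len;
  double t = 0.0, t_gdp = 0.0;
  long n_events = 0, n_restart = 0;
  bool was_empty = true;

  while (t < t_total) {
    const int len = (int) st.size();
    double rate_diss = 0.0;
    if (len >= 1) rate_diss = (st[len - 1] == 1) ? k : (kD_inf ? 0.0 : kD);
    int elig = g - ((len >= 1 && st[len - 1] == 1) ? 1 : 0);
    const double total = r + rate_diss + h * elig;
    if (total <= 0.0) break;   // e.g. r = 0 and the filament is gone
    double dt = R::exp_rand() / total;
    if (t + dt > t_total) dt = t_total - t;
    const bool sub_gdp = (len >= 2) && (st[len - 2] == 0);
    if (sub_gdp) t_gdp += dt;
    t += dt;
    if (t >= t_total) break;
    ++n_events;

    const double u = R::unif_rand() * total;
    if (u < r) {
      st.push_back(1); ++g;
    } else if (u < r + rate_diss) {
      if (st[len - 1] == 1) --g;
      st.pop_back();
      if (kD_inf) while (!st.empty() && st.back() == 0) st.pop_back();
      if (st.empty() && !was_empty) ++n_restart;
    } else if (elig > 0) {
      int j = (int) (R::unif_rand() * elig);
      if (j >= elig) j = elig - 1;
      for (int i = len - 2; i >= 0; --i) {
        if (st[i] == 1) {
          if (j == 0) { st[i] = 0; --g; break; }
          --j;
        }
      }
    }
    was_empty = st.empty();
  }

  return List::create(_["p_gdp"] = t_gdp / (t > 0 ? t : t_total),
                      _["n_events"] = (double) n_events,
                      _["n_restarts"] = (double) n_restart);
}
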