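// Agent-level stochastic simulator for hESC endoderm induction.
//
// Each cell carries a signalling-regime flag (Omega = active, A = quiescent),
// an affinity 'a' that decays geometrically in Omega and gates both regime
// transfer and proliferation competence, an age / lifespan pair, a cell-cycle
// clock (G1 gating), a senescence window, and per-lineage commitment
// propensities. The engine advances the whole population in fixed steps of
// dt hours and records daily snapshots of live counts per phenotype,
// cumulative death and cumulative divisions.
//
// A self-contained xoshiro256** generator (seeded via splitmix64, one
// independent stream per replicate run) is used instead of R's RNG so that
// replicate streams are reproducible and pairable (common random numbers
// between nominal and perturbed runs of the sensitivity analysis).

#include <Rcpp.h>
#include <cstdint>
#include <vector>

namespace {

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256 {
  uint64_t s[4];
  void seed(uint64_t v) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(v);
    if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 1;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform on (0, 1]
  inline double unif_pos() { return 1.0 - unif(); }
};

struct Cell {
  double a;       // regime affinity, > 0
  double age;     // hours (advances in Omega only)
  double life;    // assigned maximum lifespan, hours
  double cyc;     // position within the cell cycle, [0, t_cycle)
  double window;  // proliferation window before senescence, hours
  double clock;   // hours spent proliferation-competent
  double p0, p1, p2;  // lineage propensities (slots depend on stage/mechanism)
  uint8_t regime;     // 0 = Omega, 1 = A
  uint8_t phen;       // 0 hESC, 1 ME, 2 VE, 3 DE, 4 MESO
  uint8_t stage;      // 1 or 2
  uint8_t competent;  // latched true once a first falls below a_min
};

struct Pars {
  double a_min, a0max, a0max2, x_com, x_com2, d, t_g1, t_cycle;
  double l_min, l_max, w_max, aa, n_scale, dt;
};

Rcpp::NumericMatrix cells_to_matrix(const std::vector<Cell> &cells) {
  const int n = (int)cells.size();
  Rcpp::NumericMatrix m(n, 13);
  for (int i = 0; i < n; ++i) {
    const Cell &c = cells[i];
    m(i, 0) = c.a;
    m(i, 1) = c.age;
    m(i, 2) = c.life;
    m(i, 3) = c.cyc;
    m(i, 4) = c.window;
    m(i, 5) = c.clock;
    m(i, 6) = c.p0;
    m(i, 7) = c.p1;
    m(i, 8) = c.p2;
    m(i, 9) = c.regime;
    m(i, 10) = c.phen;
    m(i, 11) = c.stage;
    m(i, 12) = c.competent;
  }
  Rcpp::colnames(m) = Rcpp::CharacterVector::create(
      "a_value", "age", "life_span", "cycle_position", "proliferation_window",
      "proliferation_clock", "prop1", "prop2", "prop3", "regime", "phenotype",
      "stage", "proliferation_competent");
  return m;
}

}  // namespace

// [[Rcpp::export(name = ".sim_engine")]]
Rcpp::List sim_engine(int n_initial, int n_runs, int n_steps, int obs_every,
                      double a_min, double a0max, double a0max2, double x_com,
                      double x_com2, double d, double t_g1, double t_cycle,
                      double l_min, double l_max, double w_max, double aa,
                      double n_scale, double dt, Rcpp::IntegerVector s1_phen,
                      Rcpp::NumericVector s1_nprog,
                      Rcpp::IntegerVector s2_phen,
                      Rcpp::NumericVector s2_nprog,
                      Rcpp::LogicalVector prolif_allowed, double seed,
                      bool check_invariants, bool return_cells) {
  const Pars p = {a_min, a0max, a0max2, x_com,   x_com2,  d,  t_g1,
                  t_cycle, l_min, l_max, w_max, aa, n_scale, dt};
  const int n1 = s1_phen.size();
  const int n2 = s2_phen.size();
  int s1p[3] = {0, 0, 0}, s2p[3] = {0, 0, 0};
  double s1n[3] = {0, 0, 0}, s2n[3] = {0, 0, 0};
  for (int j = 0; j < n1; ++j) { s1p[j] = s1_phen[j]; s1n[j] = s1_nprog[j]; }
  for (int j = 0; j < n2; ++j) { s2p[j] = s2_phen[j]; s2n[j] = s2_nprog[j]; }
  bool prolif[5];
  for (int j = 0; j < 5; ++j) prolif[j] = prolif_allowed[j] != 0;

  // exploration and increment scales of the propensity update, tied to the
  // stage commitment threshold so the threshold sets the propensity unit
  const double eps1 = 0.01 * p.x_com, del1 = 0.01 * p.x_com;
  const double eps2 = 0.01 * p.x_com2, del2 = 0.01 * p.x_com2;

  const int n_days = n_steps / obs_every + 1;
  Rcpp::NumericMatrix out(n_runs * n_days, 11);
  Rcpp::LogicalVector extinct(n_runs);
  Rcpp::NumericMatrix init_cells, final_cells;

  const uint64_t master = (uint64_t)seed;
  std::vector<Cell> cells;
  std::vector<Cell> born;
  Xoshiro256 xo;

  for (int run = 0; run < n_runs; ++run) {
    xo.seed(master + (uint64_t)(run + 1) * 0x9E3779B97F4A7C15ULL);
    cells.clear();
    cells.reserve((size_t)n_initial * 2);
    for (int i = 0; i < n_initial; ++i) {
      Cell c;
      c.a = p.a0max * xo.unif_pos();
      c.age = 0.0;
      c.life = p.l_min + (p.l_max - p.l_min) * xo.unif();
      c.cyc = p.t_cycle * xo.unif();
      c.window = p.w_max * xo.unif_pos();
      c.clock = 0.0;
      c.p0 = c.p1 = c.p2 = 0.0;
      c.regime = 0;
      c.phen = 0;
      c.stage = 1;
      c.competent = 0;
      cells.push_back(c);
    }
    if (return_cells && run == 0) init_cells = cells_to_matrix(cells);

    long cum_dead = 0, cum_div = 0;
    int obs_row = run * n_days;
    int day_idx = 0;

    // snapshot lambda
    auto record = [&](int day) {
      long cnt[5] = {0, 0, 0, 0, 0};
      long in_a = 0;
      for (const Cell &c : cells) {
        ++cnt[c.phen];
        if (c.regime == 1) ++in_a;
      }
      const int r = obs_row + day;
      out(r, 0) = run + 1;
      out(r, 1) = day * obs_every * p.dt / 24.0;
      out(r, 2) = (double)cells.size();
      out(r, 3) = (double)cum_dead;
      out(r, 4) = (double)cum_div;
      out(r, 5) = (double)cnt[0];
      out(r, 6) = (double)cnt[1];
      out(r, 7) = (double)cnt[2];
      out(r, 8) = (double)cnt[3];
      out(r, 9) = (double)cnt[4];
      out(r, 10) = (double)in_a;
      if (check_invariants) {
        if ((long)cells.size() + cum_dead - cum_div != (long)n_initial)
          Rcpp::stop("conservation violated: live + dead - divisions != initial");
        for (const Cell &c : cells) {
          if (!(c.a > 0)) Rcpp::stop("invariant violated: a_value <= 0");
          if (c.regime == 1 && c.a < p.a_min)
            Rcpp::stop("invariant violated: cell below a_min in regime A");
          if (c.competent && c.a >= p.a_min)
            Rcpp::stop("invariant violated: competent cell with a >= a_min");
          if (c.phen <= 1) {  // uncommitted at current stage
            const double thr = (c.stage == 1) ? p.x_com : p.x_com2;
            if (c.p0 >= thr || c.p1 >= thr || c.p2 >= thr)
              Rcpp::stop("invariant violated: uncommitted propensity at threshold");
          }
          if (c.stage == 2 && c.phen != 1 && c.phen != 3 && c.phen != 4)
            Rcpp::stop("invariant violated: stage-2 cell with stage-1 phenotype");
        }
      }
    };

    record(day_idx++);

    for (int step = 1; step <= n_steps; ++step) {
      // regime totals frozen at the start of the step
      long n_omega = 0;
      for (const Cell &c : cells)
        if (c.regime == 0) ++n_omega;
      const long n_a = (long)cells.size() - n_omega;
      const double f_a = 1.0 / (1.0 + (double)n_a / p.n_scale);
      const double f_omega = 1.0 / (1.0 + (double)n_omega / p.n_scale);

      size_t i = 0;
      while (i < cells.size()) {
        Cell &c = cells[i];
        if (c.regime == 1) {
          // A regime: quiescent; only possible event is return to Omega
          const double q = (p.a_min / c.a) * f_omega;
          if (q >= 1.0 || xo.unif() < q) c.regime = 0;
          ++i;
          continue;
        }
        // --- Omega regime ---
        // affinity decay; crossing a_min latches proliferation competence
        c.a /= p.d;
        if (!c.competent && c.a < p.a_min) {
          c.competent = 1;
          c.clock = 0.0;
        }
        const bool in_g1 = c.cyc < p.t_g1;
        // Omega -> A transfer: G1-gated, impossible once below a_min
        if (in_g1 && c.a >= p.a_min) {
          const double norm = (c.stage == 1) ? p.a0max : p.a0max2;
          const double prob = p.aa * (c.a / norm) * f_a;
          if (prob >= 1.0 || xo.unif() < prob) {
            c.regime = 1;
            if (c.phen <= 1) {  // uncommitted propensities converge to mean
              const int nl = (c.stage == 1) ? n1 : n2;
              double m = c.p0 + c.p1 + ((nl == 3) ? c.p2 : 0.0);
              m /= (double)nl;
              c.p0 = m;
              c.p1 = m;
              if (nl == 3) c.p2 = m;
            }
            ++i;
            continue;  // frozen in A for the rest of the step
          }
        }
        // propensity update and commitment check (uncommitted cells, G1 only)
        if (in_g1 && c.phen <= 1) {
          const bool st1 = (c.stage == 1);
          const int nl = st1 ? n1 : n2;
          const int *lin = st1 ? s1p : s2p;
          const double *npr = st1 ? s1n : s2n;
          const double eps = st1 ? eps1 : eps2;
          const double del = st1 ? del1 : del2;
          const double thr = st1 ? p.x_com : p.x_com2;
          const double w0 = c.p0 + eps;
          const double w1 = c.p1 + eps;
          const double w2 = (nl == 3) ? (c.p2 + eps) : 0.0;
          const double u = xo.unif() * (w0 + w1 + w2);
          const int j = (u < w0) ? 0 : ((u < w0 + w1) ? 1 : 2);
          double *pj = (j == 0) ? &c.p0 : ((j == 1) ? &c.p1 : &c.p2);
          *pj += del * npr[j];
          if (*pj >= thr) {
            const int newphen = lin[j];
            if (newphen == 1) {
              // mesendoderm commitment: enter stage 2, re-initialise
              c.phen = 1;
              c.stage = 2;
              c.a = p.a0max2 * xo.unif_pos();
              c.competent = 0;
              c.clock = 0.0;
              c.p0 = c.p1 = c.p2 = 0.0;
            } else {
              c.phen = (uint8_t)newphen;  // terminal; propensities frozen
            }
          }
        }
        // ageing and death
        c.age += p.dt;
        if (c.age > c.life) {
          ++cum_dead;
          c = cells.back();
          cells.pop_back();
          continue;  // reprocess the swapped-in cell at index i
        }
        // cell cycle and division
        c.cyc += p.dt;
        if (c.competent) c.clock += p.dt;
        if (c.cyc >= p.t_cycle) {
          c.cyc -= p.t_cycle;
          if (c.competent && c.clock <= c.window && prolif[c.phen]) {
            Cell dtr = c;  // daughter inherits phenotype, stage, propensities, a
            dtr.age = 0.0;
            dtr.cyc = 0.0;
            dtr.clock = 0.0;
            dtr.life = p.l_min + (p.l_max - p.l_min) * xo.unif();
            dtr.window = p.w_max * xo.unif_pos();
            born.push_back(dtr);
            ++cum_div;
          }
        }
        ++i;
      }
      if (!born.empty()) {
        cells.insert(cells.end(), born.begin(), born.end());
        born.clear();
      }
      if (step % obs_every == 0) record(day_idx++);
      if (cells.empty()) {
        extinct[run] = true;
        while (day_idx < n_days) {
          const int r = obs_row + day_idx;
          out(r, 0) = run + 1;
          out(r, 1) = day_idx * obs_every * p.dt / 24.0;
          out(r, 2) = 0.0;
          out(r, 3) = (double)cum_dead;
          out(r, 4) = (double)cum_div;
          for (int k = 5; k <= 10; ++k) out(r, k) = 0.0;
          ++day_idx;
        }
        break;
      }
    }
    if (return_cells && run == 0) final_cells = cells_to_matrix(cells);
  }

  Rcpp::colnames(out) = Rcpp::CharacterVector::create(
      "run", "day", "live_count", "cumulative_dead", "divisions", "n_hesc",
      "n_mesendoderm", "n_visceral_endoderm", "n_definitive_endoderm",
      "n_mesoderm", "n_regime_a");
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("trajectories") = out,
                                      Rcpp::Named("extinct") = extinct);
  if (return_cells) {
    res["initial_cells"] = init_cells;
    res["final_cells"] = final_cells;
  }
  return res;
}
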