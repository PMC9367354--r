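// Weekly-step stochastic dairy herd engine.
//
// The engine is an individual-based simulation of cows and young stock on a
// 52-week annual grid. All stochastic draws come from a counter-based RNG
// keyed by (seed, global week, animal id, purpose), so that two runs that
// differ only in one calibration parameter share the randomness of every
// event that both runs evaluate ("common random numbers" across paired
// scenarios), and identical (params, seed) give bit-identical output.
//
// Event order within a week (documented contract of step_week()):
//   1. disease onset draws (weekly hazards) + one-time death/cull risk bumps
//   2. milk yield accrual (potential curve minus active-disease losses), feed
//   3. oestrus / insemination / conception (21-day cycle on the weekly grid)
//   4. gestation advance; calving at 40 weeks (dystocia, stillbirth, calf)
//   5. base mortality and culling draws; do-not-breed cull at late lactation
//   6. disease episode expiry; week-in-milk advance
//   7. young-stock aging: rearing mortality windows, bull-calf sale, heifer
//      breeding, pregnant-heifer sale decision, first calving (herd entry)
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

// ---- counter-based RNG (splitmix64 finalizer chain) -----------------------
inline uint64_t sm64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

inline double u01(uint64_t seed, uint64_t week, uint64_t id, uint64_t purpose) {
  uint64_t z = sm64(seed);
  z = sm64(z ^ week);
  z = sm64(z ^ id);
  z = sm64(z ^ purpose);
  // (0,1) open interval
  return ((z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// purpose codes (per disease d in 0..5 the onset draw is purpose d)
enum Purpose {
  P_DEATH = 10, P_CULL = 11, P_HEAT = 12, P_CONC = 13, P_DYST = 14,
  P_STILL = 15, P_SEX = 16, P_EARLY = 17, P_LATE = 18,
  P_DIS_DEATH = 19, P_DIS_CULL = 20, P_INIT = 21
};

const int N_DIS = 6;  // 0 milk_fever, 1 dystocia, 2 metritis, 3 ketosis,
                      // 4 mastitis, 5 lameness (dystocia drawn at calving)

struct Cow {
  uint64_t id;
  int parity;        // >= 1
  int wim;           // weeks in milk (since last calving)
  int status;        // 0 open, 1 pregnant, 2 do-not-breed
  int wp;            // weeks pregnant
  int phase;         // oestrus cycle phase in 0..2
  int dis_rem[N_DIS];
  int prev_calv_week;  // global week of previous calving, -1 if none
  bool alive;
};

struct Young {
  uint64_t id;
  int age;           // weeks
  bool female;
  int status;        // 0 open/rearing, 1 pregnant, 2 kept (pregnant, retained)
  int wp;
  int phase;
  bool alive;
};

struct Params {
  int n_target;
  int years, burn_in;
  // yield[class][wim], loss_weekly[class][dis]; class 0..2 = parity 1,2,3+
  std::vector<std::vector<double> > yield;       // 3 x n_yield_weeks
  double loss_weekly[3][N_DIS];
  double conc_mult[N_DIS], add_mort[N_DIS], add_cull[N_DIS], hazard[N_DIS];
  int duration[N_DIS];
  double dyst_target;        // cases per cow-year (I/100)
  double ci_weeks_guess;     // prior calvings spacing for adaptive dystocia q
  double p_stillbirth;       // marginal probability per calving
  double dyst_sb_mult, dyst_cow_mort;
  double h_cow_mort, h_cull; // weekly
  int elig_week_cow, dnb_week, cull_dnb_week, gestation, dry_wp, cycle;
  double ho_cow, cr_cow, ho_heif, cr_heif;
  int h_elig_week, h_fail_week;
  double h_early, h_late;    // weekly within the respective windows
  int early_lo, early_hi, late_lo, late_hi;
  double sex_ratio_female;
  double maint_sfu_day, sfu_per_kg, heifer_sfu_day, powder_kg_day;
  double cow_weight, heifer_weight;
  int male_sale_age, powder_until_age, sell_decision_wp;
};

enum Col {
  C_YEAR = 0, C_WEEK, C_COWS_START, C_COWS_END, C_COW_WEEKS, C_HEIFER_WEEKS,
  C_KG_ECM,
  C_CASE0, C_CASE1, C_CASE2, C_CASE3, C_CASE4, C_CASE5,
  C_CALVINGS, C_FIRST_CALVINGS, C_STILLBIRTHS,
  C_LIVE_F, C_LIVE_M, C_DEATH_EARLY, C_DEATH_LATE,
  C_COW_DEATHS, C_COWS_SLAUGHTERED, C_SLAUGHTER_KG_COWS,
  C_HEIFERS_SLAUGHTERED, C_SLAUGHTER_KG_HEIFERS,
  C_HEIFERS_SOLD_PREGNANT, C_HEIFERS_SOLD_OPEN,
  C_INS_COWS, C_INS_HEIFERS, C_CONC_COWS, C_CONC_HEIFERS,
  C_HEAT_ELIG_COWS, C_HEAT_DET_COWS, C_HEAT_ELIG_HEIFERS, C_HEAT_DET_HEIFERS,
  C_FEED_SFU_COWS, C_FEED_SFU_HEIFERS, C_POWDER_KG, C_BULL_CALVES_SOLD,
  C_CI_SUM_DAYS, C_CI_N, C_AFC_SUM_WEEKS, C_AFC_N,
  N_COL
};

struct Acc {
  double v[N_COL];
  void reset() { for (int i = 0; i < N_COL; ++i) v[i] = 0.0; }
};

struct Herd {
  std::vector<Cow> cows;
  std::vector<Young> young;
  double cum_cy;        // accumulated cow-years (adaptive dystocia target)
  double cum_calvings;
};

Params read_params(const List& par) {
  Params p;
  p.n_target = as<int>(par["n_target"]);
  NumericMatrix ym = par["yield_week"];
  p.yield.assign(3, std::vector<double>(ym.ncol()));
  for (int c = 0; c < 3; ++c)
    for (int w = 0; w < ym.ncol(); ++w) p.yield[c][w] = ym(c, w);
  NumericMatrix lm = par["loss_weekly"];
  for (int c = 0; c < 3; ++c)
    for (int d = 0; d < N_DIS; ++d) p.loss_weekly[c][d] = lm(c, d);
  NumericVector cm = par["conc_mult"], am = par["add_mort"],
                ac = par["add_cull"], hz = par["hazard"];
  IntegerVector du = par["duration"];
  for (int d = 0; d < N_DIS; ++d) {
    p.conc_mult[d] = cm[d]; p.add_mort[d] = am[d]; p.add_cull[d] = ac[d];
    p.hazard[d] = hz[d]; p.duration[d] = du[d];
  }
  p.dyst_target = as<double>(par["dyst_target"]);
  p.ci_weeks_guess = as<double>(par["ci_weeks_guess"]);
  p.p_stillbirth = as<double>(par["p_stillbirth"]);
  p.dyst_sb_mult = as<double>(par["dyst_sb_mult"]);
  p.dyst_cow_mort = as<double>(par["dyst_cow_mort"]);
  p.h_cow_mort = as<double>(par["h_cow_mort"]);
  p.h_cull = as<double>(par["h_cull"]);
  p.elig_week_cow = as<int>(par["elig_week_cow"]);
  p.dnb_week = as<int>(par["dnb_week"]);
  p.cull_dnb_week = as<int>(par["cull_dnb_week"]);
  p.gestation = as<int>(par["gestation"]);
  p.dry_wp = as<int>(par["dry_wp"]);
  p.cycle = as<int>(par["cycle"]);
  p.ho_cow = as<double>(par["ho_cow"]); p.cr_cow = as<double>(par["cr_cow"]);
  p.ho_heif = as<double>(par["ho_heif"]); p.cr_heif = as<double>(par["cr_heif"]);
  p.h_elig_week = as<int>(par["h_elig_week"]);
  p.h_fail_week = as<int>(par["h_fail_week"]);
  p.h_early = as<double>(par["h_early"]); p.h_late = as<double>(par["h_late"]);
  p.early_lo = as<int>(par["early_lo"]); p.early_hi = as<int>(par["early_hi"]);
  p.late_lo = as<int>(par["late_lo"]); p.late_hi = as<int>(par["late_hi"]);
  p.sex_ratio_female = as<double>(par["sex_ratio_female"]);
  p.maint_sfu_day = as<double>(par["maint_sfu_day"]);
  p.sfu_per_kg = as<double>(par["sfu_per_kg"]);
  p.heifer_sfu_day = as<double>(par["heifer_sfu_day"]);
  p.powder_kg_day = as<double>(par["powder_kg_day"]);
  p.cow_weight = as<double>(par["cow_weight"]);
  p.heifer_weight = as<double>(par["heifer_weight"]);
  p.male_sale_age = as<int>(par["male_sale_age"]);
  p.powder_until_age = as<int>(par["powder_until_age"]);
  p.sell_decision_wp = as<int>(par["sell_decision_wp"]);
  return p;
}

inline int parity_class(int parity) { return parity >= 3 ? 2 : parity - 1; }

inline uint64_t newborn_id(uint64_t mother, int parity) {
  // deterministic per (mother, parity) so ids align across paired scenarios;
  // masked to 52 bits so ids survive a round trip through R doubles
  return sm64(mother ^ (0xA5A5ULL * (uint64_t)(parity + 1))) & 0xFFFFFFFFFFFFFULL;
}

// One calving event shared by cows and first-calving heifers. Returns true if
// the dam dies of calving complications.
bool do_calving(uint64_t seed, uint64_t week, uint64_t dam_id,
                int dam_parity_at_calving, const Params& p, Herd& herd,
                Acc& acc, bool& dystocia_out) {
  acc.v[C_CALVINGS] += 1;
  herd.cum_calvings += 1;
  // adaptive per-calving dystocia probability targeting cases/cow-year
  double q = p.dyst_target * (herd.cum_cy / std::max(1.0, herd.cum_calvings));
  if (q > 0.99) q = 0.99;
  bool dyst = u01(seed, week, dam_id, P_DYST) < q;
  dystocia_out = dyst;
  if (dyst) acc.v[C_CASE1] += 1;
  // base stillbirth rate compensated for the dystocia multiplier so the
  // marginal rate equals the configured one
  double q0 = p.dyst_target * p.ci_weeks_guess / 52.0;
  double p_base = p.p_stillbirth / (1.0 - q0 + q0 * p.dyst_sb_mult);
  double p_sb = p_base * (dyst ? p.dyst_sb_mult : 1.0);
  if (p_sb > 1.0) p_sb = 1.0;
  if (u01(seed, week, dam_id, P_STILL) < p_sb) {
    acc.v[C_STILLBIRTHS] += 1;
  } else {
    Young calf;
    calf.id = newborn_id(dam_id, dam_parity_at_calving);
    calf.age = 0; calf.wp = 0; calf.status = 0; calf.alive = true;
    calf.female = u01(seed, week, dam_id, P_SEX) < p.sex_ratio_female;
    calf.phase = (int)(u01(seed, week, calf.id, P_INIT) * 3.0);
    if (calf.female) acc.v[C_LIVE_F] += 1; else acc.v[C_LIVE_M] += 1;
    herd.young.push_back(calf);
  }
  if (dyst && u01(seed, week, dam_id, P_DIS_DEATH) < p.dyst_cow_mort)
    return true;  // dam dies of calving complications
  return false;
}

int n_alive_cows(const Herd& h) {
  int n = 0;
  for (size_t i = 0; i < h.cows.size(); ++i) if (h.cows[i].alive) ++n;
  return n;
}

void step_one_week(uint64_t seed, uint64_t week, const Params& p, Herd& herd,
                   Acc& acc) {
  int cows_start = n_alive_cows(herd);
  acc.v[C_COWS_START] = cows_start;  // overwritten weekly; yearly caller keeps first

  // how many retained pregnant heifers are already committed to enter
  int incoming_kept = 0;
  for (size_t i = 0; i < herd.young.size(); ++i)
    if (herd.young[i].alive && herd.young[i].status == 2) ++incoming_kept;

  std::vector<Cow> entrants;  // first-calving heifers become cows

  // ---- cows -------------------------------------------------------------
  for (size_t i = 0; i < herd.cows.size(); ++i) {
    Cow& c = herd.cows[i];
    if (!c.alive) continue;
    acc.v[C_COW_WEEKS] += 1;
    herd.cum_cy += 1.0 / 52.0;

    // 1. disease onset (hazard diseases; dystocia handled at calving)
    bool died = false;
    for (int d = 0; d < N_DIS && !died; ++d) {
      if (d == 1) continue;
      if (p.hazard[d] > 0.0 && u01(seed, week, c.id, d) < p.hazard[d]) {
        acc.v[C_CASE0 + d] += 1;
        c.dis_rem[d] = p.duration[d];  // new episode (extends an active one)
        if (p.add_mort[d] > 0.0 &&
            u01(seed, week, c.id, P_DIS_DEATH * 100 + d) < p.add_mort[d]) {
          died = true; break;
        }
        if (p.add_cull[d] > 0.0 &&
            u01(seed, week, c.id, P_DIS_CULL * 100 + d) < p.add_cull[d]) {
          c.alive = false;
          acc.v[C_COWS_SLAUGHTERED] += 1;
          acc.v[C_SLAUGHTER_KG_COWS] += p.cow_weight;
          break;
        }
      }
    }
    if (died) { c.alive = false; acc.v[C_COW_DEATHS] += 1; continue; }
    if (!c.alive) continue;

    // 2. milk + feed
    int pc = parity_class(c.parity);
    bool dry = (c.status == 1 && c.wp >= p.dry_wp);
    if (!dry && c.wim < (int)p.yield[pc].size()) {
      double y = p.yield[pc][c.wim];
      for (int d = 0; d < N_DIS; ++d)
        if (c.dis_rem[d] > 0) y -= p.loss_weekly[pc][d];
      if (y < 0) y = 0;
      acc.v[C_KG_ECM] += y;
      acc.v[C_FEED_SFU_COWS] += y * p.sfu_per_kg;
    }
    acc.v[C_FEED_SFU_COWS] += p.maint_sfu_day * 7.0;

    // 3. reproduction
    if (c.status == 0) {
      if (c.wim >= p.elig_week_cow &&
          ((c.wim - p.elig_week_cow + c.phase) % p.cycle) == 0) {
        acc.v[C_HEAT_ELIG_COWS] += 1;
        if (u01(seed, week, c.id, P_HEAT) < p.ho_cow) {
          acc.v[C_HEAT_DET_COWS] += 1;
          acc.v[C_INS_COWS] += 1;
          double cr = p.cr_cow;
          for (int d = 0; d < N_DIS; ++d)
            if (c.dis_rem[d] > 0) cr *= p.conc_mult[d];
          if (u01(seed, week, c.id, P_CONC) < cr) {
            acc.v[C_CONC_COWS] += 1;
            c.status = 1; c.wp = 0;
          }
        }
      }
      if (c.status == 0 && c.wim >= p.dnb_week) c.status = 2;
    }

    // 4. gestation / calving
    if (c.status == 1) {
      c.wp += 1;
      if (c.wp >= p.gestation) {
        if (c.prev_calv_week >= 0) {
          acc.v[C_CI_SUM_DAYS] += (double)(week - (uint64_t)c.prev_calv_week) * 7.0;
          acc.v[C_CI_N] += 1;
        }
        c.prev_calv_week = (int)week;
        c.parity += 1;
        bool dyst = false;
        bool dam_died = do_calving(seed, week, c.id, c.parity, p, herd, acc, dyst);
        c.wim = 0; c.wp = 0; c.status = 0;
        if (dam_died) {
          c.alive = false; acc.v[C_COW_DEATHS] += 1; continue;
        }
        continue;  // calving week: no further mortality/cull draw, wim stays 0
      }
    }

    // 5. base mortality / culling
    if (u01(seed, week, c.id, P_DEATH) < p.h_cow_mort) {
      c.alive = false; acc.v[C_COW_DEATHS] += 1; continue;
    }
    bool cull = u01(seed, week, c.id, P_CULL) < p.h_cull;
    if (c.status == 2 && c.wim >= p.cull_dnb_week) cull = true;
    if (cull) {
      c.alive = false;
      acc.v[C_COWS_SLAUGHTERED] += 1;
      acc.v[C_SLAUGHTER_KG_COWS] += p.cow_weight;
      continue;
    }

    // 6. episode expiry + aging
    for (int d = 0; d < N_DIS; ++d) if (c.dis_rem[d] > 0) c.dis_rem[d] -= 1;
    c.wim += 1;
  }

  // ---- young stock --------------------------------------------------------
  int cows_now = n_alive_cows(herd);
  for (size_t i = 0; i < herd.young.size(); ++i) {
    Young& y = herd.young[i];
    if (!y.alive) continue;
    if (y.female) acc.v[C_HEIFER_WEEKS] += 1;

    // feed
    if (y.age < p.powder_until_age) acc.v[C_POWDER_KG] += p.powder_kg_day * 7.0;
    else if (y.female) acc.v[C_FEED_SFU_HEIFERS] += p.heifer_sfu_day * 7.0;

    // rearing mortality windows
    if (y.age >= p.early_lo && y.age <= p.early_hi &&
        u01(seed, week, y.id, P_EARLY) < p.h_early) {
      y.alive = false; acc.v[C_DEATH_EARLY] += 1; continue;
    }
    if (!y.female) {
      if (y.age >= p.male_sale_age) {
        y.alive = false; acc.v[C_BULL_CALVES_SOLD] += 1;
      } else {
        y.age += 1;
      }
      continue;
    }
    if (y.age >= p.late_lo && y.age <= p.late_hi &&
        u01(seed, week, y.id, P_LATE) < p.h_late) {
      y.alive = false; acc.v[C_DEATH_LATE] += 1; continue;
    }

    // breeding
    if (y.status == 0) {
      if (y.age >= p.h_elig_week &&
          ((y.age - p.h_elig_week + y.phase) % p.cycle) == 0) {
        acc.v[C_HEAT_ELIG_HEIFERS] += 1;
        if (u01(seed, week, y.id, P_HEAT) < p.ho_heif) {
          acc.v[C_HEAT_DET_HEIFERS] += 1;
          acc.v[C_INS_HEIFERS] += 1;
          if (u01(seed, week, y.id, P_CONC) < p.cr_heif) {
            acc.v[C_CONC_HEIFERS] += 1;
            y.status = 1; y.wp = 0;
          }
        }
      }
      if (y.status == 0 && y.age > p.h_fail_week) {
        y.alive = false;
        acc.v[C_HEIFERS_SLAUGHTERED] += 1;
        acc.v[C_SLAUGHTER_KG_HEIFERS] += p.heifer_weight;
        continue;
      }
    }

    if (y.status >= 1) {
      y.wp += 1;
      if (y.status == 1 && y.wp >= p.sell_decision_wp) {
        // replacement policy: keep only what the herd needs, sell surplus
        if (cows_now + incoming_kept >= p.n_target) {
          y.alive = false; acc.v[C_HEIFERS_SOLD_PREGNANT] += 1;
          continue;
        }
        y.status = 2; incoming_kept += 1;
      }
      if (y.wp >= p.gestation) {
        // first calving: the heifer enters the herd as a parity-1 cow
        acc.v[C_FIRST_CALVINGS] += 1;
        acc.v[C_AFC_SUM_WEEKS] += y.age;
        acc.v[C_AFC_N] += 1;
        Cow c;
        c.id = y.id; c.parity = 1; c.wim = 0; c.status = 0; c.wp = 0;
        c.phase = y.phase;
        for (int d = 0; d < N_DIS; ++d) c.dis_rem[d] = 0;
        c.prev_calv_week = (int)week;
        c.alive = true;
        bool dyst = false;
        bool dam_died = do_calving(seed, week, y.id, 1, p, herd, acc, dyst);
        y.alive = false;
        if (dam_died) {
          acc.v[C_COW_DEATHS] += 1;
        } else {
          entrants.push_back(c);
          cows_now += 1;
        }
        incoming_kept -= 1;
        continue;
      }
    }
    y.age += 1;
  }

  for (size_t i = 0; i < entrants.size(); ++i) herd.cows.push_back(entrants[i]);

  // compact dead animals away periodically to keep the vectors small
  if (week % 52 == 0) {
    std::vector<Cow> cc; cc.reserve(herd.cows.size());
    for (size_t i = 0; i < herd.cows.size(); ++i)
      if (herd.cows[i].alive) cc.push_back(herd.cows[i]);
    herd.cows.swap(cc);
    std::vector<Young> yy; yy.reserve(herd.young.size());
    for (size_t i = 0; i < herd.young.size(); ++i)
      if (herd.young[i].alive) yy.push_back(herd.young[i]);
    herd.young.swap(yy);
  }

  acc.v[C_COWS_END] = n_alive_cows(herd);
}

Herd init_herd(uint64_t seed, const Params& p) {
  // Steady-state-like start: parity mix 0.35/0.27/0.38, lactation stage
  // uniform, cows past the expected conception stage start pregnant. The
  // burn-in discards any residual initialization effect.
  Herd h;
  h.cum_cy = (double)p.n_target;
  h.cum_calvings = (double)p.n_target * 52.0 / p.ci_weeks_guess;
  int conc_wk = p.elig_week_cow + 2 * p.cycle;  // rough modal conception stage
  for (int i = 0; i < p.n_target; ++i) {
    Cow c;
    c.id = (uint64_t)(i + 1);
    double u = u01(seed, 0, c.id, P_INIT);
    c.parity = (u < 0.35) ? 1 : (u < 0.62 ? 2 : 3);
    c.wim = (int)(u01(seed, 0, c.id, P_INIT + 1) * 48.0);
    c.phase = (int)(u01(seed, 0, c.id, P_INIT + 2) * 3.0);
    if (c.wim > conc_wk) {
      c.status = 1;
      c.wp = std::min(c.wim - conc_wk, p.gestation - 1);
    } else {
      c.status = 0; c.wp = 0;
    }
    for (int d = 0; d < N_DIS; ++d) c.dis_rem[d] = 0;
    c.prev_calv_week = -1;
    c.alive = true;
    h.cows.push_back(c);
  }
  int n_young = (int)(0.9 * p.n_target);
  for (int i = 0; i < n_young; ++i) {
    Young y;
    y.id = (uint64_t)(100000 + i);
    y.female = true;
    y.age = (int)(u01(seed, 0, y.id, P_INIT) * (p.h_elig_week + 10));
    y.phase = (int)(u01(seed, 0, y.id, P_INIT + 2) * 3.0);
    int conc_age = p.h_elig_week + 4;
    if (y.age > conc_age) {
      y.status = 1; y.wp = std::min(y.age - conc_age, p.gestation - 1);
      if (y.wp >= 36) y.status = 2;
    } else { y.status = 0; y.wp = 0; }
    y.alive = true;
    h.young.push_back(y);
  }
  return h;
}

CharacterVector col_names() {
  CharacterVector n(N_COL);
  n[C_YEAR] = "year"; n[C_WEEK] = "week";
  n[C_COWS_START] = "cows_start"; n[C_COWS_END] = "cows_end";
  n[C_COW_WEEKS] = "cow_weeks"; n[C_HEIFER_WEEKS] = "heifer_weeks";
  n[C_KG_ECM] = "kg_ecm_delivered";
  n[C_CASE0] = "cases_milk_fever"; n[C_CASE1] = "cases_dystocia";
  n[C_CASE2] = "cases_metritis"; n[C_CASE3] = "cases_ketosis";
  n[C_CASE4] = "cases_mastitis"; n[C_CASE5] = "cases_lameness";
  n[C_CALVINGS] = "calvings"; n[C_FIRST_CALVINGS] = "first_calvings";
  n[C_STILLBIRTHS] = "stillbirths";
  n[C_LIVE_F] = "live_calves_female"; n[C_LIVE_M] = "live_calves_male";
  n[C_DEATH_EARLY] = "calf_deaths_early"; n[C_DEATH_LATE] = "calf_deaths_late";
  n[C_COW_DEATHS] = "cow_deaths"; n[C_COWS_SLAUGHTERED] = "cows_slaughtered";
  n[C_SLAUGHTER_KG_COWS] = "slaughter_kg_cows";
  n[C_HEIFERS_SLAUGHTERED] = "heifers_slaughtered";
  n[C_SLAUGHTER_KG_HEIFERS] = "slaughter_kg_heifers";
  n[C_HEIFERS_SOLD_PREGNANT] = "heifers_sold_pregnant";
  n[C_HEIFERS_SOLD_OPEN] = "heifers_sold_open";
  n[C_INS_COWS] = "inseminations_cows"; n[C_INS_HEIFERS] = "inseminations_heifers";
  n[C_CONC_COWS] = "conceptions_cows"; n[C_CONC_HEIFERS] = "conceptions_heifers";
  n[C_HEAT_ELIG_COWS] = "heats_eligible_cows"; n[C_HEAT_DET_COWS] = "heats_detected_cows";
  n[C_HEAT_ELIG_HEIFERS] = "heats_eligible_heifers";
  n[C_HEAT_DET_HEIFERS] = "heats_detected_heifers";
  n[C_FEED_SFU_COWS] = "feed_sfu_cows"; n[C_FEED_SFU_HEIFERS] = "feed_sfu_heifers";
  n[C_POWDER_KG] = "milk_powder_kg"; n[C_BULL_CALVES_SOLD] = "bull_calves_sold";
  n[C_CI_SUM_DAYS] = "ci_sum_days"; n[C_CI_N] = "ci_n";
  n[C_AFC_SUM_WEEKS] = "afc_sum_weeks"; n[C_AFC_N] = "afc_n";
  return n;
}

List herd_to_state(const Herd& h, uint64_t week) {
  int nc = 0, ny = 0;
  for (size_t i = 0; i < h.cows.size(); ++i) if (h.cows[i].alive) ++nc;
  for (size_t i = 0; i < h.young.size(); ++i) if (h.young[i].alive) ++ny;
  NumericVector cid(nc); IntegerVector cpar(nc), cwim(nc), cst(nc), cwp(nc),
    cph(nc), cprev(nc);
  IntegerMatrix cdis(nc, N_DIS);
  int k = 0;
  for (size_t i = 0; i < h.cows.size(); ++i) {
    const Cow& c = h.cows[i];
    if (!c.alive) continue;
    cid[k] = (double)c.id; cpar[k] = c.parity; cwim[k] = c.wim;
    cst[k] = c.status; cwp[k] = c.wp; cph[k] = c.phase;
    cprev[k] = c.prev_calv_week;
    for (int d = 0; d < N_DIS; ++d) cdis(k, d) = c.dis_rem[d];
    ++k;
  }
  NumericVector yid(ny); IntegerVector yage(ny), yst(ny), ywp(ny), yph(ny);
  LogicalVector yf(ny);
  k = 0;
  for (size_t i = 0; i < h.young.size(); ++i) {
    const Young& y = h.young[i];
    if (!y.alive) continue;
    yid[k] = (double)y.id; yage[k] = y.age; yst[k] = y.status; ywp[k] = y.wp;
    yph[k] = y.phase; yf[k] = y.female;
    ++k;
  }
  return List::create(
    _["week"] = (double)week,
    _["cum_cow_years"] = h.cum_cy,
    _["cum_calvings"] = h.cum_calvings,
    _["cows"] = DataFrame::create(
      _["animal_id"] = cid, _["parity"] = cpar, _["week_in_milk"] = cwim,
      _["repro_status"] = cst, _["weeks_pregnant"] = cwp, _["phase"] = cph,
      _["prev_calving_week"] = cprev),
    _["cow_disease_weeks"] = cdis,
    _["heifers"] = DataFrame::create(
      _["animal_id"] = yid, _["age_weeks"] = yage, _["female"] = yf,
      _["repro_status"] = yst, _["weeks_pregnant"] = ywp, _["phase"] = yph));
}

Herd state_to_herd(const List& state) {
  Herd h;
  h.cum_cy = as<double>(state["cum_cow_years"]);
  h.cum_calvings = as<double>(state["cum_calvings"]);
  DataFrame cows = as<DataFrame>(state["cows"]);
  IntegerMatrix cdis = state["cow_disease_weeks"];
  NumericVector cid = cows["animal_id"];
  IntegerVector cpar = cows["parity"], cwim = cows["week_in_milk"],
    cst = cows["repro_status"], cwp = cows["weeks_pregnant"],
    cph = cows["phase"], cprev = cows["prev_calving_week"];
  for (int i = 0; i < cid.size(); ++i) {
    Cow c;
    c.id = (uint64_t)cid[i]; c.parity = cpar[i]; c.wim = cwim[i];
    c.status = cst[i]; c.wp = cwp[i]; c.phase = cph[i];
    c.prev_calv_week = cprev[i];
    for (int d = 0; d < N_DIS; ++d) c.dis_rem[d] = cdis(i, d);
    c.alive = true;
    h.cows.push_back(c);
  }
  DataFrame yg = as<DataFrame>(state["heifers"]);
  NumericVector yid = yg["animal_id"];
  IntegerVector yage = yg["age_weeks"], yst = yg["repro_status"],
    ywp = yg["weeks_pregnant"], yph = yg["phase"];
  LogicalVector yf = yg["female"];
  for (int i = 0; i < yid.size(); ++i) {
    Young y;
    y.id = (uint64_t)yid[i]; y.age = yage[i]; y.female = yf[i];
    y.status = yst[i]; y.wp = ywp[i]; y.phase = yph[i]; y.alive = true;
    h.young.push_back(y);
  }
  return h;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_run_herd")]]
List cpp_run_herd(List par, int years, int burn_in, double seed,
                  bool weekly_log = false, bool return_state = false) {
  Params p = read_params(par);
  uint64_t s = (uint64_t)seed;
  Herd herd = init_herd(s, p);
  int n_keep = years - burn_in;
  NumericMatrix annual(n_keep, N_COL);
  NumericMatrix weekly(weekly_log ? n_keep * 52 : 0, N_COL);
  Acc yacc; yacc.reset();
  Acc wacc;
  uint64_t week = 0;
  int out_row = 0, wrow = 0;
  for (int yr = 1; yr <= years; ++yr) {
    yacc.reset();
    double cows_start_year = n_alive_cows(herd);
    for (int w = 1; w <= 52; ++w) {
      week += 1;
      wacc.reset();
      step_one_week(s, week, p, herd, wacc);
      if (yr > burn_in) {
        for (int j = 0; j < N_COL; ++j) yacc.v[j] += wacc.v[j];
        if (weekly_log) {
          wacc.v[C_YEAR] = yr - burn_in;
          wacc.v[C_WEEK] = w;
          for (int j = 0; j < N_COL; ++j) weekly(wrow, j) = wacc.v[j];
          ++wrow;
        }
      }
    }
    if (n_alive_cows(herd) == 0 && herd.young.empty())
      stop("herd extinction in simulated year %d", yr);
    if (yr > burn_in) {
      yacc.v[C_YEAR] = yr - burn_in;
      yacc.v[C_WEEK] = 0;
      yacc.v[C_COWS_START] = cows_start_year;
      yacc.v[C_COWS_END] = n_alive_cows(herd);
      for (int j = 0; j < N_COL; ++j) annual(out_row, j) = yacc.v[j];
      ++out_row;
    }
  }
  colnames(annual) = col_names();
  List out = List::create(_["annual"] = annual);
  if (weekly_log) { colnames(weekly) = col_names(); out["weekly"] = weekly; }
  if (return_state) out["state"] = herd_to_state(herd, week);
  return out;
}

// [[Rcpp::export(name = ".cpp_step_weeks")]]
List cpp_step_weeks(List par, List state, int n_weeks, double seed) {
  Params p = read_params(par);
  uint64_t s = (uint64_t)seed;
  Herd herd = state_to_herd(state);
  uint64_t week = (uint64_t)as<double>(state["week"]);
  NumericMatrix weekly(n_weeks, N_COL);
  Acc wacc;
  for (int w = 0; w < n_weeks; ++w) {
    week += 1;
    wacc.reset();
    step_one_week(s, week, p, herd, wacc);
    wacc.v[C_YEAR] = 0;
    wacc.v[C_WEEK] = (double)week;
    for (int j = 0; j < N_COL; ++j) weekly(w, j) = wacc.v[j];
  }
  colnames(weekly) = col_names();
  return List::create(_["weekly"] = weekly,
                      _["state"] = herd_to_state(herd, week));
}

// [[Rcpp::export(name = ".cpp_init_state")]]
List cpp_init_state(List par, double seed) {
  Params p = read_params(par);
  Herd herd = init_herd((uint64_t)seed, p);
  return herd_to_state(herd, 0);
}
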