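#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---- counter-based RNG -----------------------------------------------------
// splitmix64 finalizer used as a keyed hash: every uniform draw is a pure
// function of (cohort seed, person index, purpose, counter), so perturbing
// one parameter block leaves all other draws unchanged (common random
// numbers across calibration evaluations) and any single person can be
// replayed independently of simulation order.

static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t key) {
  // strictly inside (0, 1): safe for qnorm
  return (sm64(key) >> 11) * (1.0 / 9007199254740992.0) + 2.775557562e-17;
}

// purpose tags for the named substreams
static const uint64_t P_DEATH  = 0xA1A1A1A1A1A1A1A1ULL;
static const uint64_t P_INIT   = 0xB2B2B2B2B2B2B2B2ULL;
static const uint64_t P_MALIG  = 0xC3C3C3C3C3C3C3C3ULL;
static const uint64_t P_GROW   = 0xD4D4D4D4D4D4D4D4ULL;
static const uint64_t P_BEHAV  = 0xE5E5E5E5E5E5E5E5ULL;
static const uint64_t P_SHRINK = 0xF6F6F6F6F6F6F6F6ULL;
static const uint64_t P_SLOPE  = 0x0707070707070707ULL;
static const uint64_t P_DETECT = 0x1818181818181818ULL;
static const uint64_t P_SIDE   = 0x2929292929292929ULL;

static inline double draw(uint64_t pkey, uint64_t purpose, uint64_t counter) {
  return u01(sm64(pkey ^ purpose) ^ (counter * 0x9E3779B97F4A7C15ULL));
}

static inline double znorm(double u) { return R::qnorm(u, 0.0, 1.0, 1, 0); }

// ---- kinetics --------------------------------------------------------------

static const double CELL_VOL = 1e-6;

struct Nod {
  double r_growth, shrink_rate, slope, switch_vol, cur_vol;
  // incremental state: ert = exp(r * t) accumulated multiplicatively
  // (one exp() per nodule instead of one per nodule-cycle); raw_vol is the
  // unfloored shrink/stable trajectory value
  double er, ert, shrink_f, raw_vol;
  int onset_age;
  uint8_t behavior;  // 0 pre_switch, 1 growing, 2 shrinking, 3 stable
  bool malignant;
};

static inline double logistic_from_ert(double ert, double K) {
  double V = K * CELL_VOL * ert / (K + CELL_VOL * (ert - 1.0));
  return V < K ? V : K;
}

static inline int bin14(int age) {
  int b = (age - 15) / 5;
  if (age < 15) b = 0;
  if (b > 13) b = 13;
  return b;
}

// [[Rcpp::export(name = ".sim_cohort_cpp")]]
List sim_cohort_cpp(int n, List inputs, List params, NumericVector qx,
                    double seed, int screen_age, bool detection_on) {
  const double p_benign     = inputs["p_benign"];
  const double p_mg         = inputs["p_malig_growth"];
  const double p_ms         = inputs["p_malig_shrink"];
  const double p_bg         = inputs["p_ben_grow"];
  const double p_bs         = inputs["p_ben_shrink"];
  const double shrink_mean  = inputs["shrink_rate_mean"];
  const double shrink_sd    = inputs["shrink_rate_sd"];
  const double slope_mean   = inputs["stable_slope_mean"];
  const double slope_sd     = inputs["stable_slope_sd"];
  const double min_detect   = inputs["min_size_detect"];
  const double max_diam     = inputs["max_diameter"];
  const double K = M_PI / 6.0 * max_diam * max_diam * max_diam;
  const double v_detect = M_PI / 6.0 * min_detect * min_detect * min_detect;

  NumericVector dev   = params["dev_rate"];
  NumericVector mg_mu = params["malig_growth_logmu"];
  NumericVector mg_sd = params["malig_growth_logsigma"];
  NumericVector bg_mu = params["ben_growth_logmu"];
  NumericVector bg_sd = params["ben_growth_logsigma"];
  NumericVector B1    = params["B1"];
  NumericVector B2    = params["B2"];

  // per-age aggregates: state observed at the start of each cycle
  IntegerVector alive_undet(101), any_nodule(101), any_visible(101),
                malig_visible(101);
  IntegerVector death_age(n, -1), detection_age(n, -1), det_class(n, 0);
  NumericVector det_size(n, NA_REAL), det_size_malig(n, NA_REAL);

  std::vector<double> scr_diam;
  std::vector<int> scr_person, scr_malig;
  int screen_persons = 0;

  uint64_t seed_u = (uint64_t)(int64_t)seed;
  std::vector<Nod> nods;
  nods.reserve(16);

  for (int i = 0; i < n; ++i) {
    uint64_t pkey = sm64(seed_u * 0x2545F4914F6CDD1DULL + (uint64_t)(i + 1));
    nods.clear();
    bool detected = false, dead = false;
    // visibility of the state carried over from the previous cycle's update
    bool vis_seen = false, mvis_seen = false;

    for (int a = 0; a < 100; ++a) {
      // observe start-of-cycle state
      alive_undet[a]++;
      if (!nods.empty()) {
        any_nodule[a]++;
        if (vis_seen) any_visible[a]++;
        if (mvis_seen) malig_visible[a]++;
      }
      if (a == screen_age) {
        screen_persons++;
        for (size_t j = 0; j < nods.size(); ++j) {
          scr_person.push_back(i + 1);
          scr_diam.push_back(std::cbrt(6.0 * nods[j].cur_vol / M_PI));
          scr_malig.push_back(nods[j].malignant ? 1 : 0);
        }
      }

      // (1) all-cause mortality
      if (draw(pkey, P_DEATH, (uint64_t)a) < qx[a]) {
        death_age[i] = a;
        dead = true;
        break;
      }

      // (2) nodule development: at most one per cycle
      int b = bin14(a);
      if (draw(pkey, P_INIT, (uint64_t)a) < dev[b]) {
        Nod nd;
        nd.malignant = draw(pkey, P_MALIG, (uint64_t)a) < (1.0 - p_benign);
        double z = znorm(draw(pkey, P_GROW, (uint64_t)a));
        nd.r_growth = nd.malignant ? std::exp(mg_mu[b] + mg_sd[b] * z)
                                   : std::exp(bg_mu[b] + bg_sd[b] * z);
        (void)draw(pkey, P_SIDE, (uint64_t)a);  // side: kept for parity, unused
        nd.onset_age = a;
        nd.behavior = 0;
        nd.shrink_rate = nd.slope = nd.switch_vol = 0.0;
        nd.cur_vol = CELL_VOL;
        nd.er = std::exp(std::min(nd.r_growth, 700.0));
        nd.ert = 1.0;
        nd.shrink_f = 1.0;
        nd.raw_vol = CELL_VOL;
        nods.push_back(nd);
      }

      // (3) volume update; behavior decision at nodule age 5
      double v_big = 0.0;
      vis_seen = mvis_seen = false;
      for (size_t j = 0; j < nods.size(); ++j) {
        Nod &nd = nods[j];
        int t = a + 1 - nd.onset_age;
        if (nd.behavior <= 1) {  // pre_switch or growing: advance exp(rt)
          nd.ert *= nd.er;
          if (nd.ert > 1e290) nd.ert = 1e290;
          nd.cur_vol = logistic_from_ert(nd.ert, K);
          if (nd.behavior == 0 && t == 5) {  // behavior decision
            nd.switch_vol = nd.cur_vol;
            double u = draw(pkey, P_BEHAV, (uint64_t)nd.onset_age);
            double p1 = nd.malignant ? p_mg : p_bg;
            double p2 = nd.malignant ? p_ms : p_bs;
            if (u < p1) {
              nd.behavior = 1;
            } else if (u < p1 + p2) {
              nd.behavior = 2;
              double zr = znorm(draw(pkey, P_SHRINK, (uint64_t)nd.onset_age));
              nd.shrink_rate = std::max(shrink_mean + shrink_sd * zr, 0.0);
              nd.shrink_f = std::exp(-nd.shrink_rate);
              nd.raw_vol = nd.switch_vol;
            } else {
              nd.behavior = 3;
              double zs = znorm(draw(pkey, P_SLOPE, (uint64_t)nd.onset_age));
              nd.slope = slope_mean + slope_sd * zs;
              nd.raw_vol = nd.switch_vol;
            }
          }
        } else if (nd.behavior == 2) {
          nd.raw_vol *= nd.shrink_f;
          nd.cur_vol = std::max(nd.raw_vol, CELL_VOL);
        } else {
          nd.raw_vol += nd.slope;
          nd.cur_vol = std::max(nd.raw_vol, CELL_VOL);
        }
        if (nd.cur_vol > v_big) v_big = nd.cur_vol;
        if (nd.cur_vol >= v_detect) {
          vis_seen = true;
          if (nd.malignant) mvis_seen = true;
        }
      }

      // (4) detection on the largest nodule, gated at the 3 mm floor
      if (detection_on && v_big >= v_detect) {
        double rate = B1[b] + B2[b] * v_big;
        if (rate < 0.0) rate = 0.0;
        double p_det = 1.0 - std::exp(-rate);
        if (draw(pkey, P_DETECT, (uint64_t)a) < p_det) {
          detected = true;
          detection_age[i] = a;
          bool malig_vis = false;
          double big_m = 0.0;
          for (size_t j = 0; j < nods.size(); ++j) {
            if (nods[j].malignant && nods[j].cur_vol >= v_detect) {
              malig_vis = true;
              if (nods[j].cur_vol > big_m) big_m = nods[j].cur_vol;
            }
          }
          det_class[i] = malig_vis ? 1 : 2;
          det_size[i] = std::cbrt(6.0 * v_big / M_PI);
          if (malig_vis) det_size_malig[i] = std::cbrt(6.0 * big_m / M_PI);
          break;
        }
      }
    }

    if (!dead && !detected) {
      // survived to 100 undetected: observe the terminal state
      alive_undet[100]++;
      if (!nods.empty()) {
        any_nodule[100]++;
        if (vis_seen) any_visible[100]++;
        if (mvis_seen) malig_visible[100]++;
      }
      if (screen_age == 100) {
        screen_persons++;
        for (size_t j = 0; j < nods.size(); ++j) {
          scr_person.push_back(i + 1);
          scr_diam.push_back(std::cbrt(6.0 * nods[j].cur_vol / M_PI));
          scr_malig.push_back(nods[j].malignant ? 1 : 0);
        }
      }
    }
  }

  return List::create(
    _["alive_undetected"] = alive_undet,
    _["any_nodule"] = any_nodule,
    _["any_visible"] = any_visible,
    _["malig_visible"] = malig_visible,
    _["death_age"] = death_age,
    _["detection_age"] = detection_age,
    _["detection_class"] = det_class,
    _["detection_size"] = det_size,
    _["detection_size_malig"] = det_size_malig,
    _["screen_persons"] = screen_persons,
    _["screen_person"] = IntegerVector(scr_person.begin(), scr_person.end()),
    _["screen_diameter"] = NumericVector(scr_diam.begin(), scr_diam.end()),
    _["screen_malignant"] = IntegerVector(scr_malig.begin(), scr_malig.end()));
}
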