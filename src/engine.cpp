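#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Inner engine of the eye-trace simulator: fills the true gaze signal
// sample by sample as a sequence of drift segments, minimum-jerk
// saccades and fixation holds. Uses the R RNG so results are
// reproducible under set.seed(). All indices handed back to R are
// 1-based.

namespace {

struct Engine {
  int n;
  double dt;
  NumericVector x, y;
  IntegerVector cls;          // 0 hold, 1 drift, 2 saccade
  int idx;                    // 0-based next sample to fill
  double px, py, gx, gy;
  double v, amp, landing_sd;
  std::vector<double> sac;    // onset, offset (1-based), endx, endy, type

  Engine(int n_, double dt_, double v_, double amp_, double landing_sd_)
      : n(n_), dt(dt_), x(n_), y(n_), cls(n_), idx(1), px(0), py(0),
        gx(0), gy(0), v(v_), amp(amp_), landing_sd(landing_sd_) {
    x[0] = 0; y[0] = 0; cls[0] = 0;
  }

  void drift(int k) {
    if (k <= 0) return;
    k = std::min(k, n - idx);
    int code = (v != 0.0) ? 1 : 0;
    for (int i = 0; i < k; ++i) {
      px += v * dt;
      x[idx] = px; y[idx] = py; cls[idx] = code;
      ++idx;
    }
  }

  void hold(int k) {
    if (k <= 0) return;
    k = std::min(k, n - idx);
    for (int i = 0; i < k; ++i) {
      x[idx] = px; y[idx] = py; cls[idx] = 0;
      ++idx;
    }
  }

  // 40-80 ms (2-4 sample) minimum-jerk saccade to (tx, ty) plus landing
  // error. Records onset = last pre-saccade sample, offset = landing
  // sample. Skipped (held) if it cannot complete before the trace ends.
  void saccade(double tx, double ty, int type) {
    double lx = tx + R::rnorm(0.0, landing_sd);
    double ly = ty + R::rnorm(0.0, landing_sd);
    int dur = 2 + (int)std::floor(unif_rand() * 3.0);
    if (dur > 4) dur = 4;
    if (idx + dur > n) { hold(n - idx); return; }
    int onset1 = idx;               // 1-based index of sample idx-1
    for (int i = 1; i <= dur; ++i) {
      double tau = (double)i / dur;
      double s = 10 * pow(tau, 3) - 15 * pow(tau, 4) + 6 * pow(tau, 5);
      x[idx] = px + (lx - px) * s;
      y[idx] = py + (ly - py) * s;
      cls[idx] = 2;
      ++idx;
    }
    px = lx; py = ly;
    sac.push_back(onset1);
    sac.push_back(onset1 + dur);
    sac.push_back(lx);
    sac.push_back(ly);
    sac.push_back(type);
  }

  int samples_to_cross() const {
    if (v == 0.0) return INT_MAX;
    double sgn = (v > 0) ? 1.0 : -1.0;
    double q = ((gx + sgn * amp) - px) / (v * dt);
    if (q < 0) return 0;
    if (q > 1e8) return INT_MAX;
    return (int)std::floor(q) + 1;
  }
};

enum Task { CALIBRATION = 1, STRAIGHT_AHEAD = 2, SEARCH = 3 };

struct DarkCfg {
  double rate;
  int task;
  double center_x, scatter;
};

void draw_goal(const DarkCfg &cfg, double &gx, double &gy) {
  gx = cfg.center_x + R::rnorm(0.0, cfg.scatter);
  gy = R::rnorm(0.0, cfg.scatter);
}

void run_dark(Engine &e, int until0, const DarkCfg &cfg) {
  double next_vol_d = R_PosInf;
  if (cfg.rate > 0) {
    next_vol_d = e.idx +
      std::max(1.0, std::floor(R::rexp(1.0 / cfg.rate) / e.dt + 0.5));
  }
  while (e.idx < until0 && e.idx < e.n) {
    int k_end = until0 - e.idx;
    int k_cross = e.samples_to_cross();
    double k_vol_d = next_vol_d - e.idx;
    int k_vol = (k_vol_d > 1e9) ? INT_MAX : (int)k_vol_d;
    int k = std::min(k_end, std::min(k_cross, k_vol));
    e.drift(k);
    if (e.idx >= until0 || e.idx >= e.n) break;
    if (k_cross <= k_vol && k_cross < k_end) {
      e.saccade(e.gx, e.gy, 1);            // resetting quick phase
    } else if (k_vol < k_end) {
      draw_goal(cfg, e.gx, e.gy);
      e.saccade(e.gx, e.gy, 2);            // voluntary saccade
      next_vol_d = e.idx +
        std::max(1.0, std::floor(R::rexp(1.0 / cfg.rate) / e.dt + 0.5));
    }
  }
}

void acquire_and_hold(Engine &e, double evx, double evy, double t_on,
                      double t_off, double lat_lo, double lat_hi,
                      const DarkCfg &ambient) {
  int on0 = (int)std::floor(t_on / e.dt + 0.5);
  int off0 = std::min(e.n, (int)std::floor(t_off / e.dt + 0.5));
  double lat = R::runif(lat_lo, lat_hi);
  int sac0 = on0 + (int)std::floor(lat / e.dt + 0.5);
  if (sac0 > e.idx) run_dark(e, sac0, ambient);
  if (e.idx < off0) {
    double d2 = (e.px - evx) * (e.px - evx) + (e.py - evy) * (e.py - evy);
    if (d2 > 0.01) e.saccade(evx, evy, 3);  // target acquisition
    e.gx = e.px; e.gy = e.py;
    e.hold(off0 - e.idx);
  }
  e.gx = e.px; e.gy = e.py;
}

} // namespace

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(NumericMatrix events, double duration, int task,
                List par) {
  double dt = as<double>(par["dt"]);
  int n = (int)std::floor(duration / dt + 0.5);
  Engine e(n, dt,
           as<double>(par["slow_phase_velocity_h"]),
           as<double>(par["quick_phase_reset_amplitude"]),
           as<double>(par["landing_sd"]));

  DarkCfg cfg;
  cfg.task = task;
  if (task == SEARCH) {
    cfg.rate = as<double>(par["search_saccade_rate"]);
    cfg.center_x = as<double>(par["attention_center_x"]);
    cfg.scatter = as<double>(par["search_goal_sd"]);
  } else if (task == STRAIGHT_AHEAD) {
    cfg.rate = as<double>(par["fixation_saccade_rate"]);
    cfg.center_x = as<double>(par["ssa_bias_x"]);
    cfg.scatter = as<double>(par["fixation_scatter_sd"]);
  } else {
    cfg.rate = 0;
    cfg.center_x = 0;
    cfg.scatter = 0;
  }

  int nev = events.nrow();
  for (int j = 0; j < nev; ++j) {
    double t_on = events(j, 2), t_off = events(j, 3);
    int on0 = (int)std::floor(t_on / dt + 0.5);
    if (on0 > e.idx) {
      if (task == STRAIGHT_AHEAD && j == 0) {
        e.hold(on0 - e.idx);   // already fixating roughly straight ahead
      } else {
        run_dark(e, on0, cfg);
      }
    }
    bool fading = (task == SEARCH && j < nev - 1);
    double lat_lo = fading ? 1.0 : 0.15;
    double lat_hi = fading ? 3.0 : 0.35;
    DarkCfg ambient = cfg;
    if (task == STRAIGHT_AHEAD && j == 0) ambient.rate = 0;
    acquire_and_hold(e, events(j, 0), events(j, 1), t_on, t_off,
                     lat_lo, lat_hi, ambient);
  }
  if (task == STRAIGHT_AHEAD) {
    // darkness begins: the subject re-orients to their straight ahead
    e.gx = as<double>(par["ssa_bias_x"]);
    e.gy = 0;
  }
  if (e.idx < n) run_dark(e, n, cfg);

  int ns = (int)e.sac.size() / 5;
  NumericMatrix sm(ns, 5);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < 5; ++j) sm(i, j) = e.sac[5 * i + j];
  return List::create(_["x"] = e.x, _["y"] = e.y, _["cls"] = e.cls,
                      _["saccades"] = sm);
}

// Direct-form II transposed IIR pass; a[0] must be 1.
static void iir_forward(std::vector<double> &x, const NumericVector &b,
                        const NumericVector &a) {
  int nb = b.size(), na = a.size();
  int ns = std::max(nb, na) - 1;
  std::vector<double> s(ns, 0.0);
  for (size_t i = 0; i < x.size(); ++i) {
    double xi = x[i];
    double out = b[0] * xi + s[0];
    for (int j = 0; j < ns - 1; ++j) {
      double bj = (j + 1 < nb) ? b[j + 1] : 0.0;
      double aj = (j + 1 < na) ? a[j + 1] : 0.0;
      s[j] = bj * xi + s[j + 1] - aj * out;
    }
    double bl = (ns < nb) ? b[ns] : 0.0;
    double al = (ns < na) ? a[ns] : 0.0;
    s[ns - 1] = bl * xi - al * out;
    x[i] = out;
  }
}

// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector x, NumericVector b, NumericVector a,
                         bool zero_phase) {
  int n = x.size();
  int p = std::min(n - 1, 30);
  std::vector<double> w(n + 2 * p);
  // odd (point-symmetric) reflection padding at both ends
  for (int i = 0; i < p; ++i) w[i] = 2 * x[0] - x[p - i];
  for (int i = 0; i < n; ++i) w[p + i] = x[i];
  for (int i = 0; i < p; ++i) w[p + n + i] = 2 * x[n - 1] - x[n - 2 - i];
  iir_forward(w, b, a);
  if (zero_phase) {
    std::reverse(w.begin(), w.end());
    iir_forward(w, b, a);
    std::reverse(w.begin(), w.end());
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = w[p + i];
  return out;
}
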