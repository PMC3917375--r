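#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama recursion for the mean-reverting CheY-P process.
// amp is the per-step noise amplitude (already includes sqrt(dt)); values
// are clipped at zero inside the recursion so a clipped step propagates.
// [[Rcpp::export]]
NumericVector ou_sim_cpp(int n_steps, double y0, double y_mean, double dt,
                         double tau, double amp) {
  NumericVector y(n_steps);
  double cur = y0;
  for (int i = 0; i < n_steps; ++i) {
    cur += -(cur - y_mean) / tau * dt + amp * R::norm_rand();
    if (cur < 0.0) cur = 0.0;
    y[i] = cur;
  }
  return y;
}

static inline double hill(double y, double kd, double h) {
  if (y <= 0.0) return 0.0;
  double p = std::pow(y / kd, h);
  return p / (1.0 + p);
}

// [[Rcpp::export]]
NumericVector hill_cpp(NumericVector y, double kd, double h) {
  int n = y.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hill(y[i], kd, h);
  return out;
}

// Two-state telegraph motor driven by an instantaneous CW-bias series.
// Per step: CCW -> CW with prob cb/omega*dt, CW -> CCW with (1-cb)/omega*dt.
// init < 0 draws the initial state Bernoulli(cb[0]).
// [[Rcpp::export]]
IntegerVector motor_sim_cpp(NumericVector cb, double omega, double dt,
                            int init) {
  int n = cb.size();
  IntegerVector s(n);
  int cur = init;
  if (cur < 0) cur = (R::unif_rand() < cb[0]) ? 1 : 0;
  for (int i = 0; i < n; ++i) {
    double p = (cur == 0) ? cb[i] / omega * dt : (1.0 - cb[i]) / omega * dt;
    if (R::unif_rand() < p) cur = 1 - cur;
    s[i] = cur;
  }
  return s;
}

// Overlay the 3-state filament waveform on a binary motor trace.
// Codes: 0 = normal (CCW), 1 = semi-coiled, 2 = curly-1. Each CCW->CW
// switch enters curly-1 with probability p_curly, otherwise semi-coiled;
// semi-coiled converts to curly-1 at rate lambda_sc; curly-1 is absorbing
// within a CW interval.
// [[Rcpp::export]]
IntegerVector waveform_overlay_cpp(IntegerVector motor, double p_curly,
                                   double lambda_sc, double dt) {
  int n = motor.size();
  IntegerVector w(n);
  int prev = 0;  // treat pre-trace state as CCW
  int cw_state = 1;
  for (int i = 0; i < n; ++i) {
    if (motor[i] == 0) {
      w[i] = 0;
    } else {
      if (prev == 0) {  // fresh CW interval: draw the entry waveform
        cw_state = (R::unif_rand() < p_curly) ? 2 : 1;
      } else if (cw_state == 1 && R::unif_rand() < lambda_sc * dt) {
        cw_state = 2;
      }
      w[i] = cw_state;
    }
    prev = motor[i];
  }
  return w;
}

// Simulate one fluctuating-CheY-P cell with the trace-acceptance filter.
// accept_mode: 0 none, 1 mean Hill-transformed CW bias of the CheY-P
// trace, 2 realized motor CW occupancy averaged over flagella. The whole
// regenerate-until-accepted loop lives here so rejection is cheap.
// [[Rcpp::export]]
List fluctuating_cell_cpp(int n_steps, int n_flag, double y_mean, double dt,
                          double tau, double amp, double kd, double h,
                          double omega, double cb_lo, double cb_hi,
                          int accept_mode, int max_attempts) {
  NumericVector y(n_steps), cb(n_steps);
  IntegerMatrix motors(n_steps, n_flag);
  std::vector<double> tried_means;
  for (int att = 1; att <= max_attempts; ++att) {
    double cur = y_mean, hsum = 0.0;
    for (int i = 0; i < n_steps; ++i) {
      cur += -(cur - y_mean) / tau * dt + amp * R::norm_rand();
      if (cur < 0.0) cur = 0.0;
      y[i] = cur;
      cb[i] = hill(cur, kd, h);
      hsum += cb[i];
    }
    double mean_cb = hsum / n_steps;
    if (accept_mode == 1 && (mean_cb < cb_lo || mean_cb > cb_hi)) {
      tried_means.push_back(mean_cb);
      continue;
    }
    long cw_total = 0;
    for (int k = 0; k < n_flag; ++k) {
      int curS = (R::unif_rand() < cb[0]) ? 1 : 0;
      for (int i = 0; i < n_steps; ++i) {
        double p = (curS == 0) ? cb[i] / omega * dt
                               : (1.0 - cb[i]) / omega * dt;
        if (R::unif_rand() < p) curS = 1 - curS;
        motors(i, k) = curS;
        cw_total += curS;
      }
    }
    double occ = (double)cw_total / ((double)n_steps * n_flag);
    if (accept_mode == 2 && (occ < cb_lo || occ > cb_hi)) {
      tried_means.push_back(occ);
      continue;
    }
    return List::create(_["y"] = y, _["cb"] = cb, _["motors"] = motors,
                        _["attempts"] = att, _["accepted"] = true,
                        _["mean_cb"] = (accept_mode == 2) ? occ : mean_cb);
  }
  return List::create(_["attempts"] = max_attempts, _["accepted"] = false,
                      _["tried_means"] = wrap(tried_means));
}

// Overlap-normalized Pearson cross-correlation of two numeric series at
// integer lags -max_lag..max_lag (positive lag: x leads y).
// [[Rcpp::export]]
NumericVector cross_corr_cpp(NumericVector x, NumericVector y, int max_lag) {
  int n = x.size();
  double mx = mean(x), my = mean(y);
  NumericVector out(2 * max_lag + 1);
  for (int l = -max_lag; l <= max_lag; ++l) {
    double sxy = 0.0, sxx = 0.0, syy = 0.0;
    int lo = std::max(0, -l), hi = std::min(n, n - l);
    for (int i = lo; i < hi; ++i) {
      double a = x[i] - mx, b = y[i + l] - my;
      sxy += a * b;
      sxx += a * a;
      syy += b * b;
    }
    out[l + max_lag] =
        (sxx > 0 && syy > 0) ? sxy / std::sqrt(sxx * syy) : NA_REAL;
  }
  return out;
}
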