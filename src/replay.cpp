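#include <Rcpp.h>
using namespace Rcpp;

// Deterministic replay of a learning phase under one outcome-encoding model.
//
// Model codes: 1 UNBIASED, 2 DIVISIVE, 3 RANGE, 4 RANGE_W, 5 RANGE_WPLUS.
// par = (alpha_c, alpha_u, beta, w_c, w_u) on the natural scale; for RANGE_W
// w_c == w_u == omega, for models without an exponent both are 1.
//
// Trial encoding (one row per trial, up to 3 option slots):
//   opt:      1-based option index into the Q vector, 0 = slot unused
//   avail:    1 = selectable on this trial
//   choice:   slot (1..3) of the executed choice (free or forced)
//   forced:   1 = forced trial (no likelihood contribution)
//   outcome:  displayed raw outcome in points, NA = not shown
//
// Options never shown get last-seen fallback 50 points (the scale midpoint);
// values are range/divisively normalized within the trial's outcome vector.
// Free trials with >= 2 selectable options contribute the log softmax
// probability of the observed choice over the selectable set only.

// [[Rcpp::export]]
List replay_learning_cpp(NumericVector par, int model,
                         IntegerMatrix opt, IntegerMatrix avail,
                         IntegerVector choice, IntegerVector forced,
                         NumericMatrix outcome, int n_options) {
  const double alpha_c = par[0], alpha_u = par[1], beta = par[2];
  const double w_c = par[3], w_u = par[4];
  const int n_trials = opt.nrow();

  const double q0 = (model == 1) ? 50.0 : 0.5;
  NumericVector Q(n_options, q0);
  NumericVector last_seen(n_options, NA_REAL);

  double nll = 0.0;
  double raw[3], u[3];

  for (int t = 0; t < n_trials; ++t) {
    int m = 0;
    int slots[3];
    for (int j = 0; j < 3; ++j)
      if (opt(t, j) > 0) slots[m++] = j;

    // fill unobserved outcomes with last seen (fallback: 50 points)
    for (int k = 0; k < m; ++k) {
      int j = slots[k];
      double o = outcome(t, j);
      if (NumericVector::is_na(o)) {
        double ls = last_seen[opt(t, j) - 1];
        raw[k] = NumericVector::is_na(ls) ? 50.0 : ls;
      } else {
        raw[k] = o;
      }
    }

    // likelihood of the observed free choice over the selectable set
    int chosen_slot = choice[t] - 1;
    if (forced[t] == 0) {
      int n_avail = 0;
      double mx = R_NegInf;
      for (int k = 0; k < m; ++k) {
        int j = slots[k];
        if (avail(t, j)) {
          ++n_avail;
          double v = beta * Q[opt(t, j) - 1];
          if (v > mx) mx = v;
        }
      }
      if (n_avail >= 2) {
        double denom = 0.0;
        for (int k = 0; k < m; ++k) {
          int j = slots[k];
          if (avail(t, j)) denom += std::exp(beta * Q[opt(t, j) - 1] - mx);
        }
        nll -= beta * Q[opt(t, chosen_slot) - 1] - mx - std::log(denom);
      }
    }

    // subjective encoding of the full trial outcome vector
    if (model == 1) {
      for (int k = 0; k < m; ++k) u[k] = raw[k];
    } else if (model == 2) {
      double s = 0.0;
      for (int k = 0; k < m; ++k) s += raw[k];
      if (s == 0.0) stop("divisive normalization undefined: outcomes sum to 0");
      for (int k = 0; k < m; ++k) u[k] = raw[k] / s;
    } else {
      double mn = raw[0], mx = raw[0];
      for (int k = 1; k < m; ++k) {
        if (raw[k] < mn) mn = raw[k];
        if (raw[k] > mx) mx = raw[k];
      }
      if (mx == mn) {
        for (int k = 0; k < m; ++k) u[k] = 0.5;
      } else {
        for (int k = 0; k < m; ++k) u[k] = (raw[k] - mn) / (mx - mn);
      }
      if (model >= 4) {
        for (int k = 0; k < m; ++k) {
          double w = (slots[k] == chosen_slot) ? w_c : w_u;
          u[k] = std::pow(u[k], w);
        }
      }
    }

    // delta-rule update: chosen slot with alpha_c, all other shown with alpha_u
    for (int k = 0; k < m; ++k) {
      int i = opt(t, slots[k]) - 1;
      double a = (slots[k] == chosen_slot) ? alpha_c : alpha_u;
      Q[i] += a * (u[k] - Q[i]);
    }

    // remember displayed outcomes
    for (int k = 0; k < m; ++k) {
      int j = slots[k];
      if (!NumericVector::is_na(outcome(t, j)))
        last_seen[opt(t, j) - 1] = outcome(t, j);
    }
  }

  return List::create(_["nll"] = nll, _["q"] = Q, _["last_seen"] = last_seen);
}
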