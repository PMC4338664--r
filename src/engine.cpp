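// Compiled tick engine: a direct port of the R reference path
// (tick_core/pm_tick in architecture.R), verified against it in the test
// suite. One call runs the whole per-tick loop over a pre-binned sparse
// injection matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec logistic(const arma::vec& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// [[Rcpp::export(name = ".engine_cpp")]]
List engine_cpp(IntegerVector inj_p, IntegerVector inj_i, NumericVector inj_x,
                int n_ticks, LogicalVector learn_vec, bool record_errors,
                List weights, List pm_weights, List state0, List pars) {
  const int n_esn = as<int>(pars["n_esn"]);
  const int n = as<int>(pars["n_neurons"]);
  const int m = as<int>(pars["m"]);
  const double dt_us = as<double>(pars["dt_us"]);
  const double dt_s = as<double>(pars["dt_s"]);
  const double decay = as<double>(pars["decay"]);
  const double gate_threshold = as<double>(pars["gate_threshold"]);
  const double g_min = as<double>(pars["g_min"]);
  const double g_max = as<double>(pars["g_max"]);
  const double lambda_sel = as<double>(pars["lambda"]);
  const double kp = as<double>(pars["kp"]);
  const double theta = as<double>(pars["theta"]);
  const double t_inh_us = as<double>(pars["t_inh_us"]);
  const int n_sub = as<int>(pars["n_sub"]);
  const double lam = as<double>(pars["forgetting"]);
  const double delta = as<double>(pars["delta"]);
  const bool has_pm = as<bool>(pars["has_pm"]);
  const int pn = as<int>(pars["pm_neurons"]);
  const double pm_lam = as<double>(pars["pm_forgetting"]);
  const double pm_delta = as<double>(pars["pm_delta"]);

  // weights: fields are lists of matrices, one per ESN
  List Wr_l = weights["W_r"], Win_l = weights["W_in"],
       Wback_l = weights["W_back"], Wout_l = weights["W_out"],
       P_l = weights["P"];
  std::vector<arma::mat> Wr(n_esn), Win(n_esn), Wback(n_esn), Wout(n_esn),
      P(n_esn);
  for (int k = 0; k < n_esn; ++k) {
    Wr[k] = as<arma::mat>(Wr_l[k]);
    Win[k] = as<arma::mat>(Win_l[k]);
    Wback[k] = as<arma::mat>(Wback_l[k]);
    Wout[k] = as<arma::mat>(Wout_l[k]);
    P[k] = as<arma::mat>(P_l[k]);
  }
  std::vector<arma::mat> pmWr, pmWin, pmWback, pmWout, pmP;
  arma::mat pm_states, pm_out;
  arma::vec pm_inhibit;
  if (has_pm) {
    List pWr = pm_weights["W_r"], pWin = pm_weights["W_in"],
         pWback = pm_weights["W_back"], pWout = pm_weights["W_out"],
         pP = pm_weights["P"];
    pmWr.resize(n_esn); pmWin.resize(n_esn); pmWback.resize(n_esn);
    pmWout.resize(n_esn); pmP.resize(n_esn);
    for (int k = 0; k < n_esn; ++k) {
      pmWr[k] = as<arma::mat>(pWr[k]);
      // embed the (pn x (n_esn-1)) input matrix with a zero own-column
      arma::mat w = as<arma::mat>(pWin[k]);
      arma::mat we(pn, n_esn, arma::fill::zeros);
      int col = 0;
      for (int j = 0; j < n_esn; ++j) {
        if (j == k) continue;
        we.col(j) = w.col(col++);
      }
      pmWin[k] = we;
      pmWback[k] = as<arma::mat>(pWback[k]);
      pmWout[k] = as<arma::mat>(pWout[k]);
      pmP[k] = as<arma::mat>(pP[k]);
    }
    pm_states = as<arma::mat>(state0["pm_states"]);
    pm_out = as<arma::mat>(state0["pm_outputs"]);
    pm_inhibit = as<arma::vec>(state0["pm_inhibit"]);
  }

  arma::mat states = as<arma::mat>(state0["states"]);   // n x N
  arma::mat OUT = as<arma::mat>(state0["outputs"]);     // m x N
  arma::vec a_raw = as<arma::vec>(state0["a_raw"]);
  double running_max = as<double>(state0["running_max"]);
  double x0 = as<double>(state0["x0"]);
  double t_us = as<double>(state0["t_us"]);
  arma::ivec counts = as<arma::ivec>(state0["counts"]);

  IntegerVector winner_out(n_ticks), min_ok_out(n_ticks);
  LogicalVector gated_out(n_ticks);
  NumericVector s_w_out(n_ticks);
  arma::mat errs;
  if (record_errors) errs.set_size(n_ticks, n_esn);

  arma::vec A(m), err(n_esn), S(n_esn), currents(n_esn);
  arma::vec onehot(n_esn);
  int warn_pd = 0;

  for (int tk = 0; tk < n_ticks; ++tk) {
    t_us += dt_us;
    a_raw *= decay;
    for (int ii = inj_p[tk]; ii < inj_p[tk + 1]; ++ii) {
      a_raw[inj_i[ii]] += inj_x[ii];
    }
    double mx = a_raw.max();
    if (mx > running_max) running_max = mx;
    A = a_raw / running_max;
    double sum_a = arma::accu(A);
    for (int k = 0; k < n_esn; ++k) {
      err[k] = arma::norm(OUT.col(k) - A, 2);
      double sum_hat = arma::accu(arma::abs(OUT.col(k)));
      S[k] = (sum_a > 0 && sum_hat > 0)
                 ? arma::accu(arma::abs(OUT.col(k) % A)) / (sum_a * sum_hat)
                 : 0.0;
    }
    bool gated = (sum_a / m) > gate_threshold;
    int winner = NA_INTEGER;
    double s_w = NA_REAL;
    int min_ok = NA_INTEGER;
    bool learn = learn_vec[tk];

    if (gated) {
      int w = -1;
      double best = -1.0, best_s = -1.0;
      for (int k = 0; k < n_esn; ++k) {
        bool inhib = has_pm && pm_inhibit[k] > t_us;
        if (inhib) continue;
        currents[k] = g_min + (g_max - g_min) /
                                  (1.0 + std::exp(-(S[k] - x0) / lambda_sel));
        // the encoder is strictly increasing in S, so equal currents are a
        // saturation artifact and rank by the underlying similarity
        if (currents[k] > best || (currents[k] == best && S[k] > best_s)) {
          best = currents[k];
          best_s = S[k];
          w = k;
        }
      }
      // non-leaky IF race: the largest current spikes every theta/I; it must
      // fit at least one inter-spike interval in the window to win
      if (w >= 0 && std::floor(dt_s * best / theta + 1e-9) < 1) w = -1;
      if (w >= 0) {
        winner = w + 1;
        s_w = S[w];
        double err_min = arma::datum::inf;
        for (int k = 0; k < n_esn; ++k) {
          if (has_pm && pm_inhibit[k] > t_us) continue;
          if (err[k] < err_min) err_min = err[k];
        }
        min_ok = (err[w] <= err_min + 1e-12) ? 1 : 0;

        if (has_pm) {
          // step every estimator on the current similarities
          arma::mat pm_new(pn, n_esn);
          for (int k = 0; k < n_esn; ++k) {
            pm_new.col(k) = logistic(pmWr[k] * pm_states.col(k) +
                                     pmWin[k] * S +
                                     pmWback[k] * pm_out.col(k));
          }
          pm_states = pm_new;
          onehot.zeros();
          onehot[w] = 1.0;
          for (int k = 0; k < n_esn; ++k) {
            arma::vec out_k = pmWout[k] * pm_states.col(k);
            pm_out.col(k) = out_k;
            if ((int)out_k.index_max() == w && w == k) {
              pm_inhibit[k] = t_us + t_inh_us;
            }
            if (learn) {
              arma::vec s_k = pm_states.col(k);
              arma::vec Ps = pmP[k] * s_k;
              arma::vec gain = Ps / (pm_lam + arma::dot(s_k, Ps));
              pmWout[k] += (onehot - out_k) * gain.t();
              arma::mat Pn = (pmP[k] - gain * Ps.t()) / pm_lam;
              Pn = (Pn + Pn.t()) / 2.0;
              if (!Pn.is_finite() || arma::any(Pn.diag() <= 0)) {
                ++warn_pd;
                Pn = arma::eye(pn, pn) / pm_delta;
              }
              pmP[k] = Pn;
            }
          }
        }
        if (learn) {
          arma::vec s = states.col(w);
          arma::vec Ps = P[w] * s;
          arma::vec gain = Ps / (lam + arma::dot(s, Ps));
          Wout[w] += (A - Wout[w] * s) * gain.t();
          arma::mat Pn = (P[w] - gain * Ps.t()) / lam;
          Pn = (Pn + Pn.t()) / 2.0;
          if (!Pn.is_finite() || arma::any(Pn.diag() <= 0)) {
            ++warn_pd;
            Pn = arma::eye(n, n) / delta;
          }
          P[w] = Pn;
          counts[w] += 1;
        }
        for (int i = 0; i < n_sub; ++i) {
          x0 += kp * (s_w - x0);
          if (x0 < 0) x0 = 0;
          if (x0 > 1) x0 = 1;
        }
      }
    }
    // advance every reservoir, free-running feedback
    arma::mat snew(n, n_esn);
    for (int k = 0; k < n_esn; ++k) {
      snew.col(k) = logistic(Wr[k] * states.col(k) + Win[k] * A +
                             Wback[k] * OUT.col(k));
    }
    states = snew;
    for (int k = 0; k < n_esn; ++k) {
      OUT.col(k) = Wout[k] * states.col(k);
    }
    winner_out[tk] = winner;
    gated_out[tk] = gated;
    s_w_out[tk] = s_w;
    min_ok_out[tk] = min_ok;
    if (record_errors) errs.row(tk) = err.t();
  }

  List Wout_out(n_esn), P_out(n_esn), pmWout_out(n_esn), pmP_out(n_esn);
  for (int k = 0; k < n_esn; ++k) {
    Wout_out[k] = Wout[k];
    P_out[k] = P[k];
    if (has_pm) {
      pmWout_out[k] = pmWout[k];
      pmP_out[k] = pmP[k];
    }
  }
  List out = List::create(
      _["winner"] = winner_out, _["gated"] = gated_out,
      _["s_winner"] = s_w_out, _["min_ok"] = min_ok_out,
      _["errors"] = record_errors ? wrap(errs) : R_NilValue,
      _["states"] = states, _["outputs"] = OUT, _["a_raw"] = a_raw,
      _["running_max"] = running_max, _["x0"] = x0, _["t_us"] = t_us,
      _["counts"] = counts, _["W_out"] = Wout_out, _["P"] = P_out,
      _["warn_pd"] = warn_pd);
  if (has_pm) {
    out["pm_states"] = pm_states;
    out["pm_outputs"] = pm_out;
    out["pm_inhibit"] = pm_inhibit;
    out["pm_W_out"] = pmWout_out;
    out["pm_P"] = pmP_out;
  }
  return out;
}
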