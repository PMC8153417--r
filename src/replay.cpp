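#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// inverse index of dispersion of a Beta(a, b) posterior
static inline double chi_disp(double a, double b) {
  return (a + b) * (a + b + 1.0) / b;
}

// Deterministic replay of one subject's trial log under the arbitration
// model: actions and transitions are taken from the log, never sampled, so
// the negative log-likelihood of the logged choices is a pure function of
// the parameters. Mirrors the R components (plan_mb_values, sarsa_update,
// mb_reliability, ...) composed exactly as in agent_trial(); the pure-R
// replay path is kept as an independent oracle for this code.
// [[Rcpp::export]]
List cpp_replay_session(NumericVector par, int tau_variant,
                        NumericVector tau_par,
                        IntegerMatrix pairs,      // npair x 4
                        IntegerMatrix pair_id,    // n_states x 2
                        NumericMatrix reward_by_goal,
                        IntegerVector stage,      // per state: 1, 2, 3
                        IntegerVector goal, IntegerVector s1,
                        IntegerVector a1, IntegerVector s2v,
                        IntegerVector a2, IntegerVector sout,
                        NumericVector reward, IntegerVector is_pre,
                        List control, bool keep_latents) {
  const double alpha_mb = par[0], alpha_mf = par[1], eta = par[2],
               A_beta = par[3], A_gamma = par[4];
  const double B = as<double>(control["rate_steepness"]);
  const double eps = as<double>(control["spe_zero_threshold"]);
  const int window = as<int>(control["spe_window"]);
  NumericVector prior = control["prior"];
  const double a0 = prior[0], b0 = prior[1];
  const double rpe_max = as<double>(control["rpe_max"]);
  const double p_floor = as<double>(control["prob_floor"]);
  const bool fit_pre = as<bool>(control["fit_pretraining"]);
  const bool per_decision = as<bool>(control["p_mb_per_decision"]);

  const int npair = pairs.nrow();
  const int n_states = pair_id.nrow();
  const int n = goal.size();

  std::vector<double> T(2 * npair, 0.5);
  std::vector<double> qmf(npair, 0.0);
  std::vector<double> qmb(npair, 0.0);
  std::vector<double> vmax(n_states, 0.0);
  std::vector<int> hist(window, 0);
  int hist_n = 0, hist_pos = 0, n_zero = 0;

  double omega = rpe_max / 2.0;
  double chi_mf = (rpe_max - omega) / rpe_max;
  double chi_mb = chi_disp(a0, b0) / (chi_disp(a0, b0) + chi_disp(b0, a0));
  double p_mb = as<double>(control["p_mb_init"]);
  double nll = 0.0;
  int n_obs = 0;

  NumericMatrix lat(keep_latents ? n : 0, 13);
  if (keep_latents) std::fill(lat.begin(), lat.end(), NA_REAL);

  auto push_event = [&](double spe) {
    int z = (spe <= eps) ? 1 : 0;
    if (hist_n == window) n_zero -= hist[hist_pos]; else ++hist_n;
    hist[hist_pos] = z;
    n_zero += z;
    hist_pos = (hist_pos + 1) % window;
    double n0 = n_zero, n1 = hist_n - n_zero;
    double c0 = chi_disp(a0 + n0, b0 + n1);
    double c1 = chi_disp(a0 + n1, b0 + n0);
    chi_mb = c0 / (c0 + c1);
  };

  // SPE + FORWARD update for an observed transition; returns the SPE
  auto observe = [&](int s, int a, int snext) -> double {
    int pid = pair_id(s - 1, a - 1) - 1;
    if (pid < 0) stop("unknown (state, action) pair in log");
    int j;
    if (snext == pairs(pid, 2)) j = 0;
    else if (snext == pairs(pid, 3)) j = 1;
    else stop("logged successor is not reachable from (state, action)");
    double spe = 1.0 - T[2 * pid + j];
    push_event(spe);
    T[2 * pid + j] += alpha_mb * (1.0 - T[2 * pid + j]);
    T[2 * pid + (1 - j)] *= (1.0 - alpha_mb);
    return spe;
  };

  // backward induction over the two-stage graph for goal column g (0-based)
  auto plan = [&](int g) {
    for (int i = 0; i < npair; ++i) {
      int s = pairs(i, 0);
      if (stage[s - 1] == 2) {
        qmb[i] = T[2 * i] * reward_by_goal(pairs(i, 2) - 1, g) +
                 T[2 * i + 1] * reward_by_goal(pairs(i, 3) - 1, g);
      }
    }
    for (int s = 0; s < n_states; ++s) {
      if (stage[s] == 2) {
        double v1 = qmb[pair_id(s, 0) - 1], v2 = qmb[pair_id(s, 1) - 1];
        vmax[s] = v1 > v2 ? v1 : v2;
      }
    }
    for (int i = 0; i < npair; ++i) {
      int s = pairs(i, 0);
      if (stage[s - 1] == 1) {
        int k1 = pairs(i, 2), k2 = pairs(i, 3);
        // second-stage states carry no reward; their value is vmax
        qmb[i] = T[2 * i] * vmax[k1 - 1] + T[2 * i + 1] * vmax[k2 - 1];
      }
    }
  };

  auto tau_of = [&](double p) -> double {
    switch (tau_variant) {
      case 0: return tau_par[0];
      case 1: return tau_par[0] + (tau_par[1] - tau_par[0]) /
                     (1.0 + std::exp(-tau_par[2] * (p - tau_par[3])));
      case 2: return p * tau_par[0];
      default: return p * tau_par[0] + (1.0 - p) * tau_par[1];
    }
  };

  for (int t = 0; t < n; ++t) {
    const int g = goal[t] - 1;
    const int st1 = s1[t], act1 = a1[t], st2 = s2v[t], act2 = a2[t],
              out = sout[t];
    const bool pre = is_pre[t] != 0;

    if (pre && !fit_pre) {
      double spe1 = observe(st1, act1, st2);
      double spe2 = observe(st2, act2, out);
      if (keep_latents) {
        lat(t, 0) = spe1; lat(t, 1) = spe2;
        lat(t, 4) = chi_mb; lat(t, 5) = chi_mf; lat(t, 6) = p_mb;
      }
      continue;
    }

    // decision 1
    plan(g);
    double tau1 = tau_of(p_mb);
    int pL = pair_id(st1 - 1, 0) - 1, pR = pair_id(st1 - 1, 1) - 1;
    double qL = p_mb * qmb[pL] + (1.0 - p_mb) * qmf[pL];
    double qR = p_mb * qmb[pR] + (1.0 - p_mb) * qmf[pR];
    double m = qL > qR ? qL : qR;
    double zL = std::exp(tau1 * (qL - m)), zR = std::exp(tau1 * (qR - m));
    double pRight1 = zR / (zL + zR);
    double pch1 = (act1 == 1) ? (1.0 - pRight1) : pRight1;
    double term1 = std::log(pch1 > p_floor ? pch1 : p_floor);

    double spe1 = observe(st1, act1, st2);
    if (per_decision) {
      double b1 = A_beta / (1.0 + std::exp(B * chi_mf));
      double g1 = A_gamma / (1.0 + std::exp(B * chi_mb));
      p_mb += b1 * (1.0 - p_mb) - g1 * p_mb;
      p_mb = p_mb < 0.0 ? 0.0 : (p_mb > 1.0 ? 1.0 : p_mb);
    }

    // decision 2 (re-planned: the transition model just changed)
    plan(g);
    double tau2 = tau_of(p_mb);
    int qpL = pair_id(st2 - 1, 0) - 1, qpR = pair_id(st2 - 1, 1) - 1;
    double q2L = p_mb * qmb[qpL] + (1.0 - p_mb) * qmf[qpL];
    double q2R = p_mb * qmb[qpR] + (1.0 - p_mb) * qmf[qpR];
    double m2 = q2L > q2R ? q2L : q2R;
    double z2L = std::exp(tau2 * (q2L - m2)), z2R = std::exp(tau2 * (q2R - m2));
    double pRight2 = z2R / (z2L + z2R);
    double pch2 = (act2 == 1) ? (1.0 - pRight2) : pRight2;
    double term2 = std::log(pch2 > p_floor ? pch2 : p_floor);

    nll -= term1 + term2;
    n_obs += 2;

    double spe2 = observe(st2, act2, out);

    // SARSA on both steps + Pearce-Hall reliability
    int pid1 = pair_id(st1 - 1, act1 - 1) - 1;
    int pid2 = pair_id(st2 - 1, act2 - 1) - 1;
    double rpe1 = 0.0 + qmf[pid2] - qmf[pid1];
    qmf[pid1] += alpha_mf * rpe1;
    omega += eta * (std::fabs(rpe1) - omega);
    omega = omega < 0.0 ? 0.0 : (omega > rpe_max ? rpe_max : omega);
    chi_mf = (rpe_max - omega) / rpe_max;
    double rpe2 = reward[t] - qmf[pid2];
    qmf[pid2] += alpha_mf * rpe2;
    omega += eta * (std::fabs(rpe2) - omega);
    omega = omega < 0.0 ? 0.0 : (omega > rpe_max ? rpe_max : omega);
    chi_mf = (rpe_max - omega) / rpe_max;

    // one Euler step of the model choice probability per trial
    double beta = A_beta / (1.0 + std::exp(B * chi_mf));
    double gamma = A_gamma / (1.0 + std::exp(B * chi_mb));
    p_mb += beta * (1.0 - p_mb) - gamma * p_mb;
    p_mb = p_mb < 0.0 ? 0.0 : (p_mb > 1.0 ? 1.0 : p_mb);

    if (keep_latents) {
      lat(t, 0) = spe1;    lat(t, 1) = spe2;
      lat(t, 2) = rpe1;    lat(t, 3) = rpe2;
      lat(t, 4) = chi_mb;  lat(t, 5) = chi_mf;  lat(t, 6) = p_mb;
      lat(t, 7) = tau1;    lat(t, 8) = tau2;
      lat(t, 9) = pch1;    lat(t, 10) = pch2;
      lat(t, 11) = pRight1; lat(t, 12) = pRight2;
    }
  }

  List out = List::create(_["nll"] = nll, _["n_obs"] = n_obs);
  if (keep_latents) {
    colnames(lat) = CharacterVector::create(
      "spe1", "spe2", "rpe1", "rpe2", "chi_mb", "chi_mf", "p_mb",
      "tau1", "tau2", "p_chosen1", "p_chosen2", "p_right1", "p_right2");
    out["latents"] = lat;
  }
  return out;
}
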