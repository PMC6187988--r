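#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State coding: 0 = initial choice state, 1..4 = intermediate choice states,
// 5..8 = outcome states. Actions: 0 = L, 1 = R. The transition layout gives
// every (choice state, action) exactly two configured successors; slot 0 is
// the designated likely successor (probability 0.9 in the low-uncertainty
// condition, 0.5 in high).

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline int succ_at(const IntegerVector &succ, int s, int a, int slot) {
  return succ[(s * 2 + a) * 2 + slot];
}

struct Model {
  double qmf[5][2];   // model-free SARSA values over (choice state, action)
  double tlik[5][2];  // learned probability of the slot-0 successor
  double qmb[5][2];   // model-based values (backward induction over the tree)
  double term[4];     // current (possibly devalued) value of outcome states
  double omega_est;   // running estimate of |OPE| (MF reliability estimator)
  double zspe;        // exponentially weighted rate of zero-SPE transitions
  double p_mb;        // arbitration weight on the model-based controller
};

// Exact backward induction over the two-level tree. Outcome states carry no
// onward value, so second-stage Q is the expected terminal value; the root
// maxes over second-stage actions.
static void compute_qmb(Model &m, const IntegerVector &succ) {
  for (int s = 1; s < 5; ++s) {
    for (int a = 0; a < 2; ++a) {
      int o0 = succ_at(succ, s, a, 0) - 5;
      int o1 = succ_at(succ, s, a, 1) - 5;
      m.qmb[s][a] = m.tlik[s][a] * m.term[o0] + (1.0 - m.tlik[s][a]) * m.term[o1];
    }
  }
  for (int a = 0; a < 2; ++a) {
    int i0 = succ_at(succ, 0, a, 0);
    int i1 = succ_at(succ, 0, a, 1);
    double v0 = std::max(m.qmb[i0][0], m.qmb[i0][1]);
    double v1 = std::max(m.qmb[i1][0], m.qmb[i1][1]);
    m.qmb[0][a] = m.tlik[0][a] * v0 + (1.0 - m.tlik[0][a]) * v1;
  }
}

// Probability of action 0 under a softmax with inverse temperature beta.
static inline double softmax_p0(double q0, double q1, double beta) {
  return logistic(beta * (q0 - q1));
}

// One engine for both simulation and teacher-forced likelihood replay, so
// the fitted model walks through exactly the update path that generated the
// data. `plan` columns: condition (0 flexible / 1 specific), uncertainty
// (0 low / 1 high), goal colour (0 red, 1 yellow, 2 blue, 4 white), training
// flag. `observed` columns (replay only): a0, s1, a1, s2, excluded.
// [[Rcpp::export(name = ".run_engine")]]
List run_engine(IntegerVector succ, NumericVector out_value,
                IntegerVector out_colour, NumericVector p_likely, List par,
                IntegerMatrix plan, Nullable<IntegerMatrix> observed_,
                bool simulate, bool include_training_nll,
                NumericMatrix t_init) {
  const double alpha = as<double>(par["alpha"]);
  const double eta = as<double>(par["eta"]);
  const double omega_thr = as<double>(par["omega"]);
  const double amp12 = as<double>(par["amp_mf_to_mb"]);
  const double amp21 = as<double>(par["amp_mb_to_mf"]);
  const double beta = as<double>(par["beta"]);
  const double B = as<double>(par["B"]);
  const double bias_mf = as<double>(par["bias_mf"]);
  const double omega_max = as<double>(par["omega_max"]);
  const double p_mb0 = as<double>(par["p_mb0"]);
  const double zspe0 = as<double>(par["zspe0"]);
  const double miss_prob = as<double>(par["miss_prob"]);
  const int variant = as<int>(par["variant"]); // 0 dynamic, 1 MF-only, 2 MB-only
  const double LOG_FLOOR = 1e-12;

  IntegerMatrix obs;
  if (!simulate) {
    if (observed_.isNull()) stop("replay mode requires observed trials");
    obs = observed_.get();
    if (obs.nrow() != plan.nrow()) stop("plan/observed row mismatch");
  }

  Model m;
  for (int s = 0; s < 5; ++s)
    for (int a = 0; a < 2; ++a) {
      m.qmf[s][a] = 0.0;
      m.tlik[s][a] = t_init(s, a);
    }
  m.omega_est = 0.0;
  m.zspe = zspe0;
  m.p_mb = p_mb0;

  const int n = plan.nrow();
  IntegerMatrix out_trials(n, 7); // a0 s1 a1 s2 face shocks excluded
  NumericMatrix trace(n, 19);
  double nll = 0.0;
  int n_choices = 0, n_excluded = 0;

  for (int i = 0; i < n; ++i) {
    const int cond = plan(i, 0);
    const int unc = plan(i, 1);
    const int goal = plan(i, 2);
    const int training = plan(i, 3);
    const double ptrue = p_likely[unc];

    // goal devaluation: mismatching coins are worth the 4-shock default
    for (int o = 0; o < 4; ++o) {
      double v = out_value[o];
      if (cond == 1 && out_colour[o] != goal) v = 4.0;
      m.term[o] = -v;
    }
    compute_qmb(m, succ);

    const double p_eff =
        (variant == 1) ? 0.0 : (variant == 2) ? 1.0 : m.p_mb;

    // ---- stage 1 ----
    const double qmf0L = m.qmf[0][0], qmf0R = m.qmf[0][1];
    const double qmb0L = m.qmb[0][0], qmb0R = m.qmb[0][1];
    const double q0L = p_eff * qmb0L + (1.0 - p_eff) * qmf0L;
    const double q0R = p_eff * qmb0R + (1.0 - p_eff) * qmf0R;
    const double p0L = softmax_p0(q0L, q0R, beta);

    int a0, excl = 0;
    if (simulate) {
      if (miss_prob > 0 && R::unif_rand() < miss_prob) excl = 1;
      if (excl)
        a0 = (R::unif_rand() < 0.5) ? 0 : 1;
      else
        a0 = (R::unif_rand() < p0L) ? 0 : 1;
    } else {
      a0 = obs(i, 0);
      excl = obs(i, 4);
    }
    const double prob_a0 = (a0 == 0) ? p0L : 1.0 - p0L;
    const double lp0 = std::log(std::max(prob_a0, LOG_FLOOR));

    int s1;
    if (simulate)
      s1 = (R::unif_rand() < ptrue) ? succ_at(succ, 0, a0, 0)
                                    : succ_at(succ, 0, a0, 1);
    else
      s1 = obs(i, 1);

    const int slot1 = (s1 == succ_at(succ, 0, a0, 0)) ? 0 : 1;
    const double spe1 =
        (slot1 == 0) ? 1.0 - m.tlik[0][a0] : m.tlik[0][a0];
    if (slot1 == 0)
      m.tlik[0][a0] += alpha * spe1;
    else
      m.tlik[0][a0] -= alpha * spe1;
    m.zspe += eta * ((spe1 < omega_thr ? 1.0 : 0.0) - m.zspe);
    compute_qmb(m, succ);

    // ---- stage 2 ----
    const double qmf1L = m.qmf[s1][0], qmf1R = m.qmf[s1][1];
    const double qmb1L = m.qmb[s1][0], qmb1R = m.qmb[s1][1];
    const double q1L = p_eff * qmb1L + (1.0 - p_eff) * qmf1L;
    const double q1R = p_eff * qmb1R + (1.0 - p_eff) * qmf1R;
    const double p1L = softmax_p0(q1L, q1R, beta);

    int a1;
    if (simulate) {
      if (excl)
        a1 = (R::unif_rand() < 0.5) ? 0 : 1;
      else
        a1 = (R::unif_rand() < p1L) ? 0 : 1;
    } else {
      a1 = obs(i, 2);
    }
    const double prob_a1 = (a1 == 0) ? p1L : 1.0 - p1L;
    const double lp1 = std::log(std::max(prob_a1, LOG_FLOOR));

    // SARSA update of the first-stage pair: no outcome yet (r = 0),
    // bootstrap from the chosen second-stage action.
    const double ope1 = m.qmf[s1][a1] - m.qmf[0][a0];
    m.qmf[0][a0] += alpha * ope1;
    m.omega_est += eta * (std::fabs(ope1) - m.omega_est);

    int s2;
    if (simulate)
      s2 = (R::unif_rand() < ptrue) ? succ_at(succ, s1, a1, 0)
                                    : succ_at(succ, s1, a1, 1);
    else
      s2 = obs(i, 3);

    const int slot2 = (s2 == succ_at(succ, s1, a1, 0)) ? 0 : 1;
    const double spe2 =
        (slot2 == 0) ? 1.0 - m.tlik[s1][a1] : m.tlik[s1][a1];
    if (slot2 == 0)
      m.tlik[s1][a1] += alpha * spe2;
    else
      m.tlik[s1][a1] -= alpha * spe2;
    m.zspe += eta * ((spe2 < omega_thr ? 1.0 : 0.0) - m.zspe);

    const int o = s2 - 5;
    const double face = out_value[o];
    const double rule =
        (cond == 1 && out_colour[o] != goal) ? 4.0 : face;
    const double r = -rule;

    const double ope2 = r - m.qmf[s1][a1];
    m.qmf[s1][a1] += alpha * ope2;
    m.omega_est += eta * (std::fabs(ope2) - m.omega_est);

    // arbitration: two-state transition dynamics on (p_MF, p_MB)
    const double chi_mf = std::max(0.0, 1.0 - m.omega_est / omega_max);
    const double chi_mb = m.zspe;
    const double t12 = amp12 * logistic(B * (chi_mb - chi_mf));
    const double t21 = bias_mf * amp21 * logistic(B * (chi_mf - chi_mb));
    m.p_mb += t12 * (1.0 - m.p_mb) - t21 * m.p_mb;
    if (m.p_mb < 0.0) m.p_mb = 0.0;
    if (m.p_mb > 1.0) m.p_mb = 1.0;

    const int shocks = training ? 0 : (int)rule;
    const bool include = !excl && (include_training_nll || !training);
    if (include) {
      nll -= (lp0 + lp1);
      n_choices += 2;
    }
    if (excl) ++n_excluded;

    out_trials(i, 0) = a0;
    out_trials(i, 1) = s1;
    out_trials(i, 2) = a1;
    out_trials(i, 3) = s2;
    out_trials(i, 4) = (int)face;
    out_trials(i, 5) = shocks;
    out_trials(i, 6) = excl;

    trace(i, 0) = p_eff; // weight that governed this trial's choices
    trace(i, 1) = chi_mf;
    trace(i, 2) = chi_mb;
    trace(i, 3) = m.omega_est;
    trace(i, 4) = ope1;
    trace(i, 5) = ope2;
    trace(i, 6) = spe1;
    trace(i, 7) = spe2;
    trace(i, 8) = prob_a0;
    trace(i, 9) = prob_a1;
    trace(i, 10) = excl ? NA_REAL : (lp0 + lp1);
    trace(i, 11) = qmf0L;
    trace(i, 12) = qmf0R;
    trace(i, 13) = qmb0L;
    trace(i, 14) = qmb0R;
    trace(i, 15) = qmf1L;
    trace(i, 16) = qmf1R;
    trace(i, 17) = qmb1L;
    trace(i, 18) = qmb1R;
  }

  return List::create(_["trials"] = out_trials, _["trace"] = trace,
                      _["nll"] = nll, _["n_choices"] = n_choices,
                      _["n_excluded"] = n_excluded);
}
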