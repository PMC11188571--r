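#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout used throughout: (alpha_l, alpha_f, kappa_r, kappa_p, psi).
// Disabled parameters are passed as 0, which makes the update rules collapse to
// the reduced model exactly.

static inline double sigmoid(double x) {
  if (x >= 0.0) {
    return 1.0 / (1.0 + std::exp(-x));
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double clamp_prob(double p, double eps) {
  if (p < eps) return eps;
  if (p > 1.0 - eps) return 1.0 - eps;
  return p;
}

// One trial's value update. tone in {0,1}; pull in {0,1}; r, p binary model
// indicators. Only the presented tone's pair is touched.
static inline void update_pair(double q_pull[2], double q_non[2], int tone,
                               int pull, double r, double p,
                               const double* par) {
  const double al = par[0], af = par[1], kr = par[2], kp = par[3], psi = par[4];
  if (pull) {
    q_pull[tone] += al * (kr * r - kp * p - q_pull[tone]);
    q_non[tone]  *= (1.0 - af);
  } else {
    q_pull[tone] *= (1.0 - af);
    q_non[tone]  += al * (psi - q_non[tone]);
  }
}

// [[Rcpp::export]]
double cpp_nll(IntegerVector tone, IntegerVector action, IntegerVector reward,
               IntegerVector punish, NumericVector par, NumericVector q_pull0,
               NumericVector q_non0, double eps = 1e-12) {
  const int n = tone.size();
  double q_pull[2] = { q_pull0[0], q_pull0[1] };
  double q_non[2]  = { q_non0[0],  q_non0[1]  };
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int x = tone[t], a = action[t];
    const double p_pull = sigmoid(q_pull[x] - q_non[x]);
    const double z = a ? p_pull : 1.0 - p_pull;
    nll -= std::log(clamp_prob(z, eps));
    update_pair(q_pull, q_non, x, a, reward[t], punish[t], REAL(par));
  }
  return nll;
}

// Negative log-likelihood with its exact gradient in the five parameters,
// obtained by carrying d(Q)/d(theta) through the update recursions. The
// probability clamp is inactive except at degenerate parameter values, where
// the gradient of the clamped term is taken as 0.
// [[Rcpp::export]]
List cpp_nll_grad(IntegerVector tone, IntegerVector action,
                  IntegerVector reward, IntegerVector punish,
                  NumericVector par, NumericVector q_pull0,
                  NumericVector q_non0, double eps = 1e-12) {
  const int n = tone.size();
  const double al = par[0], af = par[1], kr = par[2], kp = par[3], psi = par[4];
  double q_pull[2] = { q_pull0[0], q_pull0[1] };
  double q_non[2]  = { q_non0[0],  q_non0[1]  };
  double g_pull[2][5] = {{0}};  // d q_pull[x] / d theta
  double g_non[2][5]  = {{0}};
  double nll = 0.0;
  NumericVector grad(5);
  for (int t = 0; t < n; ++t) {
    const int x = tone[t], a = action[t];
    const double p_pull = sigmoid(q_pull[x] - q_non[x]);
    const double z = a ? p_pull : 1.0 - p_pull;
    nll -= std::log(clamp_prob(z, eps));
    if (z > eps && z < 1.0 - eps) {
      const double w = a - p_pull;  // dlog z / d(q_pull - q_non)
      for (int k = 0; k < 5; ++k) {
        grad[k] -= w * (g_pull[x][k] - g_non[x][k]);
      }
    }
    const double r = reward[t], p = punish[t];
    if (a) {
      const double delta = kr * r - kp * p - q_pull[x];
      for (int k = 0; k < 5; ++k) g_pull[x][k] *= (1.0 - al);
      g_pull[x][0] += delta;       // d/d alpha_l
      g_pull[x][2] += al * r;      // d/d kappa_r
      g_pull[x][3] -= al * p;      // d/d kappa_p
      q_pull[x] += al * delta;
      for (int k = 0; k < 5; ++k) g_non[x][k] *= (1.0 - af);
      g_non[x][1] -= q_non[x];     // d/d alpha_f (pre-update value)
      q_non[x] *= (1.0 - af);
    } else {
      for (int k = 0; k < 5; ++k) g_pull[x][k] *= (1.0 - af);
      g_pull[x][1] -= q_pull[x];
      q_pull[x] *= (1.0 - af);
      const double delta = psi - q_non[x];
      for (int k = 0; k < 5; ++k) g_non[x][k] *= (1.0 - al);
      g_non[x][0] += delta;
      g_non[x][4] += al;
      q_non[x] += al * delta;
    }
  }
  return List::create(_["nll"] = nll, _["grad"] = grad);
}

// Full per-trial trajectory: choice probability before the update and the four
// Q-values after the update, plus the negative log-likelihood.
// [[Rcpp::export]]
List cpp_trajectory(IntegerVector tone, IntegerVector action,
                    IntegerVector reward, IntegerVector punish,
                    NumericVector par, NumericVector q_pull0,
                    NumericVector q_non0, double eps = 1e-12) {
  const int n = tone.size();
  double q_pull[2] = { q_pull0[0], q_pull0[1] };
  double q_non[2]  = { q_non0[0],  q_non0[1]  };
  NumericVector p_pull_out(n);
  NumericMatrix q_out(n, 4); // qA_pull, qB_pull, qA_non, qB_non after trial t
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int x = tone[t], a = action[t];
    const double p_pull = sigmoid(q_pull[x] - q_non[x]);
    p_pull_out[t] = p_pull;
    const double z = a ? p_pull : 1.0 - p_pull;
    nll -= std::log(clamp_prob(z, eps));
    update_pair(q_pull, q_non, x, a, reward[t], punish[t], REAL(par));
    q_out(t, 0) = q_pull[0]; q_out(t, 1) = q_pull[1];
    q_out(t, 2) = q_non[0];  q_out(t, 3) = q_non[1];
  }
  return List::create(_["nll"] = nll, _["p_pull"] = p_pull_out, _["q"] = q_out);
}

// Forward simulation of a synthetic agent interacting with the task
// environment over a fixed tone schedule. Consumes exactly three uniforms per
// trial (action, reward, punishment) from R's RNG so runs are reproducible
// under set.seed() irrespective of which branches fire.
// rew_prob, pun_prob: length-2 (tone A, tone B) physical outcome
// probabilities. omission = 1 derives the model punishment indicator as
// pull-without-reward; omission = 0 uses the physical air-puff.
// [[Rcpp::export]]
List cpp_generate_agent(IntegerVector tone, NumericVector par,
                        NumericVector q_pull0, NumericVector q_non0,
                        NumericVector rew_prob, NumericVector pun_prob,
                        int omission) {
  const int n = tone.size();
  double q_pull[2] = { q_pull0[0], q_pull0[1] };
  double q_non[2]  = { q_non0[0],  q_non0[1]  };
  IntegerVector action(n), reward(n), punish_phys(n), punish_ind(n);
  NumericVector p_pull_out(n);
  NumericMatrix q_out(n, 4);
  for (int t = 0; t < n; ++t) {
    const int x = tone[t];
    const double p_pull = sigmoid(q_pull[x] - q_non[x]);
    p_pull_out[t] = p_pull;
    const double u_act = unif_rand();
    const double u_rew = unif_rand();
    const double u_pun = unif_rand();
    int a = u_act < p_pull ? 1 : 0;
    int r = 0, pp = 0;
    if (a) {
      r  = u_rew < rew_prob[x] ? 1 : 0;
      pp = u_pun < pun_prob[x] ? 1 : 0;
    }
    const int p_mod = a ? (omission ? (r ? 0 : 1) : pp) : 0;
    action[t] = a; reward[t] = r; punish_phys[t] = pp; punish_ind[t] = p_mod;
    update_pair(q_pull, q_non, x, a, r, p_mod, REAL(par));
    q_out(t, 0) = q_pull[0]; q_out(t, 1) = q_pull[1];
    q_out(t, 2) = q_non[0];  q_out(t, 3) = q_non[1];
  }
  return List::create(_["action"] = action, _["reward"] = reward,
                      _["punish_phys"] = punish_phys,
                      _["punish_ind"] = punish_ind,
                      _["p_pull"] = p_pull_out, _["q"] = q_out);
}

// Posterior-predictive simulation over the actual tone order. Per replicate
// and trial the simulated action is drawn from the model's choice
// probability; outcomes follow the coupling rule: when simulated and actual
// actions are both pull, the recorded outcomes are replayed; when the
// simulation pulls but the animal did not, outcomes are drawn from the task
// probabilities; a simulated non-pull yields no outcome. actual_punish must
// already be the model punishment indicator.
// Exactly three uniforms are consumed per (replicate, trial) so that two
// calls under the same RNG state see identical random numbers (common random
// numbers across grid values in the perturbation scan).
// [[Rcpp::export]]
List cpp_simulate(IntegerVector tone, IntegerVector actual_action,
                  IntegerVector actual_reward, IntegerVector actual_punish,
                  NumericVector par, NumericVector q_pull0,
                  NumericVector q_non0, NumericVector rew_prob,
                  NumericVector pun_prob, int omission, int n_reps,
                  int keep_reps = 0) {
  const int n = tone.size();
  NumericVector choice_sum(n);
  NumericVector rmse_rep(n_reps);
  IntegerMatrix reps_out(keep_reps ? n_reps : 0, keep_reps ? n : 0);
  for (int rep = 0; rep < n_reps; ++rep) {
    double q_pull[2] = { q_pull0[0], q_pull0[1] };
    double q_non[2]  = { q_non0[0],  q_non0[1]  };
    double sse = 0.0;
    for (int t = 0; t < n; ++t) {
      const int x = tone[t];
      const double p_pull = sigmoid(q_pull[x] - q_non[x]);
      const double u_act = unif_rand();
      const double u_rew = unif_rand();
      const double u_pun = unif_rand();
      const int a = u_act < p_pull ? 1 : 0;
      int r = 0, p_mod = 0;
      if (a) {
        if (actual_action[t]) {
          r = actual_reward[t];
          p_mod = actual_punish[t];
        } else {
          r = u_rew < rew_prob[x] ? 1 : 0;
          const int pp = u_pun < pun_prob[x] ? 1 : 0;
          p_mod = omission ? (r ? 0 : 1) : pp;
        }
      }
      update_pair(q_pull, q_non, x, a, r, p_mod, REAL(par));
      choice_sum[t] += a;
      const double d = a - actual_action[t];
      sse += d * d;
      if (keep_reps) reps_out(rep, t) = a;
    }
    rmse_rep[rep] = std::sqrt(sse / n);
  }
  NumericVector mean_choice(n);
  for (int t = 0; t < n; ++t) mean_choice[t] = choice_sum[t] / n_reps;
  List out = List::create(_["mean_choice"] = mean_choice,
                          _["rmse_rep"] = rmse_rep);
  if (keep_reps) out["reps"] = reps_out;
  return out;
}
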