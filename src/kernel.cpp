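#include <Rcpp.h>
using namespace Rcpp;

// Shared update/choice kernel for the hybrid model-based / model-free agent.
// The simulator and the likelihood must agree trial-for-trial, so both are
// thin drivers over this struct.
//
// Conventions: games 0..G-1; first-stage actions 0 (left) / 1 (right);
// second-stage states indexed 2g+a, where 2g+a is action a's common
// destination in game g. Values initialised at 0.5, the midpoint of the
// reward-probability bounds.

struct HybridAgent {
  double alpha, beta, w, pi, lambda;
  double p_common;
  int n_games;
  std::vector<double> q_mf;   // first-stage cached values, 2G
  std::vector<double> v2;     // second-stage state values, 2G
  std::vector<int> last_act;  // previous choice per game, -1 if none

  HybridAgent(double alpha_, double beta_, double w_, double pi_,
              double lambda_, double p_common_, int n_games_)
      : alpha(alpha_), beta(beta_), w(w_), pi(pi_), lambda(lambda_),
        p_common(p_common_), n_games(n_games_),
        q_mf(2 * n_games_, 0.5), v2(2 * n_games_, 0.5),
        last_act(n_games_, -1) {}

  // outcome_value: devaluation zeroes the incentive value of devalued
  // second-stage states; only the model-based branch sees this.
  inline double uval(int s, bool post_deval, const int* devalued) const {
    return (post_deval && devalued[s]) ? 0.0 : 1.0;
  }

  inline void mb_values(int g, bool post_deval, const int* devalued,
                        double* q_mb) const {
    for (int a = 0; a < 2; ++a) {
      int dest = 2 * g + a, alt = 2 * g + (1 - a);
      q_mb[a] = p_common * uval(dest, post_deval, devalued) * v2[dest] +
                (1.0 - p_common) * uval(alt, post_deval, devalued) * v2[alt];
    }
  }

  inline void net_values(int g, bool post_deval, const int* devalued,
                         double* q_net) const {
    double q_mb[2];
    mb_values(g, post_deval, devalued, q_mb);
    for (int a = 0; a < 2; ++a)
      q_net[a] = w * q_mb[a] + (1.0 - w) * q_mf[2 * g + a];
  }

  // P(action = 0) under softmax of beta*Qnet + pi*stickiness
  inline double p_left(int g, bool post_deval, const int* devalued) const {
    double q_net[2];
    net_values(g, post_deval, devalued, q_net);
    double x0 = beta * q_net[0] + (pi != 0.0 && last_act[g] == 0 ? pi : 0.0);
    double x1 = beta * q_net[1] + (pi != 0.0 && last_act[g] == 1 ? pi : 0.0);
    double d = x1 - x0;
    if (d > 35.0) d = 35.0;
    if (d < -35.0) d = -35.0;
    return 1.0 / (1.0 + std::exp(d));
  }

  // delta-rule updates after an observed reward; lambda = 1 sends the
  // terminal reward straight to the first-stage cache
  inline void learn(int g, int a, int s, double r) {
    double v_old = v2[s];
    double target = (1.0 - lambda) * v_old + lambda * r;
    q_mf[2 * g + a] += alpha * (target - q_mf[2 * g + a]);
    v2[s] += alpha * (r - v_old);
  }
};

static double nll_one(const HybridAgent& proto, const IntegerVector& game,
                      const IntegerVector& action, const IntegerVector& sstate,
                      const IntegerVector& reward,
                      const IntegerVector& post_deval,
                      const IntegerVector& devalued_state,
                      const IntegerVector& contrib) {
  HybridAgent ag = proto;
  const int* dev = INTEGER(devalued_state);
  double nll = 0.0;
  int T = game.size();
  for (int t = 0; t < T; ++t) {
    int a = action[t];
    if (a < 0) continue;  // missed/withheld trial: no likelihood, no update
    int g = game[t];
    if (contrib[t]) {
      double p0 = ag.p_left(g, post_deval[t] != 0, dev);
      double p = (a == 0) ? p0 : 1.0 - p0;
      if (p < 1e-300) p = 1e-300;
      nll -= std::log(p);
    }
    if (reward[t] >= 0 && sstate[t] >= 0) ag.learn(g, a, sstate[t], reward[t]);
    ag.last_act[g] = a;
  }
  return nll;
}

// [[Rcpp::export]]
double nll_cpp(NumericVector par, double p_common, int n_games,
               IntegerVector game, IntegerVector action, IntegerVector sstate,
               IntegerVector reward, IntegerVector post_deval,
               IntegerVector devalued_state, IntegerVector contrib) {
  HybridAgent ag(par[0], par[1], par[2], par[3], par[4], p_common, n_games);
  return nll_one(ag, game, action, sstate, reward, post_deval, devalued_state,
                 contrib);
}

// negative log-likelihoods for a cohort: theta is n_subjects x 4
// (alpha, beta, w, pi) on the natural scale; data is a list of per-subject
// lists with elements game, action, sstate, reward, post_deval,
// devalued_state, contrib
// [[Rcpp::export]]
NumericVector cohort_nll_cpp(NumericMatrix theta, double lambda,
                             double p_common, int n_games, List data) {
  int n = data.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    List d = data[i];
    HybridAgent ag(theta(i, 0), theta(i, 1), theta(i, 2), theta(i, 3), lambda,
                   p_common, n_games);
    out[i] = nll_one(ag, d["game"], d["action"], d["sstate"], d["reward"],
                     d["post_deval"], d["devalued_state"], d["contrib"]);
  }
  return out;
}

// Simulate one subject through a prepared phase schedule.
// phase codes: 0 training (feedback shown), 1 no-feedback, 2 test.
// walk: T x 2G matrix of reward probabilities (rows for non-training trials
// are ignored). Returns -1 codes for none/hidden.
// null_link severs devaluation from the agent's values: choices and
// respond decisions ignore outcome_value, and engagement is a flat
// per-subject probability.
// [[Rcpp::export]]
List sim_subject_cpp(NumericVector par, double p_common, int n_games,
                     double reward_value, double response_cost,
                     NumericMatrix walk, IntegerVector game,
                     IntegerVector phase, IntegerVector post_deval,
                     IntegerVector devalued_state, IntegerVector allow_withhold,
                     double omission_rate, bool null_link,
                     double null_respond_p) {
  double alpha = par[0], beta = par[1], w = par[2], pi = par[3];
  double beta_resp = par[4], resp_bias = par[5], lambda = par[6];
  HybridAgent ag(alpha, beta, w, pi, lambda, p_common, n_games);
  int T = game.size();
  IntegerVector action(T), sstate(T), transition(T), reward(T);
  const int* dev = INTEGER(devalued_state);
  std::vector<int> no_dev(2 * n_games, 0);
  for (int t = 0; t < T; ++t) {
    int g = game[t];
    bool pd = !null_link && post_deval[t] != 0;
    const int* dv = null_link ? no_dev.data() : dev;
    action[t] = -1; sstate[t] = -1; transition[t] = -1; reward[t] = -1;
    if (phase[t] == 0 && omission_rate > 0.0 && unif_rand() < omission_rate)
      continue;  // lapse: missed trial
    if (allow_withhold[t]) {
      double presp;
      if (null_link) {
        presp = null_respond_p;
      } else {
        double q_net[2];
        ag.net_values(g, pd, dv, q_net);
        double e = std::max(q_net[0], q_net[1]) * reward_value - response_cost;
        presp = 1.0 / (1.0 + std::exp(-(beta_resp * e + resp_bias)));
      }
      if (unif_rand() >= presp) continue;  // withhold
    }
    double p0 = ag.p_left(g, pd, dv);
    int a = (unif_rand() < p0) ? 0 : 1;
    action[t] = a;
    if (phase[t] == 0) {
      // only training trials play out the transition and deliver feedback;
      // no-feedback and test trials stop at the first stage
      bool common = unif_rand() < p_common;
      int s = common ? (2 * g + a) : (2 * g + (1 - a));
      sstate[t] = s;
      transition[t] = common ? 0 : 1;
      int r = (unif_rand() < walk(t, s)) ? 1 : 0;
      reward[t] = r;
      ag.learn(g, a, s, r);
    }
    ag.last_act[g] = a;
  }
  return List::create(_["action"] = action, _["sstate"] = sstate,
                      _["transition"] = transition, _["reward"] = reward);
}
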