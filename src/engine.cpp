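#include <Rcpp.h>
using namespace Rcpp;

// Engine parameter vector layout (see engine_args() on the R side):
// 0-2 wvec (weight on system 1 per component), 3 sys1_type, 4 sys1_alpha,
// 5 sys1_lam, 6 sys1_alphaT, 7 sys2_type, 8 sys2_alpha, 9 sys2_lam,
// 10 sys2_alphaT, 11 beta, 12 stay, 13 fictive.

// One value-learning system. type 0 = model-free TD(lambda) Q-learner,
// type 1 = model-based planner with transition table and reward estimates.
// All tables live on the [0,1] reward scale; fictive (mirrored) updates set
// the unvisited paired entry to 1 - the visited entry.
struct Sys {
  int type;
  double alpha, lam, alphaT;
  bool fictive;
  // MF state: q0[a] first-level action values, q2[s] second-level values
  double q0[2], q2[2];
  // MB state: p13 = P(S1->S3), p24 = P(S2->S4); R3, R4 terminal rewards
  double p13, p24, R3, R4;

  void init(const double* par, bool fict) {
    type = (int)par[0];
    alpha = par[1];
    lam = par[2];
    alphaT = par[3];
    fictive = fict;
    q0[0] = q0[1] = q2[0] = q2[1] = 0.5;
    p13 = p24 = 1.0;  // mapping A
    R3 = R4 = 0.5;
  }

  // first-level action values under this system
  void qvals(double* out) const {
    if (type == 0) {
      out[0] = q0[0]; out[1] = q0[1];
    } else {
      out[0] = p13 * R3 + (1.0 - p13) * R4;  // A1 -> S1
      out[1] = (1.0 - p24) * R3 + p24 * R4;  // A2 -> S2
    }
  }

  // experience one trial: started0 = started at S0 with a choice,
  // s2 in {0,1} (S1/S2), term in {0,1} (S3/S4), r = reward received
  void update(bool started0, int choice, int s2, int term, double r) {
    if (type == 0) {
      double d2 = r - q2[s2];
      if (started0) {
        // first-level prediction error uses pre-update second-level value;
        // lambda carries the terminal-reward error back within the trial
        double d1 = q2[s2] - q0[choice];
        q0[choice] += alpha * (d1 + lam * d2);
      }
      q2[s2] += alpha * d2;
      if (fictive) q2[1 - s2] = 1.0 - q2[s2];
    } else {
      // the observed pair implies one of the two complementary mappings;
      // both rows move toward it (rate 1 unless alphaT is freed)
      double targetA = ((s2 == 0 && term == 0) || (s2 == 1 && term == 1)) ? 1.0 : 0.0;
      p13 += alphaT * (targetA - p13);
      p24 += alphaT * (targetA - p24);
      if (term == 0) {
        R3 += alpha * (r - R3);
        if (fictive) R4 = 1.0 - R3;
      } else {
        R4 += alpha * (r - R4);
        if (fictive) R3 = 1.0 - R4;
      }
    }
  }
};

static inline double softmax_p1(double qa, double qb, double beta) {
  // overflow-safe probability of the first action
  double z = beta * (qa - qb);
  if (z > 0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

// Negative log-likelihood of the observed first-level choices.
// start: 0/1/2 (S0/S1/S2); choice: 0/1 or -1 (no choice recorded);
// s2, term: 0/1 or -1 (no experience, e.g. missed trial); reward in [0,1].
// w_idx selects which component of the weight vector governs each trial.
// probs (optional, length n) receives the per-trial probability of A1.
static double run_nll(const IntegerVector& start, const IntegerVector& choice,
                      const IntegerVector& s2, const IntegerVector& term,
                      const NumericVector& reward, const IntegerVector& w_idx,
                      const NumericVector& eng, double* probs) {
  int n = start.size();
  bool fict = eng[13] != 0.0;
  Sys A, B;
  A.init(&eng[3], fict);
  B.init(&eng[7], fict);
  double beta = eng[11], stay = eng[12];
  int prev = -1;
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    bool started0 = (start[t] == 0);
    if (started0 && choice[t] >= 0) {
      double qa[2], qb[2], q[2];
      A.qvals(qa); B.qvals(qb);
      double w = eng[w_idx[t]];
      q[0] = w * qa[0] + (1.0 - w) * qb[0];
      q[1] = w * qa[1] + (1.0 - w) * qb[1];
      if (prev >= 0) q[prev] += stay;
      double p = softmax_p1(q[0], q[1], beta);
      if (probs) probs[t] = p;
      double pc = (choice[t] == 0) ? p : 1.0 - p;
      if (pc < 1e-300) pc = 1e-300;
      nll -= std::log(pc);
      prev = choice[t];
    }
    if (s2[t] >= 0 && term[t] >= 0 && R_finite(reward[t])) {
      bool chose = started0 && choice[t] >= 0;
      int ch = chose ? choice[t] : 0;
      A.update(chose, ch, s2[t], term[t], reward[t]);
      B.update(chose, ch, s2[t], term[t], reward[t]);
    }
  }
  return nll;
}

// [[Rcpp::export]]
double cpp_nll(IntegerVector start, IntegerVector choice, IntegerVector s2,
               IntegerVector term, NumericVector reward, IntegerVector w_idx,
               NumericVector eng) {
  return run_nll(start, choice, s2, term, reward, w_idx, eng, nullptr);
}

// As cpp_nll, but also returns the per-trial probability of choosing A1
// (NA on trials without a recorded choice).
// [[Rcpp::export]]
List cpp_nll_probs(IntegerVector start, IntegerVector choice, IntegerVector s2,
                   IntegerVector term, NumericVector reward,
                   IntegerVector w_idx, NumericVector eng) {
  int n = start.size();
  NumericVector p1(n, NA_REAL);
  double nll = run_nll(start, choice, s2, term, reward, w_idx, eng, p1.begin());
  return List::create(_["nll"] = nll, _["p1"] = p1);
}

// Simulate an agent through a pre-generated task episode.
// conting: 0 = mapping A (S1->S3, S2->S4), 1 = mapping B;
// payoff_high: payoff of the currently high-rewarded terminal state;
// high_state: 0/1 (S3/S4); u: uniform draws deciding each first-level choice.
// [[Rcpp::export]]
List cpp_simulate(IntegerVector start, IntegerVector conting,
                  NumericVector payoff_high, IntegerVector high_state,
                  NumericVector u, IntegerVector w_idx, NumericVector eng) {
  int n = start.size();
  bool fict = eng[13] != 0.0;
  Sys A, B;
  A.init(&eng[3], fict);
  B.init(&eng[7], fict);
  double beta = eng[11], stay = eng[12];
  int prev = -1;
  IntegerVector choice(n, NA_INTEGER), s2v(n), termv(n);
  NumericVector rew(n), p1(n, NA_REAL);

  for (int t = 0; t < n; ++t) {
    bool started0 = (start[t] == 0);
    int s2;
    if (started0) {
      double qa[2], qb[2], q[2];
      A.qvals(qa); B.qvals(qb);
      double w = eng[w_idx[t]];
      q[0] = w * qa[0] + (1.0 - w) * qb[0];
      q[1] = w * qa[1] + (1.0 - w) * qb[1];
      if (prev >= 0) q[prev] += stay;
      double p = softmax_p1(q[0], q[1], beta);
      p1[t] = p;
      int ch = (u[t] < p) ? 0 : 1;
      choice[t] = ch;
      prev = ch;
      s2 = ch;  // A1 -> S1, A2 -> S2 deterministically
    } else {
      s2 = start[t] - 1;
    }
    int term = (conting[t] == 0) ? s2 : 1 - s2;
    double r = (term == high_state[t]) ? payoff_high[t] : 1.0 - payoff_high[t];
    s2v[t] = s2; termv[t] = term; rew[t] = r;
    A.update(started0, started0 ? choice[t] : 0, s2, term, r);
    B.update(started0, started0 ? choice[t] : 0, s2, term, r);
  }
  return List::create(_["choice"] = choice, _["s2"] = s2v, _["term"] = termv,
                      _["reward"] = rew, _["p1"] = p1);
}
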