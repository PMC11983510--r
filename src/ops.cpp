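// Exported granular operations. The R module surface wraps these, and the
// episode runners use the same inline implementations from core.h, so there is
// a single source of truth for every formula.
#include <Rcpp.h>
#include "core.h"
using namespace Rcpp;

// [[Rcpp::export]]
double cpp_compute_rpe(double r, double q_next, double q_curr, double gamma) {
  return md::rpe(r, q_next, q_curr, gamma);
}

// [[Rcpp::export]]
int cpp_classify_pe(double pe, double omega) {
  return md::classify_pe(pe, omega);  // 0 negative, 1 zero, 2 positive
}

// [[Rcpp::export]]
List cpp_ph_update(double assoc, double eta, double rpe_val, double rpe_max) {
  md::PHTracker t;
  t.assoc = assoc; t.eta = eta; t.rpe_max = rpe_max;
  double rel = t.update(rpe_val);
  return List::create(_["assoc"] = t.assoc, _["rel_mf"] = rel);
}

// [[Rcpp::export]]
List cpp_dir_update(NumericVector counts, double prior, int cat, double decay) {
  md::DirTracker t;
  for (int i = 0; i < 3; ++i) t.c[i] = counts[i];
  t.prior = prior; t.decay = decay;
  t.observe(cat);
  return List::create(_["counts"] = NumericVector::create(t.c[0], t.c[1], t.c[2]),
                      _["mean_zero"] = t.mean_zero(),
                      _["var_zero"] = t.var_zero());
}

// [[Rcpp::export]]
double cpp_pmb_update(double p, double rel_mf, double rel_mb,
                      double A_alpha, double B_alpha,
                      double A_beta, double B_beta) {
  md::ArbParams ap;
  ap.Aa = A_alpha; ap.Ba = B_alpha; ap.Ab = A_beta; ap.Bb = B_beta;
  return md::pmb_update(p, rel_mf, rel_mb, ap);
}

// [[Rcpp::export]]
NumericVector cpp_trans_row_update(NumericVector row, int sn, double g) {
  NumericVector out = clone(row);
  md::trans_row_update(out.begin(), out.size(), sn, g);
  return out;
}

// [[Rcpp::export]]
int cpp_eps_greedy(NumericVector q, double epsilon) {
  return md::eps_greedy(q.begin(), q.size(), epsilon);  // 0-based
}

// [[Rcpp::export]]
int cpp_sample_categorical(NumericVector p) {
  return md::sample_categorical(p.begin(), p.size());   // 0-based
}

// ---- environment steppers ---------------------------------------------------

// [[Rcpp::export]]
List cpp_mdt_step(int state, int action, double p_intended, int goal_kind,
                  int target, NumericVector token_values) {
  md::StepOut o = md::mdt_step(state, action, p_intended, goal_kind, target,
                               token_values.begin());
  return List::create(_["next_state"] = o.next, _["reward"] = o.reward,
                      _["terminal"] = o.terminal);
}

// [[Rcpp::export]]
List cpp_grid_step(int state, int action, double p_intended, int rows, int cols,
                   double r_left, double r_right) {
  md::StepOut o = md::grid_step(state, action, p_intended, rows, cols,
                                r_left, r_right);
  return List::create(_["next_state"] = o.next, _["reward"] = o.reward,
                      _["terminal"] = o.terminal);
}

// [[Rcpp::export]]
NumericVector cpp_pong_reset(List par) {
  md::PongParams pp;
  pp.paddle_p = as<double>(par["paddle_p"]);
  md::PongState st;
  md::pong_reset(st, pp);
  return NumericVector::create(st.bx, st.by, st.vx, st.vy, st.py, st.oy);
}

// [[Rcpp::export]]
List cpp_pong_step(NumericVector state, int action, bool stochastic,
                   int goal_kind, int target, List par) {
  md::PongParams pp;
  pp.paddle_p = as<double>(par["paddle_p"]);
  md::PongState st;
  st.bx = state[0]; st.by = state[1]; st.vx = state[2];
  st.vy = state[3]; st.py = state[4]; st.oy = state[5];
  md::PongOut o = md::pong_step(st, action, stochastic, goal_kind, target, pp);
  NumericVector obs(6);
  md::pong_observe(st, pp, obs.begin());
  return List::create(
      _["state"] = NumericVector::create(st.bx, st.by, st.vx, st.vy, st.py, st.oy),
      _["obs"] = obs, _["reward"] = o.reward, _["terminal"] = o.terminal,
      _["contact_segment"] = o.contact_segment);
}

// ---- tabular rollout (mental simulation) ------------------------------------

// Generates up to n_steps simulated transitions from s0, chaining until a
// predicted terminal or the horizon; never fabricates from a cold model.
// t_est: (S*A) x S row-major transition matrix; q: S x A values used by the
// epsilon-greedy simulated policy.
// [[Rcpp::export]]
List cpp_tab_rollout(NumericMatrix t_est, NumericVector r_est,
                     IntegerVector visits, LogicalVector terminal_states,
                     NumericMatrix q, int s0, int n_steps, int horizon,
                     double epsilon) {
  int S = t_est.ncol(), A = r_est.size() / S;
  bool any_visit = false;
  for (int i = 0; i < visits.size(); ++i) if (visits[i] > 0) any_visit = true;
  std::vector<int> sv, av, snv;
  std::vector<double> rv;
  std::vector<bool> tv;
  if (any_visit) {
    int s = s0;
    int depth = 0;
    std::vector<double> qrow(A), trow(S);
    for (int i = 0; i < n_steps && depth < horizon; ++i, ++depth) {
      for (int a = 0; a < A; ++a) qrow[a] = q(s, a);
      int a = md::eps_greedy(qrow.data(), A, epsilon);
      int sa = s * A + a;
      for (int j = 0; j < S; ++j) trow[j] = t_est(sa, j);
      int sn = md::sample_categorical(trow.data(), S);
      double r = r_est[sa];
      bool term = terminal_states[sn];
      sv.push_back(s); av.push_back(a); snv.push_back(sn);
      rv.push_back(r); tv.push_back(term);
      if (term) break;
      s = sn;
    }
  }
  int n = sv.size();
  IntegerVector s_out(n), a_out(n), sn_out(n);
  NumericVector r_out(n);
  LogicalVector term_out(n), sim_out(n);
  for (int i = 0; i < n; ++i) {
    s_out[i] = sv[i]; a_out[i] = av[i]; sn_out[i] = snv[i];
    r_out[i] = rv[i]; term_out[i] = tv[i]; sim_out[i] = true;
  }
  return List::create(_["s"] = s_out, _["a"] = a_out, _["r"] = r_out,
                      _["s_next"] = sn_out, _["terminal"] = term_out,
                      _["simulated"] = sim_out);
}
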