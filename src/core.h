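#ifndef METADYNA_CORE_H
#define METADYNA_CORE_H

#include <R.h>
#include <Rmath.h>
#include <vector>
#include <cmath>
#include <algorithm>

namespace md {

// ---- RNG: everything draws from R's generator so set.seed() in R gives
// ---- full-trajectory determinism across the R/C++ boundary.
inline double ru() { return unif_rand(); }
inline double rnorm1() { return norm_rand(); }
inline int rint(int n) {            // uniform on 0..n-1
  int k = (int)std::floor(ru() * n);
  return k >= n ? n - 1 : k;
}

inline double clamp01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }
inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// argmax with uniform random tie-breaking (seeded via R RNG)
inline int argmax_tie(const double* q, int n) {
  double best = q[0];
  for (int i = 1; i < n; ++i) if (q[i] > best) best = q[i];
  int ties = 0, pick = 0;
  for (int i = 0; i < n; ++i) if (q[i] >= best - 1e-12) ++ties;
  int k = ties > 1 ? rint(ties) : 0;
  for (int i = 0; i < n; ++i) {
    if (q[i] >= best - 1e-12) { if (k == 0) { pick = i; break; } --k; }
  }
  return pick;
}

// epsilon-greedy: one uniform draw for the explore test, then either a uniform
// action or a (tie-broken) argmax. Shared by every agent so that degenerate
// configurations are step-for-step identical.
inline int eps_greedy(const double* q, int n, double eps) {
  if (ru() < eps) return rint(n);
  return argmax_tie(q, n);
}

inline int sample_categorical(const double* p, int n) {
  double u = ru(), acc = 0.0;
  for (int i = 0; i < n; ++i) { acc += p[i]; if (u <= acc) return i; }
  return n - 1;
}

// ---- Arbitration primitives -------------------------------------------------

// temporal-difference reward prediction error
inline double rpe(double r, double q_next, double q_curr, double gamma) {
  return r + gamma * q_next - q_curr;
}

// Pearce-Hall associability tracker: running mean |RPE| mapped linearly to [0,1]
struct PHTracker {
  double assoc = 0.0, eta = 0.2, rpe_max = 1.0;
  double update(double rpe_val) {
    assoc = (1.0 - eta) * assoc + eta * std::fabs(rpe_val);
    return rel();
  }
  double rel() const { return clamp01(1.0 - assoc / rpe_max); }
};

// symmetric zero band: |PE| <= omega -> zero (1); PE < -omega -> negative (0);
// PE > omega -> positive (2)
inline int classify_pe(double pe, double omega) {
  if (pe < -omega) return 0;
  if (pe > omega) return 2;
  return 1;
}

// Dirichlet pseudo-count tracker over {negative, zero, positive} SPE events.
// decay = 1 reproduces the plain conjugate posterior; decay < 1 forgets
// exponentially so the reliability can track non-stationary schedules.
struct DirTracker {
  double c[3] = {0.0, 0.0, 0.0};
  double prior = 1.0, decay = 1.0;
  void observe(int cat) {
    if (decay < 1.0) for (int i = 0; i < 3; ++i) c[i] *= decay;
    c[cat] += 1.0;
  }
  double mean_zero() const {
    double tot = c[0] + c[1] + c[2] + 3.0 * prior;
    return (c[1] + prior) / tot;
  }
  double var_zero() const {
    double tot = c[0] + c[1] + c[2] + 3.0 * prior;
    double m = (c[1] + prior) / tot;
    return m * (1.0 - m) / (tot + 1.0);
  }
};

struct ArbParams {
  double Aa = 0.3, Ba = 3.0, Ab = 0.3, Bb = 3.0;
};

inline double pmb_update(double p, double rel_mf, double rel_mb,
                         const ArbParams& ap) {
  double alpha = ap.Aa / (1.0 + std::exp(ap.Ba * rel_mf));
  double beta  = ap.Ab / (1.0 + std::exp(ap.Bb * rel_mb));
  return clamp01(p + alpha * (1.0 - p) - beta * p);
}

// ---- Tabular world model ----------------------------------------------------

// One row update of the transition-probability learning rule:
// matched successor: t <- t + g*(1-t); others: t <- t*(1-g); then renormalize.
inline void trans_row_update(double* row, int S, int sn, double g) {
  double sum = 0.0;
  for (int j = 0; j < S; ++j) {
    if (j == sn) row[j] += g * (1.0 - row[j]);
    else row[j] *= (1.0 - g);
    sum += row[j];
  }
  if (sum > 0) for (int j = 0; j < S; ++j) row[j] /= sum;
}

struct TabModel {
  int S = 0, A = 0;
  std::vector<double> T;       // (s*A+a)*S + sn
  std::vector<double> Rhat;    // s*A+a
  std::vector<int> visits;     // s*A+a
  double gamma_t = 0.2;        // model step size; NaN -> 1/count mode
  double r_step = 0.2;         // reward EWMA step; 1/count in count mode
  bool count_mode = false;

  void init(int S_, int A_) {
    S = S_; A = A_;
    T.assign((size_t)S * A * S, 1.0 / S);
    Rhat.assign((size_t)S * A, 0.0);
    visits.assign((size_t)S * A, 0);
  }
  double* row(int s, int a) { return &T[((size_t)s * A + a) * S]; }
  const double* row(int s, int a) const { return &T[((size_t)s * A + a) * S]; }
  double tprob(int s, int a, int sn) const { return row(s, a)[sn]; }

  void update(int s, int a, int sn, double r) {
    int sa = s * A + a;
    ++visits[sa];
    double g = count_mode ? 1.0 / visits[sa] : gamma_t;
    trans_row_update(row(s, a), S, sn, g);
    double rs = count_mode ? 1.0 / visits[sa] : r_step;
    Rhat[sa] += rs * (r - Rhat[sa]);
  }
  bool cold(int s, int a) const { return visits[s * A + a] == 0; }
};

// ---- Environments -----------------------------------------------------------

struct StepOut {
  int next = 0;
  double reward = 0.0;
  bool terminal = false;
};

// Two-stage Markov decision task.
// States: 0 root; 1,2 intermediate; 3..6 terminal token states (tokens 0..3).
// Intermediate state i holds tokens 2*(i-1) and 2*(i-1)+1.
inline StepOut mdt_step(int state, int action, double p_intended,
                        int goal_kind /*0 flexible, 1 specific*/, int target,
                        const double* token_values) {
  StepOut out;
  if (state == 0) {
    int intended = 1 + action;
    out.next = (ru() < p_intended) ? intended : 3 - intended;
    out.reward = 0.0;
    out.terminal = false;
  } else {
    int base = 2 * (state - 1);
    int tok_int = base + action, tok_oth = base + (1 - action);
    int tok = (ru() < p_intended) ? tok_int : tok_oth;
    out.next = 3 + tok;
    out.reward = goal_kind == 1 ? (tok == target ? 1.0 : 0.0)
                                : token_values[tok];
    out.terminal = true;
  }
  return out;
}

// Gridworld with terminal reward zones along the left and right edges
// (columns 0 and cols-1). (row, col) 0-based; state = row*cols + col.
// Actions: 0 up, 1 down, 2 left, 3 right. With prob p_intended the intended
// direction executes, otherwise one of the remaining three (uniform). Walls
// block (position unchanged).
inline StepOut grid_step(int state, int action, double p_intended,
                         int rows, int cols, double r_left, double r_right) {
  int r = state / cols, c = state % cols;
  int dir = action;
  if (ru() >= p_intended) {
    int k = rint(3);
    dir = (k >= action) ? k + 1 : k;  // uniform over the other three
  }
  int nr = r, nc = c;
  if (dir == 0) nr = r - 1;
  else if (dir == 1) nr = r + 1;
  else if (dir == 2) nc = c - 1;
  else nc = c + 1;
  if (nr < 0 || nr >= rows || nc < 0 || nc >= cols) { nr = r; nc = c; }
  StepOut out;
  out.next = nr * cols + nc;
  if (nc == 0) { out.reward = r_left; out.terminal = true; }
  else if (nc == cols - 1) { out.reward = r_right; out.terminal = true; }
  else { out.reward = 0.0; out.terminal = false; }
  return out;
}

// ---- Pong -------------------------------------------------------------------

struct PongParams {
  double width = 84.0, height = 84.0;
  double pad_len = 20.0;
  double agent_x = 80.0, opp_x = 3.0;
  double paddle_speed = 3.0, opp_speed = 1.5;
  double ball_vx = 2.0, max_vy = 2.5;
  double jitter = 0.67;       // ~ +/-15 degree reflection jitter at |vx| = 2
  double paddle_p = 0.9;      // P(intended paddle displacement), stochastic cfg
};

struct PongState {
  double bx, by, vx, vy, py, oy;
};

inline void pong_serve(PongState& st, const PongParams& pp) {
  st.bx = pp.width / 2.0;
  st.by = pp.height * (0.25 + 0.5 * ru());
  st.vx = pp.ball_vx;                     // toward the agent
  st.vy = -1.0 + 2.0 * ru();
}

inline void pong_reset(PongState& st, const PongParams& pp) {
  st.py = (pp.height - pp.pad_len) / 2.0;
  st.oy = (pp.height - pp.pad_len) / 2.0;
  pong_serve(st, pp);
}

struct PongOut {
  double reward = 0.0;
  bool terminal = false;
  int contact_segment = -1;   // 0..3 at agent-paddle contact, else -1
};

// Actions: 0 stay, 1 up (y decreases), 2 down.
inline PongOut pong_step(PongState& st, int action, bool stochastic,
                         int goal_kind /*0 flexible, 1 specific*/, int target,
                         const PongParams& pp) {
  PongOut out;
  // agent paddle (stochastic cfg: intended displacement with prob paddle_p,
  // otherwise one of the other two uniformly)
  int mv = action;
  if (stochastic && ru() >= pp.paddle_p) {
    int k = rint(2);
    mv = (k >= action) ? k + 1 : k;
  }
  if (mv == 1) st.py -= pp.paddle_speed;
  else if (mv == 2) st.py += pp.paddle_speed;
  st.py = clampd(st.py, 0.0, pp.height - pp.pad_len);
  // opponent tracks the ball with capped speed
  double want = st.by - pp.pad_len / 2.0;
  st.oy += clampd(want - st.oy, -pp.opp_speed, pp.opp_speed);
  st.oy = clampd(st.oy, 0.0, pp.height - pp.pad_len);
  // ball
  st.bx += st.vx;
  st.by += st.vy;
  if (st.by < 0) { st.by = -st.by; st.vy = -st.vy; }
  if (st.by > pp.height) { st.by = 2 * pp.height - st.by; st.vy = -st.vy; }

  if (st.vx > 0 && st.bx >= pp.agent_x) {
    if (st.by >= st.py && st.by <= st.py + pp.pad_len) {
      // agent-paddle contact
      double seg_len = pp.pad_len / 4.0;
      int seg = (int)std::floor((st.by - st.py) / seg_len);
      if (seg < 0) seg = 0;
      if (seg > 3) seg = 3;
      out.contact_segment = seg;
      if (goal_kind == 1) {
        out.reward = (seg == target) ? 1.0 : 0.0;
        out.terminal = true;
        return out;
      }
      double offset = st.by - (st.py + pp.pad_len / 2.0);
      st.bx = pp.agent_x;
      st.vx = -std::fabs(st.vx);
      st.vy = offset / (pp.pad_len / 2.0) * pp.max_vy;
      if (stochastic) st.vy += pp.jitter * (2.0 * ru() - 1.0);
      st.vy = clampd(st.vy, -pp.max_vy - 0.5, pp.max_vy + 0.5);
    } else if (st.bx > pp.agent_x + 2.0) {
      // agent missed
      out.reward = (goal_kind == 1) ? 0.0 : -1.0;
      out.terminal = true;
      return out;
    }
  } else if (st.vx < 0 && st.bx <= pp.opp_x) {
    if (st.by >= st.oy && st.by <= st.oy + pp.pad_len) {
      double offset = st.by - (st.oy + pp.pad_len / 2.0);
      st.bx = pp.opp_x;
      st.vx = std::fabs(st.vx);
      st.vy = offset / (pp.pad_len / 2.0) * pp.max_vy;
      if (stochastic) st.vy += pp.jitter * (2.0 * ru() - 1.0);
      st.vy = clampd(st.vy, -pp.max_vy - 0.5, pp.max_vy + 0.5);
    } else if (st.bx < pp.opp_x - 2.0) {
      // opponent missed
      if (goal_kind == 1) {
        pong_serve(st, pp);   // specific goal only ends at the agent's paddle
      } else {
        out.reward = 1.0;
        out.terminal = true;
        return out;
      }
    }
  }
  return out;
}

inline void pong_observe(const PongState& st, const PongParams& pp, double* obs) {
  obs[0] = st.bx / pp.width;
  obs[1] = st.by / pp.height;
  obs[2] = (st.vx + 3.0) / 6.0;
  obs[3] = (st.vy + 3.0) / 6.0;
  obs[4] = st.py / (pp.height - pp.pad_len);
  obs[5] = st.oy / (pp.height - pp.pad_len);
}

}  // namespace md

#endif
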