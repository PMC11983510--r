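// Tabular episode runners for the two-stage MDT and the LoCA-style gridworld.
// One shared agent core implements Q-learning, SARSA, FORWARD (pure
// model-based), Dyna-Q, Meta-Dyna and the hybrid arbitration agents
// (FORWARD+SARSA, FORWARD+Q-learning).
#include <Rcpp.h>
#include <deque>
#include <utility>
#include "core.h"
using namespace Rcpp;

namespace {

enum AgentType { A_QL = 0, A_SARSA, A_FORWARD, A_DYNAQ, A_META,
                 A_FSARSA, A_FQL };

int agent_code(const std::string& nm) {
  if (nm == "q-learning") return A_QL;
  if (nm == "sarsa") return A_SARSA;
  if (nm == "forward") return A_FORWARD;
  if (nm == "dyna-q") return A_DYNAQ;
  if (nm == "meta-dyna") return A_META;
  if (nm == "forward+sarsa") return A_FSARSA;
  if (nm == "forward+qlearning") return A_FQL;
  stop("unknown tabular agent: " + nm);
  return -1;
}

double getd(const List& cfg, const char* nm, double def) {
  return cfg.containsElementNamed(nm) ? as<double>(cfg[nm]) : def;
}
int geti(const List& cfg, const char* nm, int def) {
  return cfg.containsElementNamed(nm) ? as<int>(cfg[nm]) : def;
}
bool getb(const List& cfg, const char* nm, bool def) {
  return cfg.containsElementNamed(nm) ? as<bool>(cfg[nm]) : def;
}

struct TabCfg {
  double lr_mf, lr_mb, gamma, epsilon, eps_decay, eps_min;
  int n_planning, horizon, vi_sweeps, max_steps;
  double gamma_t, r_step;
  bool count_mode;
  double ph_eta, rpe_max, omega, dir_prior, dir_decay, p0, sim_epsilon;
  md::ArbParams arb;
  bool mf_per_step, planning_per_step, record_actions, wm_train_on_sim;
  int planning_backup;  // 0: sampled-successor TD target; 1: expectation over
                        // the model's successor distribution (jitter-free)
  int sim_start;  // 0: restart chains at the episode start state
                  // 1: restart chains at uniformly remembered states

  explicit TabCfg(const List& cfg) {
    lr_mf = getd(cfg, "lr_mf", 0.1);
    lr_mb = getd(cfg, "lr_mb", 0.1);
    gamma = getd(cfg, "gamma", 0.9);
    epsilon = getd(cfg, "epsilon", 0.1);
    eps_decay = getd(cfg, "eps_decay", 1.0);
    eps_min = getd(cfg, "eps_min", 0.0);
    n_planning = geti(cfg, "n_planning", 10);
    horizon = geti(cfg, "horizon", 30);
    vi_sweeps = geti(cfg, "vi_sweeps", 1);
    max_steps = geti(cfg, "max_steps", 100);
    gamma_t = getd(cfg, "gamma_t", 0.2);
    r_step = getd(cfg, "r_step", 0.2);
    count_mode = getb(cfg, "count_mode", false);
    ph_eta = getd(cfg, "ph_eta", 0.2);
    rpe_max = getd(cfg, "rpe_max", 1.0);
    omega = getd(cfg, "omega", 0.2);
    dir_prior = getd(cfg, "dir_prior", 1.0);
    dir_decay = getd(cfg, "dir_decay", 0.98);
    p0 = getd(cfg, "p_mb0", 0.5);
    sim_epsilon = getd(cfg, "sim_epsilon", 0.5);
    arb.Aa = getd(cfg, "A_alpha", 0.3);
    arb.Ba = getd(cfg, "B_alpha", 3.0);
    arb.Ab = getd(cfg, "A_beta", 0.3);
    arb.Bb = getd(cfg, "B_beta", 3.0);
    mf_per_step = getb(cfg, "mf_per_step", false);
    planning_per_step = getb(cfg, "planning_per_step", false);
    record_actions = getb(cfg, "record_actions", false);
    wm_train_on_sim = getb(cfg, "wm_train_on_sim", true);
    std::string pb = cfg.containsElementNamed("planning_backup")
                         ? as<std::string>(cfg["planning_backup"]) : "sample";
    planning_backup = (pb == "expected") ? 1 : 0;
    std::string ss = cfg.containsElementNamed("sim_start")
                         ? as<std::string>(cfg["sim_start"]) : "s0";
    sim_start = (ss == "visited") ? 1 : 0;
  }
};

struct Trans {
  int s, a, sn;
  double r;
  bool term, sim;
};

// environment interface driven by a per-episode schedule row
struct TabEnv {
  int S, A;
  std::vector<bool> term;
  virtual int reset(int ep) = 0;
  virtual md::StepOut step(int s, int a, int ep) = 0;
  virtual double max_reward(int ep) = 0;
  virtual int max_steps(const TabCfg& c) = 0;
  virtual ~TabEnv() {}
};

struct MdtEnv : TabEnv {
  NumericVector p, tokens;
  IntegerVector goal, target;
  MdtEnv(NumericVector p_, IntegerVector g_, IntegerVector t_, NumericVector tok)
      : p(p_), goal(g_), target(t_), tokens(tok) {
    S = 7; A = 2;
    term.assign(S, false);
    for (int s = 3; s < 7; ++s) term[s] = true;
  }
  int reset(int) override { return 0; }
  md::StepOut step(int s, int a, int ep) override {
    return md::mdt_step(s, a, p[ep], goal[ep], target[ep], tokens.begin());
  }
  double max_reward(int) override { return 1.0; }
  int max_steps(const TabCfg&) override { return 2; }
};

struct GridEnv : TabEnv {
  int rows, cols;
  NumericVector p, rl, rr;
  IntegerVector start_mode;
  GridEnv(int rows_, int cols_, NumericVector p_, NumericVector rl_,
          NumericVector rr_, IntegerVector sm)
      : rows(rows_), cols(cols_), p(p_), rl(rl_), rr(rr_), start_mode(sm) {
    S = rows * cols; A = 4;
    term.assign(S, false);
    for (int r = 0; r < rows; ++r) {
      term[r * cols] = true;
      term[r * cols + cols - 1] = true;
    }
  }
  int reset(int ep) override {
    int r = md::rint(rows);
    int c = start_mode[ep] == 1 ? 1 : 1 + md::rint(cols - 2);
    return r * cols + c;
  }
  md::StepOut step(int s, int a, int ep) override {
    return md::grid_step(s, a, p[ep], rows, cols, rl[ep], rr[ep]);
  }
  double max_reward(int ep) override { return std::max(rl[ep], rr[ep]); }
  int max_steps(const TabCfg& c) override { return c.max_steps; }
};

struct TabAgent {
  int type;
  TabCfg cfg;
  int S, A;
  std::vector<double> Qmf, Qmb;
  md::TabModel model;
  md::PHTracker ph;
  md::DirTracker dir;
  double pmb, eps;
  std::vector<bool> visited_flag;
  std::vector<int> visited_states;          // non-terminal states seen as s
  std::vector<std::pair<int,int>> visited_sa;
  std::vector<bool> visited_sa_flag;
  std::deque<Trans> model_queue;            // RB_MB entries not yet trained on
  long rbmf_size = 0, rbmf_sim = 0, qmb_real_updates = 0, sim_count = 0;

  TabAgent(int type_, const TabCfg& c, const TabEnv& env)
      : type(type_), cfg(c), S(env.S), A(env.A) {
    Qmf.assign((size_t)S * A, 0.0);
    Qmb.assign((size_t)S * A, 0.0);
    model.init(S, A);
    model.gamma_t = c.gamma_t;
    model.r_step = c.r_step;
    model.count_mode = c.count_mode;
    ph.eta = c.ph_eta; ph.rpe_max = c.rpe_max;
    dir.prior = c.dir_prior; dir.decay = c.dir_decay;
    pmb = c.p0;
    eps = c.epsilon;
    visited_flag.assign(S, false);
    visited_sa_flag.assign((size_t)S * A, false);
  }

  bool arbitrating() const {
    return type == A_META || type == A_FSARSA || type == A_FQL;
  }
  double qval(int s, int a) const {
    size_t i = (size_t)s * A + a;
    if (type == A_QL || type == A_SARSA || type == A_DYNAQ) return Qmf[i];
    if (type == A_FORWARD) return Qmb[i];
    return pmb * Qmb[i] + (1.0 - pmb) * Qmf[i];
  }
  int act(int s) {
    std::vector<double> q(A);
    for (int a = 0; a < A; ++a) q[a] = qval(s, a);
    return md::eps_greedy(q.data(), A, eps);
  }
  void note_visit(int s, int a, const std::vector<bool>& term) {
    if (!term[s] && !visited_flag[s]) {
      visited_flag[s] = true;
      visited_states.push_back(s);
    }
    size_t sa = (size_t)s * A + a;
    if (!visited_sa_flag[sa]) {
      visited_sa_flag[sa] = true;
      visited_sa.push_back({s, a});
    }
  }
  double vmax(const std::vector<double>& Q, int s,
              const std::vector<bool>& term) const {
    if (term[s]) return 0.0;
    double m = Q[(size_t)s * A];
    for (int a = 1; a < A; ++a) m = std::max(m, Q[(size_t)s * A + a]);
    return m;
  }
  void qlearn(std::vector<double>& Q, const Trans& t, double lr,
              const std::vector<bool>& term) {
    size_t i = (size_t)t.s * A + t.a;
    double tgt = t.r + (t.term ? 0.0 : cfg.gamma * vmax(Q, t.sn, term));
    Q[i] += lr * (tgt - Q[i]);
  }
  // model update with SPE bookkeeping for real transitions
  void model_train_one(const Trans& t, bool track_spe) {
    if (track_spe) {
      double spe = 1.0 - model.tprob(t.s, t.a, t.sn);
      dir.observe(md::classify_pe(spe, cfg.omega));
    }
    model.update(t.s, t.a, t.sn, t.r);
  }
  void vi_sweep(const std::vector<bool>& term) {
    for (int k = 0; k < cfg.vi_sweeps; ++k) {
      for (int s = 0; s < S; ++s) {
        if (term[s]) continue;
        for (int a = 0; a < A; ++a) {
          const double* row = model.row(s, a);
          double v = model.Rhat[(size_t)s * A + a];
          for (int sn = 0; sn < S; ++sn)
            if (row[sn] > 0 && !term[sn]) v += cfg.gamma * row[sn] * vmax(Qmb, sn, term);
          Qmb[(size_t)s * A + a] = v;
        }
      }
    }
  }
  // Meta-Dyna mental simulation: n simulated transitions per episode.
  // Chains start at the episode start state (or uniformly remembered states),
  // choose actions epsilon-greedily on the integrated values with the
  // simulation exploration rate, stop at predicted terminals, and are then
  // replayed in reverse order into Q_MB (reverse replay: one chain suffices
  // to propagate terminal reward back to the chain's start). Simulated
  // transitions train Q_MB only and are appended to the world-model buffer.
  void plan_meta(const std::vector<bool>& term, int s0) {
    if (visited_states.empty()) return;  // cold model: never fabricate
    int done = 0;
    std::vector<Trans> chain;
    while (done < cfg.n_planning) {
      int s = (cfg.sim_start == 1)
                  ? visited_states[md::rint((int)visited_states.size())]
                  : s0;
      int depth = 0;
      chain.clear();
      while (done < cfg.n_planning && depth < cfg.horizon) {
        std::vector<double> q(A);
        for (int a = 0; a < A; ++a) q[a] = qval(s, a);
        int a = md::eps_greedy(q.data(), A, cfg.sim_epsilon);
        int sn = md::sample_categorical(model.row(s, a), S);
        Trans t{s, a, sn, model.Rhat[(size_t)s * A + a], term[sn], true};
        chain.push_back(t);
        model_queue.push_back(t);
        ++sim_count; ++done; ++depth;
        if (t.term) break;
        s = sn;
      }
      for (int i = (int)chain.size() - 1; i >= 0; --i) {
        if (cfg.planning_backup == 1) {
          const Trans& t = chain[i];
          const double* row = model.row(t.s, t.a);
          double tgt = t.r;
          for (int sn = 0; sn < S; ++sn)
            if (row[sn] > 0 && !term[sn])
              tgt += cfg.gamma * row[sn] * vmax(Qmb, sn, term);
          size_t ix = (size_t)t.s * A + t.a;
          Qmb[ix] += cfg.lr_mb * (tgt - Qmb[ix]);
        } else {
          qlearn(Qmb, chain[i], cfg.lr_mb, term);
        }
      }
    }
  }
  // classical Dyna-Q planning: random revisits of known (s,a)
  void plan_dyna(const std::vector<bool>& term, int n) {
    if (visited_sa.empty()) return;
    for (int i = 0; i < n; ++i) {
      auto sa = visited_sa[md::rint((int)visited_sa.size())];
      int sn = md::sample_categorical(model.row(sa.first, sa.second), S);
      Trans t{sa.first, sa.second, sn,
              model.Rhat[(size_t)sa.first * A + sa.second], term[sn], true};
      qlearn(Qmf, t, cfg.lr_mf, term);
      ++sim_count;
    }
  }
};

}  // namespace

static List run_tabular(TabEnv& env, const std::string& agent_name,
                        const List& cfg_list, int n_episodes) {
  TabCfg cfg(cfg_list);
  int type = agent_code(agent_name);
  TabAgent ag(type, cfg, env);

  NumericVector ep_reward(n_episodes), ep_pmb(n_episodes),
      ep_relmf(n_episodes), ep_relmb(n_episodes);
  IntegerVector ep_optimal(n_episodes), ep_steps(n_episodes);
  std::vector<int> act_trace;

  std::vector<Trans> episode;
  for (int ep = 0; ep < n_episodes; ++ep) {
    episode.clear();
    int s = env.reset(ep);
    const int s_start = s;
    int cap = env.max_steps(cfg);
    double total = 0.0;
    int a_pending = -1;
    for (int st = 0; st < cap; ++st) {
      int a = (type == A_SARSA && a_pending >= 0) ? a_pending : ag.act(s);
      if (cfg.record_actions) act_trace.push_back(a);
      md::StepOut o = env.step(s, a, ep);
      Trans tr{s, a, o.next, o.reward, o.terminal, false};
      episode.push_back(tr);
      ag.note_visit(s, a, env.term);
      total += o.reward;
      ++ag.rbmf_size;

      switch (type) {
        case A_QL:
          ag.qlearn(ag.Qmf, tr, cfg.lr_mf, env.term);
          break;
        case A_SARSA: {
          double qn = 0.0;
          if (!o.terminal) {
            a_pending = ag.act(o.next);
            qn = ag.Qmf[(size_t)o.next * env.A + a_pending];
          }
          size_t i = (size_t)s * env.A + a;
          ag.Qmf[i] += cfg.lr_mf * (o.reward + cfg.gamma * qn - ag.Qmf[i]);
          break;
        }
        case A_FORWARD:
          ag.model_train_one(tr, false);
          break;
        case A_DYNAQ:
          ag.qlearn(ag.Qmf, tr, cfg.lr_mf, env.term);
          ag.model_train_one(tr, false);
          if (cfg.planning_per_step) ag.plan_dyna(env.term, cfg.n_planning);
          break;
        case A_META:
          if (cfg.mf_per_step) {
            double q_next = tr.term ? 0.0 : ag.vmax(ag.Qmf, tr.sn, env.term);
            double e = md::rpe(tr.r, q_next, ag.Qmf[(size_t)tr.s * env.A + tr.a],
                               cfg.gamma);
            ag.ph.update(e);
            ag.qlearn(ag.Qmf, tr, cfg.lr_mf, env.term);
          }
          ag.model_queue.push_back(tr);  // real experience also feeds RB_MB
          break;
        case A_FSARSA:
        case A_FQL: {
          // hybrids: per-step MF learner + per-step model learning with SPE
          double q_next;
          if (type == A_FSARSA) {
            q_next = 0.0;
            if (!o.terminal) {
              a_pending = ag.act(o.next);
              q_next = ag.Qmf[(size_t)o.next * env.A + a_pending];
            }
          } else {
            q_next = tr.term ? 0.0 : ag.vmax(ag.Qmf, tr.sn, env.term);
          }
          size_t i = (size_t)s * env.A + a;
          double e = md::rpe(o.reward, q_next, ag.Qmf[i], cfg.gamma);
          ag.ph.update(e);
          ag.Qmf[i] += cfg.lr_mf * e;
          ag.model_train_one(tr, true);
          break;
        }
      }
      s = o.next;
      if (o.terminal) break;
    }

    // post-episode phases
    switch (type) {
      case A_FORWARD:
        ag.vi_sweep(env.term);
        break;
      case A_DYNAQ:
        if (!cfg.planning_per_step) ag.plan_dyna(env.term, cfg.n_planning);
        break;
      case A_META: {
        // (1) train Q_MF on the episode's real experience; collect RPEs
        if (!cfg.mf_per_step) {
          for (const Trans& tr : episode) {
            double q_next = tr.term ? 0.0 : ag.vmax(ag.Qmf, tr.sn, env.term);
            double e = md::rpe(tr.r, q_next,
                               ag.Qmf[(size_t)tr.s * env.A + tr.a], cfg.gamma);
            ag.ph.update(e);
            ag.qlearn(ag.Qmf, tr, cfg.lr_mf, env.term);
          }
        }
        // (2) train the world model on new RB_MB entries (previous planning's
        //     simulated transitions, then this episode's real ones); SPE and
        //     the Dirichlet reliability come from real transitions only
        while (!ag.model_queue.empty()) {
          Trans t = ag.model_queue.front();
          ag.model_queue.pop_front();
          if (!t.sim || cfg.wm_train_on_sim) ag.model_train_one(t, !t.sim);
        }
        // (3) mental simulation trains Q_MB only
        ag.plan_meta(env.term, s_start);
        // (4) reliability -> P_MB -> integrated Q (integration is implicit in
        //     qval(); Eq. 5 convex combination)
        ag.pmb = md::pmb_update(ag.pmb, ag.ph.rel(), ag.dir.mean_zero(), cfg.arb);
        break;
      }
      case A_FSARSA:
      case A_FQL:
        ag.vi_sweep(env.term);
        ag.pmb = md::pmb_update(ag.pmb, ag.ph.rel(), ag.dir.mean_zero(), cfg.arb);
        break;
      default:
        break;
    }
    ag.eps = std::max(cfg.eps_min, ag.eps * cfg.eps_decay);

    ep_reward[ep] = total;
    ep_optimal[ep] = std::fabs(total - env.max_reward(ep)) < 1e-9 ? 1 : 0;
    ep_steps[ep] = (int)episode.size();
    ep_pmb[ep] = ag.arbitrating() ? ag.pmb : NA_REAL;
    ep_relmf[ep] = ag.arbitrating() ? ag.ph.rel() : NA_REAL;
    ep_relmb[ep] = ag.arbitrating() ? ag.dir.mean_zero() : NA_REAL;
  }

  NumericMatrix qmf(env.S, env.A), qmb(env.S, env.A);
  for (int s = 0; s < env.S; ++s)
    for (int a = 0; a < env.A; ++a) {
      qmf(s, a) = ag.Qmf[(size_t)s * env.A + a];
      qmb(s, a) = ag.Qmb[(size_t)s * env.A + a];
    }
  NumericMatrix t_est(env.S * env.A, env.S);
  NumericVector r_est(env.S * env.A);
  IntegerVector visits(env.S * env.A);
  for (int sa = 0; sa < env.S * env.A; ++sa) {
    r_est[sa] = ag.model.Rhat[sa];
    visits[sa] = ag.model.visits[sa];
    for (int sn = 0; sn < env.S; ++sn) t_est(sa, sn) = ag.model.T[(size_t)sa * env.S + sn];
  }
  List out = List::create(
      _["reward"] = ep_reward, _["optimal"] = ep_optimal, _["steps"] = ep_steps,
      _["p_mb"] = ep_pmb, _["rel_mf"] = ep_relmf, _["rel_mb"] = ep_relmb,
      _["q_mf"] = qmf, _["q_mb"] = qmb, _["t_est"] = t_est, _["r_est"] = r_est,
      _["visits"] = visits,
      _["diag"] = List::create(_["rbmf_simulated"] = ag.rbmf_sim,
                               _["rbmf_size"] = ag.rbmf_size,
                               _["qmb_real_updates"] = ag.qmb_real_updates,
                               _["simulated_transitions"] = ag.sim_count));
  if (cfg.record_actions) out["actions"] = wrap(act_trace);
  return out;
}

// [[Rcpp::export]]
List run_mdt_tabular_cpp(std::string agent, NumericVector p_intended,
                         IntegerVector goal_kind, IntegerVector target,
                         NumericVector token_values, List cfg) {
  MdtEnv env(p_intended, goal_kind, target, token_values);
  return run_tabular(env, agent, cfg, p_intended.size());
}

// [[Rcpp::export]]
List run_grid_tabular_cpp(std::string agent, int rows, int cols,
                          NumericVector p_intended, NumericVector r_left,
                          NumericVector r_right, IntegerVector start_mode,
                          List cfg) {
  GridEnv env(rows, cols, p_intended, r_left, r_right, start_mode);
  return run_tabular(env, agent, cfg, p_intended.size());
}
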