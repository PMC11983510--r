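// Network-backed agent runners: DQN, Dyna-Q (network variant) and Meta-Dyna
// with feed-forward Q networks and the recurrent mixture-density world model.
// Used for the network MDT variant and the Pong environment.
#include <RcppArmadillo.h>
#include <deque>
#include "core.h"
#include "net.h"
using namespace Rcpp;

namespace {

enum NetAgent { N_DQN = 0, N_DYNAQ, N_META };

int net_agent_code(const std::string& nm) {
  if (nm == "dqn") return N_DQN;
  if (nm == "dyna-q") return N_DYNAQ;
  if (nm == "meta-dyna") return N_META;
  stop("unknown network agent: " + nm);
  return -1;
}

double getd(const List& cfg, const char* nm, double def) {
  return cfg.containsElementNamed(nm) ? as<double>(cfg[nm]) : def;
}
int geti(const List& cfg, const char* nm, int def) {
  return cfg.containsElementNamed(nm) ? as<int>(cfg[nm]) : def;
}

struct NetCfg {
  int h_q, h_wm, K, n_planning, horizon, wm_seq_len, wm_reps, batch,
      train_every, target_sync, replay_cap, max_steps;
  bool wm_train_on_sim, mf_per_step;
  double lr_q, lr_q_mb, lr_wm, gamma, epsilon, eps_decay, eps_min, temperature,
      ph_eta, rpe_max, omega, dir_prior, dir_decay, p0, sim_epsilon;
  int sim_start;
  md::ArbParams arb;

  explicit NetCfg(const List& cfg) {
    h_q = geti(cfg, "hidden_q", 32);
    h_wm = geti(cfg, "hidden_wm", 32);
    K = geti(cfg, "n_components", 5);
    n_planning = geti(cfg, "n_planning", 10);
    horizon = geti(cfg, "horizon", 30);
    wm_seq_len = geti(cfg, "wm_seq_len", 16);
    wm_reps = geti(cfg, "wm_reps", 2);
    batch = geti(cfg, "batch_size", 16);
    train_every = geti(cfg, "train_every", 4);
    target_sync = geti(cfg, "target_sync", 100);
    replay_cap = geti(cfg, "replay_capacity", 10000);
    max_steps = geti(cfg, "max_steps", 600);
    lr_q = getd(cfg, "lr_q", 1e-3);
    lr_q_mb = getd(cfg, "lr_q_mb", -1.0);
    if (lr_q_mb <= 0) lr_q_mb = lr_q;   // default: same Adam rate as Q_MF
    lr_wm = getd(cfg, "lr_wm", 1e-3);
    gamma = getd(cfg, "gamma", 0.9);
    epsilon = getd(cfg, "epsilon", 0.1);
    eps_decay = getd(cfg, "eps_decay", 1.0);
    eps_min = getd(cfg, "eps_min", 0.0);
    temperature = getd(cfg, "temperature", 1.0);
    ph_eta = getd(cfg, "ph_eta", 0.2);
    rpe_max = getd(cfg, "rpe_max", 1.0);
    omega = getd(cfg, "omega", 1.0);
    dir_prior = getd(cfg, "dir_prior", 1.0);
    dir_decay = getd(cfg, "dir_decay", 0.98);
    p0 = getd(cfg, "p_mb0", 0.5);
    sim_epsilon = getd(cfg, "sim_epsilon", 0.6);
    wm_train_on_sim = cfg.containsElementNamed("wm_train_on_sim")
                          ? as<bool>(cfg["wm_train_on_sim"]) : true;
    mf_per_step = cfg.containsElementNamed("mf_per_step")
                      ? as<bool>(cfg["mf_per_step"]) : false;
    arb.Aa = getd(cfg, "A_alpha", 0.3);
    arb.Ba = getd(cfg, "B_alpha", 3.0);
    arb.Ab = getd(cfg, "A_beta", 0.3);
    arb.Bb = getd(cfg, "B_beta", 3.0);
    std::string ss = cfg.containsElementNamed("sim_start")
                         ? as<std::string>(cfg["sim_start"]) : "s0";
    sim_start = (ss == "visited") ? 1 : 0;
  }
};

// vector-observation environment interface
struct VecEnv {
  int D = 0, nA = 0;
  virtual void reset(int ep, arma::vec& obs) = 0;
  virtual bool step(int a, arma::vec& obs_next, double& r) = 0;  // -> terminal
  virtual int max_steps(const NetCfg& c) = 0;
  virtual ~VecEnv() {}
};

struct MdtVecEnv : VecEnv {
  NumericVector p, tokens;
  IntegerVector goal, target;
  int state = 0, ep_cur = 0;
  MdtVecEnv(NumericVector p_, IntegerVector g_, IntegerVector t_,
            NumericVector tok)
      : p(p_), goal(g_), target(t_), tokens(tok) {
    D = 7; nA = 2;
  }
  void onehot(int s, arma::vec& obs) {
    obs.zeros(D);
    obs(s) = 1.0;
  }
  void reset(int ep, arma::vec& obs) override {
    ep_cur = ep;
    state = 0;
    onehot(state, obs);
  }
  bool step(int a, arma::vec& obs_next, double& r) override {
    md::StepOut o = md::mdt_step(state, a, p[ep_cur], goal[ep_cur],
                                 target[ep_cur], tokens.begin());
    state = o.next;
    onehot(state, obs_next);
    r = o.reward;
    return o.terminal;
  }
  int max_steps(const NetCfg&) override { return 2; }
};

struct PongVecEnv : VecEnv {
  LogicalVector seg_stoch;
  IntegerVector seg_goal, seg_target;
  int period;
  long t_global = 0;
  md::PongParams pp;
  md::PongState st;
  PongVecEnv(LogicalVector ss, IntegerVector sg, IntegerVector stg, int per,
             double paddle_p)
      : seg_stoch(ss), seg_goal(sg), seg_target(stg), period(per) {
    D = 6; nA = 3;
    pp.paddle_p = paddle_p;
  }
  int seg() const {
    long k = t_global / period;
    if (k >= seg_stoch.size()) k = seg_stoch.size() - 1;
    return (int)k;
  }
  void reset(int, arma::vec& obs) override {
    md::pong_reset(st, pp);
    obs.set_size(D);
    md::pong_observe(st, pp, obs.memptr());
  }
  bool step(int a, arma::vec& obs_next, double& r) override {
    int k = seg();
    md::PongOut o = md::pong_step(st, a, seg_stoch[k], seg_goal[k],
                                  seg_target[k], pp);
    ++t_global;
    obs_next.set_size(D);
    md::pong_observe(st, pp, obs_next.memptr());
    r = o.reward;
    return o.terminal;
  }
  int max_steps(const NetCfg& c) override { return c.max_steps; }
};

// one episode of experience, in order (the recurrent model trains on
// episode-ordered sequences only)
struct Seq {
  arma::mat S, Sn;          // D x T
  std::vector<int> a;
  arma::vec r, term, spe, rpe;
  bool simulated = false;
};

struct WmBuffer {
  std::deque<Seq> seqs;
  size_t cap = 64;
  void push(Seq s) {
    seqs.push_back(std::move(s));
    if (seqs.size() > cap) seqs.pop_front();
  }
};

arma::mat build_inputs(const Seq& q, int nA) {
  int D = q.S.n_rows, T = q.S.n_cols;
  arma::mat X(D + nA + 2, T, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    X.submat(0, t, D - 1, t) = q.S.col(t);
    X(D + q.a[t], t) = 1.0;
    if (t > 0) {
      X(D + nA, t) = q.spe(t - 1);
      X(D + nA + 1, t) = q.rpe(t - 1);
    }
  }
  return X;
}

void wm_train_on(md::GRUMDN& wm, const Seq& q, int nA, int seq_len) {
  int T = q.S.n_cols;
  arma::mat X = build_inputs(q, nA);
  int lo = 0, hi = T - 1;
  if (T > seq_len) {
    lo = md::rint(T - seq_len + 1);
    hi = lo + seq_len - 1;
  }
  wm.train_seq(X.cols(lo, hi), q.Sn.cols(lo, hi),
               q.r.subvec(lo, hi), q.term.subvec(lo, hi));
}

struct Reservoir {
  std::vector<arma::vec> buf;
  size_t cap = 512, next = 0;
  void push(const arma::vec& s) {
    if (buf.size() < cap) buf.push_back(s);
    else { buf[next] = s; next = (next + 1) % cap; }
  }
  const arma::vec& sample() const { return buf[md::rint((int)buf.size())]; }
  bool empty() const { return buf.empty(); }
};

struct Replay {
  arma::mat S, Sn;
  std::vector<int> a;
  arma::vec r, term;
  int cap, n = 0, next = 0;
  void init(int D, int cap_) {
    cap = cap_;
    S.set_size(D, cap); Sn.set_size(D, cap);
    a.assign(cap, 0); r.set_size(cap); term.set_size(cap);
  }
  void push(const arma::vec& s, int a_, double r_, const arma::vec& sn, bool t_) {
    S.col(next) = s; Sn.col(next) = sn;
    a[next] = a_; r(next) = r_; term(next) = t_ ? 1.0 : 0.0;
    next = (next + 1) % cap;
    if (n < cap) ++n;
  }
};

}  // namespace

static List run_net(VecEnv& env, const std::string& agent_name,
                    const List& cfg_list, int n_episodes) {
  NetCfg cfg(cfg_list);
  int type = net_agent_code(agent_name);
  int D = env.D, nA = env.nA;

  md::MLP qmf, qmb, qtarget;
  qmf.init(D, cfg.h_q, nA, cfg.lr_q);
  if (type == N_META) qmb.init(D, cfg.h_q, nA, cfg.lr_q_mb);
  if (type == N_DQN) { qtarget.init(D, cfg.h_q, nA, cfg.lr_q); qtarget.copy_from(qmf); }
  md::GRUMDN wm;
  if (type != N_DQN) wm.init(D, nA, cfg.h_wm, cfg.K, cfg.lr_wm);

  Replay replay;
  if (type == N_DQN) replay.init(D, cfg.replay_cap);
  WmBuffer rb_mb;
  Reservoir reservoir;
  md::PHTracker ph; ph.eta = cfg.ph_eta; ph.rpe_max = cfg.rpe_max;
  md::DirTracker dir; dir.prior = cfg.dir_prior; dir.decay = cfg.dir_decay;
  double pmb = cfg.p0, eps = cfg.epsilon;
  long steps_total = 0;

  NumericVector ep_reward(n_episodes), ep_pmb(n_episodes), ep_relmf(n_episodes),
      ep_relmb(n_episodes);
  IntegerVector ep_optimal(n_episodes), ep_steps(n_episodes),
      ep_interactions(n_episodes);

  auto qvals = [&](const arma::vec& s) {
    arma::vec q = qmf.forward(s);
    if (type == N_META) q = pmb * qmb.forward(s) + (1.0 - pmb) * q;
    return q;
  };

  arma::vec s(D), sn(D);
  for (int ep = 0; ep < n_episodes; ++ep) {
    env.reset(ep, s);
    double total = 0.0;
    int cap = env.max_steps(cfg);
    Seq epi;
    std::vector<arma::vec> Ss, Sns;
    std::vector<int> as;
    std::vector<double> rs, terms, rpe_step;
    for (int st = 0; st < cap; ++st) {
      arma::vec q = qvals(s);
      int a = md::eps_greedy(q.memptr(), nA, eps);
      double r;
      bool term = env.step(a, sn, r);
      total += r;
      ++steps_total;
      reservoir.push(s);
      Ss.push_back(s); Sns.push_back(sn);
      as.push_back(a); rs.push_back(r); terms.push_back(term ? 1.0 : 0.0);

      if (type == N_DQN) {
        replay.push(s, a, r, sn, term);
        if (replay.n >= cfg.batch && steps_total % cfg.train_every == 0) {
          int B = cfg.batch;
          arma::mat X(D, B), Xn(D, B);
          std::vector<int> ab(B);
          arma::vec tgt(B);
          for (int b = 0; b < B; ++b) {
            int i = md::rint(replay.n);
            X.col(b) = replay.S.col(i);
            Xn.col(b) = replay.Sn.col(i);
            ab[b] = replay.a[i];
            tgt(b) = replay.r(i);
            if (replay.term(i) < 0.5) {
              arma::vec qn = qtarget.forward(Xn.col(b));
              tgt(b) += cfg.gamma * qn.max();
            }
          }
          qmf.td_batch(X, ab, tgt);
        }
        if (steps_total % cfg.target_sync == 0) qtarget.copy_from(qmf);
      } else if (type == N_DYNAQ) {
        // online single-sample Q update from real experience
        double tgt = r;
        if (!term) tgt += cfg.gamma * qmf.forward(sn).max();
        qmf.td_step(s, a, tgt);
      } else if (type == N_META && cfg.mf_per_step) {
        double tgt = r;
        if (!term) tgt += cfg.gamma * qmf.forward(sn).max();
        double e = tgt - qmf.forward(s)(a);
        rpe_step.push_back(e);
        ph.update(e);
        qmf.td_step(s, a, tgt);
      }
      s = sn;
      if (term) break;
    }
    int T = (int)Ss.size();

    if (type != N_DQN && T > 0) {
      epi.S.set_size(D, T); epi.Sn.set_size(D, T);
      epi.r.set_size(T); epi.term.set_size(T);
      epi.spe.zeros(T); epi.rpe.zeros(T);
      epi.a = as;
      for (int t = 0; t < T; ++t) {
        epi.S.col(t) = Ss[t];
        epi.Sn.col(t) = Sns[t];
        epi.r(t) = rs[t];
        epi.term(t) = terms[t];
      }
      if (type == N_META) {
        // (1) Q_MF trains on the episode's real experience; RPEs feed the
        //     Pearce-Hall reliability (per-episode batch by default, online
        //     per-step behind the mf_per_step flag)
        if (cfg.mf_per_step) {
          for (int t = 0; t < T; ++t) epi.rpe(t) = rpe_step[t];
        } else {
          for (int t = 0; t < T; ++t) {
            double tgt = epi.r(t);
            if (epi.term(t) < 0.5) tgt += cfg.gamma * qmf.forward(epi.Sn.col(t)).max();
            double e = tgt - qmf.forward(epi.S.col(t))(epi.a[t]);
            epi.rpe(t) = e;
            ph.update(e);
            qmf.td_step(epi.S.col(t), epi.a[t], tgt);
          }
        }
        // (2) SPE from the world model's pre-update predictions; Dirichlet
        //     reliability over {negative, zero, positive} SPE categories
        {
          arma::vec h(wm.H, arma::fill::zeros);
          for (int t = 0; t < T; ++t) {
            arma::vec x(wm.in, arma::fill::zeros);
            x.subvec(0, D - 1) = epi.S.col(t);
            x(D + epi.a[t]) = 1.0;
            if (t > 0) { x(D + nA) = epi.spe(t - 1); x(D + nA + 1) = epi.rpe(t - 1); }
            h = wm.cell(x, h, nullptr);
            arma::vec y = wm.Wo * h + wm.bo.col(0);
            md::GMMPred p = wm.head(y);
            double spe = md::spe_zscore(epi.Sn.col(t), p);
            epi.spe(t) = spe;
            dir.observe(md::classify_pe(spe, cfg.omega));
          }
        }
      }
      // (3) world model trains on RB_MB (real + simulated sequences)
      rb_mb.push(epi);
      wm_train_on(wm, rb_mb.seqs.back(), nA, cfg.wm_seq_len);
      for (int rep = 1; rep < cfg.wm_reps && rb_mb.seqs.size() > 1; ++rep)
        wm_train_on(wm, rb_mb.seqs[md::rint((int)rb_mb.seqs.size())], nA,
                    cfg.wm_seq_len);

      // (4) mental simulation: n simulated transitions train the planner's Q
      if (!reservoir.empty() && ep > 0) {
        md::MLP& qplan = (type == N_META) ? qmb : qmf;
        int done = 0;
        Seq sim;
        std::vector<arma::vec> sS, sSn;
        std::vector<int> sa;
        std::vector<double> sr, sterm;
        while (done < cfg.n_planning) {
          arma::vec cur = (cfg.sim_start == 1) ? reservoir.sample()
                                               : epi.S.col(0);
          arma::vec h(wm.H, arma::fill::zeros);
          int depth = 0;
          int chain_lo = (int)sS.size();
          while (done < cfg.n_planning && depth < cfg.horizon) {
            arma::vec q = (type == N_META) ? (pmb * qmb.forward(cur) +
                                              (1.0 - pmb) * qmf.forward(cur))
                                           : qmf.forward(cur);
            int a = md::eps_greedy(q.memptr(), nA, cfg.sim_epsilon);
            arma::vec x(wm.in, arma::fill::zeros);
            x.subvec(0, D - 1) = cur;
            x(D + a) = 1.0;
            h = wm.cell(x, h, nullptr);
            arma::vec y = wm.Wo * h + wm.bo.col(0);
            md::GMMPred p = wm.head(y, cfg.temperature);
            arma::vec nxt;
            double r;
            bool term;
            wm.sample(p, cfg.temperature, nxt, r, term);
            sS.push_back(cur); sSn.push_back(nxt);
            sa.push_back(a); sr.push_back(r); sterm.push_back(term ? 1.0 : 0.0);
            ++done; ++depth;
            if (term) break;
            cur = nxt;
          }
          // reverse replay of the chain into the planner's Q
          for (int i = (int)sS.size() - 1; i >= chain_lo; --i) {
            double tgt = sr[i];
            if (sterm[i] < 0.5) tgt += cfg.gamma * qplan.forward(sSn[i]).max();
            qplan.td_step(sS[i], sa[i], tgt);
          }
        }
        if (!sS.empty() && cfg.wm_train_on_sim) {
          int Ts = (int)sS.size();
          sim.S.set_size(D, Ts); sim.Sn.set_size(D, Ts);
          sim.r.set_size(Ts); sim.term.set_size(Ts);
          sim.spe.zeros(Ts); sim.rpe.zeros(Ts);
          sim.a = sa; sim.simulated = true;
          for (int t = 0; t < Ts; ++t) {
            sim.S.col(t) = sS[t]; sim.Sn.col(t) = sSn[t];
            sim.r(t) = sr[t]; sim.term(t) = sterm[t];
          }
          rb_mb.push(std::move(sim));
        }
      }
      // (5) reliabilities -> P_MB
      if (type == N_META)
        pmb = md::pmb_update(pmb, ph.rel(), dir.mean_zero(), cfg.arb);
    }

    eps = std::max(cfg.eps_min, eps * cfg.eps_decay);
    ep_reward[ep] = total;
    ep_optimal[ep] = std::fabs(total - 1.0) < 1e-9 ? 1 : 0;
    ep_steps[ep] = T;
    ep_interactions[ep] = (int)steps_total;
    ep_pmb[ep] = type == N_META ? pmb : NA_REAL;
    ep_relmf[ep] = type == N_META ? ph.rel() : NA_REAL;
    ep_relmb[ep] = type == N_META ? dir.mean_zero() : NA_REAL;
    if (ep % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["reward"] = ep_reward, _["optimal"] = ep_optimal,
                      _["steps"] = ep_steps, _["interactions"] = ep_interactions,
                      _["p_mb"] = ep_pmb, _["rel_mf"] = ep_relmf,
                      _["rel_mb"] = ep_relmb);
}

// [[Rcpp::export]]
List run_mdt_net_cpp(std::string agent, NumericVector p_intended,
                     IntegerVector goal_kind, IntegerVector target,
                     NumericVector token_values, List cfg) {
  MdtVecEnv env(p_intended, goal_kind, target, token_values);
  return run_net(env, agent, cfg, p_intended.size());
}

// [[Rcpp::export]]
List run_pong_cpp(std::string agent, int n_episodes, LogicalVector seg_stochastic,
                  IntegerVector seg_goal, IntegerVector seg_target, int period,
                  double paddle_p, List cfg) {
  PongVecEnv env(seg_stochastic, seg_goal, seg_target, period, paddle_p);
  return run_net(env, agent, cfg, n_episodes);
}
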