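#ifndef METADYNA_NET_H
#define METADYNA_NET_H

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
#include "core.h"

namespace md {

// All weight initialisation uses R's RNG (norm_rand) for seed determinism.
inline arma::mat rinit(int r, int c, double scale) {
  arma::mat m(r, c);
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = scale * norm_rand();
  return m;
}

struct Adam {
  arma::mat m, v;
  double lr = 1e-3;
  long t = 0;
  void init(const arma::mat& p) { m.zeros(arma::size(p)); v.zeros(arma::size(p)); }
  void step(arma::mat& p, const arma::mat& g) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    ++t;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

// ---- feed-forward Q network (one ReLU hidden layer) -------------------------

struct MLP {
  arma::mat W1, W2, b1, b2;
  Adam aW1, aW2, ab1, ab2;

  void init(int in, int h, int out, double lr) {
    W1 = rinit(h, in, std::sqrt(2.0 / in));
    W2 = rinit(out, h, std::sqrt(2.0 / h));
    b1.zeros(h, 1);
    b2.zeros(out, 1);
    aW1.init(W1); aW2.init(W2); ab1.init(b1); ab2.init(b2);
    aW1.lr = aW2.lr = ab1.lr = ab2.lr = lr;
  }
  arma::vec forward(const arma::vec& x) const {
    arma::vec h = arma::clamp(W1 * x + b1, 0.0, arma::datum::inf);
    return W2 * h + b2;
  }
  // squared-TD-error gradient step on a batch of (x, a, target)
  void td_batch(const arma::mat& X, const std::vector<int>& acts,
                const arma::vec& tgt) {
    int B = X.n_cols;
    arma::mat A1 = W1 * X;
    A1.each_col() += b1.col(0);
    arma::mat H = arma::clamp(A1, 0.0, arma::datum::inf);
    arma::mat Q = W2 * H;
    Q.each_col() += b2.col(0);
    arma::mat dQ(Q.n_rows, B, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      dQ(acts[b], b) = (Q(acts[b], b) - tgt(b)) / B;
    arma::mat gW2 = dQ * H.t();
    arma::mat gb2 = arma::sum(dQ, 1);
    arma::mat dH = W2.t() * dQ;
    dH.elem(arma::find(A1 <= 0)).zeros();
    arma::mat gW1 = dH * X.t();
    arma::mat gb1 = arma::sum(dH, 1);
    aW1.step(W1, gW1); aW2.step(W2, gW2); ab1.step(b1, gb1); ab2.step(b2, gb2);
  }
  void td_step(const arma::vec& x, int a, double target) {
    td_batch(arma::mat(x), std::vector<int>{a}, arma::vec{target});
  }
  void copy_from(const MLP& o) { W1 = o.W1; W2 = o.W2; b1 = o.b1; b2 = o.b2; }
};

// ---- recurrent mixture-density world model ----------------------------------
// Single-layer GRU; the output head parameterises a diagonal Gaussian mixture
// over the next state, a Gaussian over the reward, and a Bernoulli terminal
// flag. Inputs per step: [state, one-hot action, SPE, RPE].

struct GMMPred {
  arma::vec w;          // K
  arma::mat mu, sigma;  // D x K
  double r_mu, r_sigma, p_term;
};

struct GRUMDN {
  int in = 0, H = 0, K = 0, D = 0, out_dim = 0;
  arma::mat Wz, Uz, Wr, Ur, Wh, Uh, Wo, bz, br, bh, bo;
  Adam oWz, oUz, oWr, oUr, oWh, oUh, oWo, obz, obr, obh, obo;
  static constexpr double LS_MIN = -4.0, LS_MAX = 3.0;

  void init(int state_dim, int n_actions, int H_, int K_, double lr) {
    D = state_dim; K = K_; H = H_;
    in = D + n_actions + 2;
    out_dim = K + 2 * K * D + 2 + 1;
    double sx = std::sqrt(1.0 / in), sh = std::sqrt(1.0 / H);
    Wz = rinit(H, in, sx); Uz = rinit(H, H, sh);
    Wr = rinit(H, in, sx); Ur = rinit(H, H, sh);
    Wh = rinit(H, in, sx); Uh = rinit(H, H, sh);
    Wo = rinit(out_dim, H, sh);
    bz.zeros(H, 1); br.zeros(H, 1); bh.zeros(H, 1); bo.zeros(out_dim, 1);
    Adam* opt[] = {&oWz, &oUz, &oWr, &oUr, &oWh, &oUh, &oWo, &obz, &obr, &obh, &obo};
    arma::mat* par[] = {&Wz, &Uz, &Wr, &Ur, &Wh, &Uh, &Wo, &bz, &br, &bh, &bo};
    for (int i = 0; i < 11; ++i) { opt[i]->init(*par[i]); opt[i]->lr = lr; }
  }

  struct Cache {
    arma::vec x, hprev, z, r, hb, h, y;
  };

  arma::vec cell(const arma::vec& x, const arma::vec& hprev, Cache* cc) const {
    arma::vec z = 1.0 / (1.0 + arma::exp(-(Wz * x + Uz * hprev + bz.col(0))));
    arma::vec r = 1.0 / (1.0 + arma::exp(-(Wr * x + Ur * hprev + br.col(0))));
    arma::vec hb = arma::tanh(Wh * x + Uh * (r % hprev) + bh.col(0));
    arma::vec h = (1.0 - z) % hprev + z % hb;
    if (cc) { cc->x = x; cc->hprev = hprev; cc->z = z; cc->r = r; cc->hb = hb; cc->h = h; }
    return h;
  }

  GMMPred head(const arma::vec& y, double temperature = 1.0) const {
    GMMPred p;
    arma::vec logits = y.subvec(0, K - 1) / temperature;
    logits -= logits.max();
    p.w = arma::exp(logits);
    p.w /= arma::accu(p.w);
    p.mu.set_size(D, K);
    p.sigma.set_size(D, K);
    for (int k = 0; k < K; ++k)
      for (int d = 0; d < D; ++d) {
        p.mu(d, k) = y(K + k * D + d);
        p.sigma(d, k) = std::exp(clampd(y(K + K * D + k * D + d), LS_MIN, LS_MAX));
      }
    p.r_mu = y(K + 2 * K * D);
    p.r_sigma = std::exp(clampd(y(K + 2 * K * D + 1), LS_MIN, LS_MAX));
    p.p_term = 1.0 / (1.0 + std::exp(-y(K + 2 * K * D + 2)));
    return p;
  }

  // negative log-likelihood of one (next-state, reward, terminal) target and
  // the gradient wrt the raw output vector y
  double loss_grad_y(const arma::vec& y, const arma::vec& xs, double rr,
                     double term, arma::vec& dy) const {
    const double L2PI = std::log(2.0 * M_PI);
    dy.zeros(out_dim);
    arma::vec logits = y.subvec(0, K - 1);
    double mx = logits.max();
    arma::vec pi = arma::exp(logits - mx);
    pi /= arma::accu(pi);
    arma::vec ll(K);
    for (int k = 0; k < K; ++k) {
      double s = std::log(pi(k) + 1e-300);
      for (int d = 0; d < D; ++d) {
        double ls = clampd(y(K + K * D + k * D + d), LS_MIN, LS_MAX);
        double sig = std::exp(ls);
        double z = (xs(d) - y(K + k * D + d)) / sig;
        s += -0.5 * L2PI - ls - 0.5 * z * z;
      }
      ll(k) = s;
    }
    double m = ll.max();
    double lse = m + std::log(arma::accu(arma::exp(ll - m)));
    double L_state = -lse;
    arma::vec g = arma::exp(ll - lse);  // responsibilities
    for (int k = 0; k < K; ++k) {
      dy(k) = pi(k) - g(k);
      for (int d = 0; d < D; ++d) {
        double lsr_ = y(K + K * D + k * D + d);
        double ls = clampd(lsr_, LS_MIN, LS_MAX);
        double sig = std::exp(ls);
        double z = (xs(d) - y(K + k * D + d)) / sig;
        dy(K + k * D + d) = -g(k) * z / sig;
        dy(K + K * D + k * D + d) =
            (lsr_ > LS_MIN && lsr_ < LS_MAX) ? g(k) * (1.0 - z * z) : 0.0;
      }
    }
    int ir = K + 2 * K * D;
    double lsr_raw = y(ir + 1);
    double lsr = clampd(lsr_raw, LS_MIN, LS_MAX);
    double sr = std::exp(lsr);
    double zr = (rr - y(ir)) / sr;
    double L_r = 0.5 * L2PI + lsr + 0.5 * zr * zr;
    dy(ir) = -zr / sr;
    dy(ir + 1) = (lsr_raw > LS_MIN && lsr_raw < LS_MAX) ? (1.0 - zr * zr) : 0.0;
    double ot = y(ir + 2);
    double L_t = (ot > 0 ? ot : 0.0) + std::log1p(std::exp(-std::fabs(ot))) - term * ot;
    dy(ir + 2) = 1.0 / (1.0 + std::exp(-ot)) - term;
    return L_state + L_r + L_t;
  }

  // forward/backward over one episode-ordered sequence; fills grads, returns
  // mean per-step loss
  double bptt(const arma::mat& X, const arma::mat& Sn, const arma::vec& rr,
              const arma::vec& term, std::vector<arma::mat>& grads) const {
    int T = X.n_cols;
    std::vector<Cache> cc(T);
    arma::vec h(H, arma::fill::zeros);
    double loss = 0.0;
    std::vector<arma::vec> dys(T);
    for (int t = 0; t < T; ++t) {
      h = cell(X.col(t), h, &cc[t]);
      cc[t].y = Wo * h + bo.col(0);
      arma::vec dy;
      loss += loss_grad_y(cc[t].y, Sn.col(t), rr(t), term(t), dy);
      dys[t] = dy / T;
    }
    arma::mat gWz(arma::size(Wz), arma::fill::zeros), gUz(arma::size(Uz), arma::fill::zeros),
        gWr(arma::size(Wr), arma::fill::zeros), gUr(arma::size(Ur), arma::fill::zeros),
        gWh(arma::size(Wh), arma::fill::zeros), gUh(arma::size(Uh), arma::fill::zeros),
        gWo(arma::size(Wo), arma::fill::zeros), gbz(H, 1, arma::fill::zeros),
        gbr(H, 1, arma::fill::zeros), gbh(H, 1, arma::fill::zeros),
        gbo(out_dim, 1, arma::fill::zeros);
    arma::vec dh(H, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      const Cache& c = cc[t];
      gWo += dys[t] * c.h.t();
      gbo += dys[t];
      dh += Wo.t() * dys[t];
      arma::vec dhb = dh % c.z;
      arma::vec dz = dh % (c.hb - c.hprev);
      arma::vec dhprev = dh % (1.0 - c.z);
      arma::vec dah = dhb % (1.0 - c.hb % c.hb);
      gWh += dah * c.x.t();
      gUh += dah * (c.r % c.hprev).t();
      gbh += dah;
      arma::vec tmp = Uh.t() * dah;
      dhprev += tmp % c.r;
      arma::vec dr = tmp % c.hprev;
      arma::vec daz = dz % c.z % (1.0 - c.z);
      arma::vec dar = dr % c.r % (1.0 - c.r);
      gWz += daz * c.x.t(); gUz += daz * c.hprev.t(); gbz += daz;
      gWr += dar * c.x.t(); gUr += dar * c.hprev.t(); gbr += dar;
      dhprev += Uz.t() * daz + Ur.t() * dar;
      dh = dhprev;
    }
    grads = {gWz, gUz, gWr, gUr, gWh, gUh, gWo, gbz, gbr, gbh, gbo};
    return loss / T;
  }

  double train_seq(const arma::mat& X, const arma::mat& Sn, const arma::vec& rr,
                   const arma::vec& term, double clip = 5.0) {
    std::vector<arma::mat> g;
    double loss = bptt(X, Sn, rr, term, g);
    double nrm = 0.0;
    for (auto& gi : g) nrm += arma::accu(gi % gi);
    nrm = std::sqrt(nrm);
    if (nrm > clip) for (auto& gi : g) gi *= clip / nrm;
    Adam* opt[] = {&oWz, &oUz, &oWr, &oUr, &oWh, &oUh, &oWo, &obz, &obr, &obh, &obo};
    arma::mat* par[] = {&Wz, &Uz, &Wr, &Ur, &Wh, &Uh, &Wo, &bz, &br, &bh, &bo};
    for (int i = 0; i < 11; ++i) opt[i]->step(*par[i], g[i]);
    return loss;
  }

  // sample a next state / reward / terminal from the prediction
  // (temperature scales the mixture-weight logits and the component scales)
  void sample(const GMMPred& p, double temperature, arma::vec& xs, double& rr,
              bool& term) const {
    int k = sample_categorical(p.w.memptr(), K);
    xs.set_size(D);
    double sc = std::sqrt(std::max(temperature, 1e-8));
    for (int d = 0; d < D; ++d)
      xs(d) = p.mu(d, k) + p.sigma(d, k) * sc * norm_rand();
    rr = p.r_mu;
    term = ru() < p.p_term;
  }
};

// SPE from a mixture prediction: z-scored deviation from the dominant
// component (default mode), or the literal mu/sigma ratio.
inline double spe_zscore(const arma::vec& obs, const GMMPred& p) {
  arma::uword k = p.w.index_max();
  double s = 0.0;
  for (arma::uword d = 0; d < obs.n_elem; ++d)
    s += std::fabs(obs(d) - p.mu(d, k)) / p.sigma(d, k);
  return s / obs.n_elem;
}
inline double spe_literal(const GMMPred& p) {
  arma::uword k = p.w.index_max();
  double s = 0.0;
  for (arma::uword d = 0; d < p.mu.n_rows; ++d)
    s += p.mu(d, k) / p.sigma(d, k);
  return s / p.mu.n_rows;
}

}  // namespace md

#endif
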