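// R-facing wrappers around the feed-forward Q network and the recurrent
// mixture-density world model (handles are external pointers).
#include <RcppArmadillo.h>
#include "net.h"
using namespace Rcpp;

// [[Rcpp::export]]
SEXP cpp_mlp_new(int n_in, int hidden, int n_out, double lr) {
  md::MLP* net = new md::MLP();
  net->init(n_in, hidden, n_out, lr);
  return XPtr<md::MLP>(net, true);
}

// [[Rcpp::export]]
NumericVector cpp_mlp_forward(SEXP ptr, NumericVector x) {
  XPtr<md::MLP> net(ptr);
  arma::vec xv(x.begin(), x.size());
  arma::vec q = net->forward(xv);
  return NumericVector(q.begin(), q.end());
}

// [[Rcpp::export]]
void cpp_mlp_td_batch(SEXP ptr, NumericMatrix X, IntegerVector actions,
                      NumericVector targets) {
  XPtr<md::MLP> net(ptr);
  arma::mat Xm(X.begin(), X.nrow(), X.ncol());
  std::vector<int> acts(actions.begin(), actions.end());
  arma::vec tgt(targets.begin(), targets.size());
  net->td_batch(Xm, acts, tgt);
}

// [[Rcpp::export]]
List cpp_mlp_get_params(SEXP ptr) {
  XPtr<md::MLP> net(ptr);
  return List::create(_["W1"] = net->W1, _["b1"] = net->b1,
                      _["W2"] = net->W2, _["b2"] = net->b2);
}

// [[Rcpp::export]]
void cpp_mlp_set_params(SEXP ptr, List par) {
  XPtr<md::MLP> net(ptr);
  net->W1 = as<arma::mat>(par["W1"]);
  net->b1 = as<arma::mat>(par["b1"]);
  net->W2 = as<arma::mat>(par["W2"]);
  net->b2 = as<arma::mat>(par["b2"]);
}

// [[Rcpp::export]]
SEXP cpp_mdn_new(int state_dim, int n_actions, int hidden, int K, double lr) {
  md::GRUMDN* net = new md::GRUMDN();
  net->init(state_dim, n_actions, hidden, K, lr);
  return XPtr<md::GRUMDN>(net, true);
}

// [[Rcpp::export]]
double cpp_mdn_train_seq(SEXP ptr, NumericMatrix X, NumericMatrix Sn,
                         NumericVector r, NumericVector term) {
  XPtr<md::GRUMDN> net(ptr);
  arma::mat Xm(X.begin(), X.nrow(), X.ncol());
  arma::mat Sm(Sn.begin(), Sn.nrow(), Sn.ncol());
  arma::vec rv(r.begin(), r.size()), tv(term.begin(), term.size());
  return net->train_seq(Xm, Sm, rv, tv);
}

// [[Rcpp::export]]
double cpp_mdn_loss(SEXP ptr, NumericMatrix X, NumericMatrix Sn,
                    NumericVector r, NumericVector term) {
  XPtr<md::GRUMDN> net(ptr);
  arma::mat Xm(X.begin(), X.nrow(), X.ncol());
  arma::mat Sm(Sn.begin(), Sn.nrow(), Sn.ncol());
  arma::vec rv(r.begin(), r.size()), tv(term.begin(), term.size());
  std::vector<arma::mat> g;
  return net->bptt(Xm, Sm, rv, tv, g);
}

// [[Rcpp::export]]
List cpp_mdn_grads(SEXP ptr, NumericMatrix X, NumericMatrix Sn,
                   NumericVector r, NumericVector term) {
  XPtr<md::GRUMDN> net(ptr);
  arma::mat Xm(X.begin(), X.nrow(), X.ncol());
  arma::mat Sm(Sn.begin(), Sn.nrow(), Sn.ncol());
  arma::vec rv(r.begin(), r.size()), tv(term.begin(), term.size());
  std::vector<arma::mat> g;
  double loss = net->bptt(Xm, Sm, rv, tv, g);
  const char* nm[] = {"Wz", "Uz", "Wr", "Ur", "Wh", "Uh", "Wo",
                      "bz", "br", "bh", "bo"};
  List out;
  for (int i = 0; i < 11; ++i) out[nm[i]] = g[i];
  out["loss"] = loss;
  return out;
}

// [[Rcpp::export]]
List cpp_mdn_get_params(SEXP ptr) {
  XPtr<md::GRUMDN> net(ptr);
  return List::create(_["Wz"] = net->Wz, _["Uz"] = net->Uz, _["Wr"] = net->Wr,
                      _["Ur"] = net->Ur, _["Wh"] = net->Wh, _["Uh"] = net->Uh,
                      _["Wo"] = net->Wo, _["bz"] = net->bz, _["br"] = net->br,
                      _["bh"] = net->bh, _["bo"] = net->bo);
}

// [[Rcpp::export]]
void cpp_mdn_set_params(SEXP ptr, List par) {
  XPtr<md::GRUMDN> net(ptr);
  net->Wz = as<arma::mat>(par["Wz"]); net->Uz = as<arma::mat>(par["Uz"]);
  net->Wr = as<arma::mat>(par["Wr"]); net->Ur = as<arma::mat>(par["Ur"]);
  net->Wh = as<arma::mat>(par["Wh"]); net->Uh = as<arma::mat>(par["Uh"]);
  net->Wo = as<arma::mat>(par["Wo"]); net->bz = as<arma::mat>(par["bz"]);
  net->br = as<arma::mat>(par["br"]); net->bh = as<arma::mat>(par["bh"]);
  net->bo = as<arma::mat>(par["bo"]);
}

static List pred_to_list(const md::GMMPred& p) {
  return List::create(_["weights"] = NumericVector(p.w.begin(), p.w.end()),
                      _["means"] = wrap(p.mu), _["scales"] = wrap(p.sigma),
                      _["reward_mean"] = p.r_mu, _["reward_scale"] = p.r_sigma,
                      _["p_terminal"] = p.p_term);
}

// per-step mixture predictions along an input sequence (hidden state reset)
// [[Rcpp::export]]
List cpp_mdn_predict(SEXP ptr, NumericMatrix X, double temperature) {
  XPtr<md::GRUMDN> net(ptr);
  arma::mat Xm(X.begin(), X.nrow(), X.ncol());
  int T = Xm.n_cols;
  arma::vec h(net->H, arma::fill::zeros);
  List out(T);
  for (int t = 0; t < T; ++t) {
    h = net->cell(Xm.col(t), h, nullptr);
    arma::vec y = net->Wo * h + net->bo.col(0);
    out[t] = pred_to_list(net->head(y, temperature));
  }
  return out;
}

// Mental-simulation rollout from a network world model: epsilon-greedy on the
// supplied Q network, mixture sampling with temperature, stops at a predicted
// terminal or the horizon.
// [[Rcpp::export]]
List cpp_mdn_rollout(SEXP mdn_ptr, SEXP q_ptr, NumericVector s0, int n_steps,
                     int horizon, double epsilon, double temperature) {
  XPtr<md::GRUMDN> net(mdn_ptr);
  XPtr<md::MLP> qnet(q_ptr);
  int D = net->D, nA = net->in - net->D - 2;
  arma::vec s(s0.begin(), s0.size());
  arma::vec h(net->H, arma::fill::zeros);
  int cap = std::min(n_steps, horizon);
  arma::mat S(D, cap), Snext(D, cap);
  IntegerVector acts(cap);
  NumericVector rews(cap);
  LogicalVector terms(cap), sims(cap);
  int n = 0;
  for (int i = 0; i < cap; ++i) {
    arma::vec q = qnet->forward(s);
    int a = md::eps_greedy(q.memptr(), nA, epsilon);
    arma::vec x(net->in, arma::fill::zeros);
    x.subvec(0, D - 1) = s;
    x(D + a) = 1.0;
    h = net->cell(x, h, nullptr);
    arma::vec y = net->Wo * h + net->bo.col(0);
    md::GMMPred p = net->head(y, temperature);
    arma::vec sn;
    double r;
    bool term;
    net->sample(p, temperature, sn, r, term);
    S.col(n) = s;
    Snext.col(n) = sn;
    acts[n] = a;
    rews[n] = r;
    terms[n] = term;
    sims[n] = true;
    ++n;
    if (term) break;
    s = sn;
  }
  return List::create(_["s"] = wrap(S.cols(0, std::max(n - 1, 0))),
                      _["a"] = acts[Range(0, std::max(n - 1, 0))],
                      _["r"] = rews[Range(0, std::max(n - 1, 0))],
                      _["s_next"] = wrap(Snext.cols(0, std::max(n - 1, 0))),
                      _["terminal"] = terms[Range(0, std::max(n - 1, 0))],
                      _["simulated"] = sims[Range(0, std::max(n - 1, 0))],
                      _["n"] = n);
}
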