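# World model: tabular transition learning, mixture network, rollouts.

test_that("the two-branch transition update matches hand arithmetic", {
  m <- tabular_model(2, 1, gamma_t = 0.2)
  m <- tabular_update(m, 1, 1, 1)          # row starts at (0.5, 0.5)
  expect_equal(m$t_est[1, ], c(0.6, 0.4))
  # zero step size leaves the row unchanged
  m0 <- tabular_model(2, 1, gamma_t = 0)
  m0 <- tabular_update(m0, 1, 1, 1)
  expect_equal(m0$t_est[1, ], c(0.5, 0.5))
  # full step overwrites with a one-hot row
  m1 <- tabular_model(4, 2, gamma_t = 1)
  m1 <- tabular_update(m1, 2, 1, 3)
  expect_equal(m1$t_est[3, ], c(0, 0, 1, 0))
  expect_error(tabular_update(m1, 9, 1, 1), "unknown state")
  expect_error(tabular_update(m1, 1, 5, 1), "unknown action")
})

test_that("transition rows always sum to one under random updates", {
  set.seed(5)
  m <- tabular_model(5, 3, gamma_t = 0.3)
  for (i in 1:500) {
    m <- tabular_update(m, sample(5, 1), sample(3, 1), sample(5, 1), runif(1))
    expect_equal(rowSums(m$t_est), rep(1, 15), tolerance = 1e-12)
  }
})

test_that("count-mode estimates recover a 0.9/0.1 branch from 1000 draws", {
  set.seed(9)
  m <- tabular_model(3, 1, gamma_t = NA)   # 1/n steps: empirical frequencies
  sn <- ifelse(runif(1000) < 0.9, 2L, 3L)
  for (s2 in sn) m <- tabular_update(m, 1, 1, s2, 1)
  expect_lt(abs(m$t_est[1, 2] - 0.9), 0.03)
  expect_lt(abs(m$t_est[1, 3] - 0.1), 0.03)
  expect_false(tabular_predict(m, 1, 1)$cold)
  # reward estimate is the running mean in count mode
  expect_equal(tabular_predict(m, 1, 1)$reward, 1)
})

test_that("cold state-action pairs predict uniform with a cold flag", {
  m <- tabular_model(4, 2)
  p <- tabular_predict(m, 2, 2)
  expect_true(p$cold)
  expect_equal(p$probs, rep(0.25, 4))
  expect_equal(p$reward, 0)
})

test_that("tabular model recovers the task's transition matrix (L-inf 0.05)", {
  set.seed(31)
  sched <- flat_mdt_schedule(2000, p_intended = 0.9)
  res <- run_mdt("forward", sched, list(count_mode = TRUE, epsilon = 0.3),
                 details = TRUE)
  truth <- mdt_mdp(0.9)
  err <- 0
  for (s in 1:3) for (a in 1:2) {
    sa <- (s - 1) * 2 + a
    err <- max(err, max(abs(res$t_est[sa, ] - truth$trans[s, a, ])))
  }
  expect_lte(err, 0.05)
})

test_that("rollouts reproduce a deterministic chain and stop at terminals", {
  # chain 1 -> 2 -> 3 (terminal)
  m <- tabular_model(3, 1, gamma_t = 1)
  m <- tabular_update(m, 1, 1, 2)
  m <- tabular_update(m, 2, 1, 3, reward = 1)
  q <- matrix(0, 3, 1)
  out <- rollout(m, q, s0 = 1, rollout_config(n_steps = 5),
                 terminal_states = c(FALSE, FALSE, TRUE), epsilon = 0)
  expect_equal(out$s, c(1, 2))
  expect_equal(out$s_next, c(2, 3))
  expect_equal(out$terminal, c(FALSE, TRUE))
  expect_true(all(out$simulated))
  # a loop with no terminal fills the full budget
  m2 <- tabular_model(3, 1, gamma_t = 1)
  m2 <- tabular_update(m2, 1, 1, 2)
  m2 <- tabular_update(m2, 2, 1, 3)
  m2 <- tabular_update(m2, 3, 1, 1)
  out2 <- rollout(m2, q, 1, rollout_config(n_steps = 5, horizon = 10),
                  terminal_states = rep(FALSE, 3), epsilon = 0)
  expect_equal(nrow(out2), 5)
})

test_that("a cold model yields an empty rollout, never fabricated experience", {
  m <- tabular_model(3, 2)
  out <- rollout(m, matrix(0, 3, 2), 1, rollout_config(),
                 terminal_states = rep(FALSE, 3))
  expect_equal(nrow(out), 0)
  expect_error(rollout_config(n_steps = 0), "positive")
})

test_that("simulated successor frequencies match the learned distribution", {
  set.seed(77)
  m <- tabular_model(3, 1, gamma_t = NA)
  sn <- ifelse(runif(4000) < 0.7, 2L, 3L)
  for (s2 in sn) m <- tabular_update(m, 1, 1, s2)
  target <- m$t_est[1, 2]
  q <- matrix(0, 3, 1)
  term <- c(FALSE, TRUE, TRUE)
  hits <- vapply(1:10000, function(i)
    rollout(m, q, 1, rollout_config(n_steps = 1), term)$s_next[1] == 2,
    logical(1))
  expect_lt(abs(mean(hits) - target), 0.02)
})

test_that("mixture NLL has the exact closed-form anchors", {
  # K = 1, target at the mean, sigma = 1/sqrt(2*pi): density 1 -> NLL 0
  sig <- 1 / sqrt(2 * pi)
  p <- gmm_prediction(1, matrix(c(0.3, -0.2)), matrix(c(sig, sig)))
  expect_equal(mdn_nll(p, c(0.3, -0.2)), 0, tolerance = 1e-12)
  # two equal components, target at component 1's mean:
  # loss <= single-component NLL + log 2
  p2 <- gmm_prediction(c(0.5, 0.5), cbind(c(0, 0), c(5, 5)),
                       cbind(c(1, 1), c(1, 1)))
  p1 <- gmm_prediction(1, cbind(c(0, 0)), cbind(c(1, 1)))
  expect_lte(mdn_nll(p2, c(0, 0)), mdn_nll(p1, c(0, 0)) + log(2) + 1e-12)
  # shrinking sigma away from the target blows the loss up monotonically
  losses <- vapply(c(1, 0.3, 0.1, 0.03), function(s)
    mdn_nll(gmm_prediction(1, matrix(1), matrix(s)), 2), numeric(1))
  expect_true(all(diff(losses) > 0))
  expect_error(gmm_prediction(c(0.6, 0.6), cbind(0, 1), cbind(1, 1)),
               "sum to 1")
})

test_that("analytic MDN-RNN gradients agree with finite differences", {
  set.seed(123)
  wm <- mdn_world_model(state_dim = 2, n_actions = 2, hidden = 5,
                        n_components = 2, lr = 1e-3)
  Tn <- 3
  X <- matrix(rnorm(6 * Tn), 6, Tn)      # 2 + 2 + 2 input dims
  Sn <- matrix(rnorm(2 * Tn), 2, Tn)
  r <- rnorm(Tn); term <- c(0, 0, 1)
  g <- cpp_mdn_grads(wm$ptr, X, Sn, r, term)
  par <- cpp_mdn_get_params(wm$ptr)
  eps <- 1e-5
  for (nm in c("Wz", "Uh", "Wo", "bh")) {
    idx <- cbind(c(1, 2), c(1, 2))
    for (k in 1:2) {
      i <- idx[k, 1]; j <- min(idx[k, 2], ncol(par[[nm]]))
      pp <- par; pp[[nm]][i, j] <- pp[[nm]][i, j] + eps
      cpp_mdn_set_params(wm$ptr, pp)
      up <- cpp_mdn_loss(wm$ptr, X, Sn, r, term)
      pp[[nm]][i, j] <- pp[[nm]][i, j] - 2 * eps
      cpp_mdn_set_params(wm$ptr, pp)
      dn <- cpp_mdn_loss(wm$ptr, X, Sn, r, term)
      cpp_mdn_set_params(wm$ptr, par)
      numeric_g <- (up - dn) / (2 * eps)   # gradient of the mean loss
      expect_lt(abs(g[[nm]][i, j] - numeric_g),
                1e-4 * max(1, abs(numeric_g)))
    }
  }
})

test_that("training improves held-out likelihood on a deterministic loop", {
  set.seed(21)
  onehot <- function(i, n = 4) { v <- numeric(n); v[i] <- 1; v }
  make_ep <- function() {
    states <- t(sapply(1:4, onehot))
    nxt <- t(sapply(c(2, 3, 4, 1), onehot))
    list(states = states, actions = rep(1L, 4), rewards = rep(0, 4),
         next_states = nxt, terminal = c(0, 0, 0, 1))
  }
  wm <- mdn_world_model(4, 2, hidden = 16, n_components = 2, lr = 3e-3)
  held <- make_ep()
  X <- metadyna:::.mdn_inputs(wm, held)
  before <- cpp_mdn_loss(wm$ptr, X, t(held$next_states), held$rewards,
                         held$terminal)
  wm <- train_world_model(wm, replicate(40, make_ep(), simplify = FALSE),
                          epochs = 4)
  after <- cpp_mdn_loss(wm$ptr, X, t(held$next_states), held$rewards,
                        held$terminal)
  expect_lt(after, before)
})

test_that("the recurrent model rejects non-episode (shuffled/flat) input", {
  wm <- mdn_world_model(4, 2, hidden = 8)
  flat <- data.frame(s = 1:4, a = 1, r = 0)
  expect_error(train_world_model(wm, flat, 1), "list of episodes")
  expect_error(train_world_model(wm, list(), 1), "non-empty")
  expect_error(train_world_model(wm, list(list(states = diag(4))), 1),
               "needs")
})

test_that("every forward pass satisfies the mixture-prediction invariants", {
  set.seed(99)
  wm <- mdn_world_model(3, 2, hidden = 8, n_components = 4)
  for (i in 1:20) {
    Tn <- sample(2:6, 1)
    ep <- list(states = matrix(rnorm(3 * Tn), Tn, 3),
               actions = sample(2, Tn, replace = TRUE))
    preds <- predict(wm, ep)
    for (p in preds) {
      expect_s3_class(p, "gmm_prediction")
      expect_equal(sum(p$weights), 1, tolerance = 1e-6)
      expect_true(all(p$weights >= 0))
      expect_true(all(p$scales > 0))
      expect_gte(p$p_terminal, 0)
      expect_lte(p$p_terminal, 1)
    }
  }
})
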