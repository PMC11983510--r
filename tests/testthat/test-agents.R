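# Agents: granular updates, degenerate equivalences, buffer hygiene,
# convergence on stationary tasks.

test_that("Q-learning updates match hand arithmetic and converge on a chain", {
  q <- matrix(0, 2, 1)
  tr <- list(s = 1, a = 1, r = 1, s_next = 2, terminal = TRUE)
  expect_equal(qlearn_update(q, tr, lr = 1)[1, 1], 1)       # full-step terminal
  expect_equal(qlearn_update(q, tr, lr = 0), q)             # zero step
  # 2-state chain: s1 -> s2 (r = 0), s2 -> terminal (r = 1); gamma = 0.9
  q <- matrix(0, 3, 1)
  t1 <- list(s = 1, a = 1, r = 0, s_next = 2, terminal = FALSE)
  t2 <- list(s = 2, a = 1, r = 1, s_next = 3, terminal = TRUE)
  for (i in 1:300) { q <- qlearn_update(q, t1, 0.2, 0.9); q <- qlearn_update(q, t2, 0.2, 0.9) }
  expect_equal(q[2, 1], 1, tolerance = 1e-8)
  expect_equal(q[1, 1], 0.9, tolerance = 1e-8)
})

test_that("SARSA: terminal case equals Q-learning; greedy next-action too", {
  q <- matrix(c(0.3, 0.1, 0.8, 0.2), 2, 2)
  tr_term <- list(s = 1, a = 1, r = 1, s_next = 2, terminal = TRUE)
  expect_equal(sarsa_update(q, tr_term, a_next = 1, lr = 0.5),
               qlearn_update(q, tr_term, lr = 0.5))
  tr <- list(s = 1, a = 2, r = 0.2, s_next = 2, terminal = FALSE)
  greedy <- which.max(q[2, ])
  expect_equal(sarsa_update(q, tr, a_next = greedy, lr = 0.3),
               qlearn_update(q, tr, lr = 0.3))
})

test_that("SARSA converges to on-policy values of a fixed epsilon-soft policy", {
  # 3-state chain, 1 action per state effectively; policy randomizes between
  # 'advance' and 'stay' in state 1 with probs (0.8, 0.2)
  # V satisfies: V1 = 0.8*(0 + g*V2) + 0.2*(0 + g*V1); V2 = 1 (terminal next)
  g <- 0.9
  v2 <- 1
  v1 <- 0.8 * g * v2 / (1 - 0.2 * g)
  q <- matrix(0, 3, 2)    # state 1: a1 advance, a2 stay
  set.seed(44)
  for (i in 1:4000) {
    a <- if (runif(1) < 0.8) 1 else 2
    a_next <- if (runif(1) < 0.8) 1 else 2
    if (a == 1) {
      q <- sarsa_update(q, list(s = 1, a = 1, r = 0, s_next = 2,
                                terminal = FALSE), a_next = 1, lr = 0.05, g)
      q <- sarsa_update(q, list(s = 2, a = 1, r = 1, s_next = 3,
                                terminal = TRUE), a_next = 1, lr = 0.05, g)
    } else {
      q <- sarsa_update(q, list(s = 1, a = 2, r = 0, s_next = 1,
                                terminal = FALSE), a_next = a_next,
                        lr = 0.05, g)
    }
  }
  v1_hat <- 0.8 * q[1, 1] + 0.2 * q[1, 2]
  expect_equal(v1_hat, v1, tolerance = 0.05)
})

test_that("FORWARD reaches dynamic-programming values and re-plans on reward moves", {
  # deterministic 4-state MDP: 1 -(a1)-> 2 -(a1)-> 4(r=1); 1 -(a2)-> 3 -(a1)-> 4(r=0)
  model <- tabular_model(4, 2, gamma_t = 1, r_step = 1)
  q_mb <- matrix(0, 4, 2)
  term <- c(FALSE, FALSE, FALSE, TRUE)
  trs <- list(list(s = 1, a = 1, r = 0, s_next = 2, terminal = FALSE),
              list(s = 1, a = 2, r = 0, s_next = 3, terminal = FALSE),
              list(s = 2, a = 1, r = 1, s_next = 4, terminal = TRUE),
              list(s = 2, a = 2, r = 1, s_next = 4, terminal = TRUE),
              list(s = 3, a = 1, r = 0, s_next = 4, terminal = TRUE),
              list(s = 3, a = 2, r = 0, s_next = 4, terminal = TRUE))
  for (rep in 1:5) for (tr in trs) {
    out <- forward_update(model, q_mb, tr, term)
    model <- out$model; q_mb <- out$q_mb
  }
  trans <- array(0, c(4, 2, 4)); rew <- matrix(0, 4, 2)
  trans[1, 1, 2] <- 1; trans[1, 2, 3] <- 1
  trans[2, 1, 4] <- trans[2, 2, 4] <- 1; rew[2, ] <- 1
  trans[3, 1, 4] <- trans[3, 2, 4] <- 1
  expect_equal(q_mb, vi_oracle(trans, rew, term), tolerance = 1e-6)
  expect_equal(which.max(q_mb[1, ]), 1)
  # relocate the reward to the other branch; transitions unchanged
  trs2 <- trs
  trs2[[3]]$r <- trs2[[4]]$r <- 0
  trs2[[5]]$r <- trs2[[6]]$r <- 1
  for (rep in 1:5) for (tr in trs2) {
    out <- forward_update(model, q_mb, tr, term)
    model <- out$model; q_mb <- out$q_mb
  }
  expect_equal(which.max(q_mb[1, ]), 2)   # argmax follows the new reward
  # an empty model leaves values at their prior
  empty <- forward_update(tabular_model(4, 2), matrix(0, 4, 2),
                          trs[[1]], term)
  expect_true(all(abs(empty$q_mb[3, ]) < 1e-9))
})

test_that("epsilon-greedy selection: greedy, uniform, and tie-breaking", {
  expect_true(all(replicate(50, select_action(c(0.1, 0.9, 0.2), 0)) == 2))
  set.seed(55)
  acts <- replicate(6000, select_action(c(1, 1, 1), 1))
  expect_true(all(abs(table(acts) / 6000 - 1 / 3) < 0.02))
  set.seed(56)
  ties <- replicate(10000, select_action(c(0.5, 0.5, 0.1), 0))
  expect_true(all(ties %in% 1:2))
  expect_lt(abs(mean(ties == 1) - 0.5), 0.02)
})

test_that("P_MB forced to 0 reproduces Q-learning step for step", {
  set.seed(61)
  sched <- mdt_schedule(300)
  cfg0 <- list(p_mb0 = 0, A_alpha = 1e-12, A_beta = 1e-12, n_planning = 0L,
               mf_per_step = TRUE, record_actions = TRUE)
  set.seed(61)
  meta <- run_mdt("meta-dyna", sched, cfg0, details = TRUE)
  set.seed(61)
  ql <- run_mdt("q-learning", sched, list(record_actions = TRUE),
                details = TRUE)
  expect_identical(meta$actions, ql$actions)
  expect_equal(meta$log$reward, ql$log$reward)
  expect_equal(meta$q_mf, ql$q_mf)
})

test_that("P_MB forced to 1 with a learned model recovers the DP policy", {
  set.seed(62)
  sched <- flat_mdt_schedule(500, p_intended = 1)
  cfg1 <- list(p_mb0 = 1, A_alpha = 1, B_alpha = 0, A_beta = 1e-12,
               lr_mb = 0.3)
  res <- run_mdt("meta-dyna", sched, cfg1, details = TRUE)
  truth <- mdt_mdp(1)
  q_star <- vi_oracle(truth$trans, truth$rew, truth$terminal)
  for (s in 1:3)
    expect_equal(which.max(res$q_mb[s, ]), which.max(q_star[s, ]))
})

test_that("replay buffers stay hygienic: no simulated data reaches Q_MF", {
  set.seed(63)
  res <- run_mdt("meta-dyna", mdt_schedule(400), details = TRUE)
  expect_equal(res$diag$rbmf_simulated, 0)
  expect_equal(res$diag$qmb_real_updates, 0)
  expect_gt(res$diag$simulated_transitions, 0)
  expect_equal(res$diag$rbmf_size, sum(res$log$steps))
})

test_that("more planning accelerates Dyna-Q on a deterministic gridworld", {
  sched <- flat_grid_schedule(120, p_intended = 1, r_left = 0, r_right = 1)
  mean_opt <- function(n, seed) {
    set.seed(seed)
    mean(run_loca("dyna-q", sched, list(n_planning = n))$optimal)
  }
  gains <- vapply(1:6, function(seed) mean_opt(20, seed) - mean_opt(1, seed),
                  numeric(1))
  expect_gt(mean(gains), 0)
})

test_that("planning with an exact model leaves converged values unchanged", {
  # deterministic chain learned exactly; Q at the Bellman fixed point
  m <- tabular_model(3, 1, gamma_t = 1, r_step = 1)
  m <- tabular_update(m, 1, 1, 2, 0)
  m <- tabular_update(m, 2, 1, 3, 1)
  q <- matrix(c(0.9, 1, 0), 3, 1)
  out <- rollout(m, q, 1, rollout_config(n_steps = 2),
                 terminal_states = c(FALSE, FALSE, TRUE), epsilon = 0)
  for (i in seq_len(nrow(out)))
    q <- qlearn_update(q, as.list(out[i, ]), lr = 0.5, gamma = 0.9)
  expect_equal(q, matrix(c(0.9, 1, 0), 3, 1), tolerance = 1e-9)
})

test_that("all agents converge on the stationary deterministic task", {
  sched <- flat_mdt_schedule(600, p_intended = 1)
  for (ag in c("q-learning", "sarsa", "dyna-q", "forward", "meta-dyna")) {
    set.seed(70)
    log <- run_mdt(ag, sched, list(eps_decay = 0.99))
    expect_gt(mean(log$optimal[501:600]), 0.9)
  }
})

test_that("every agent's trajectory is reproducible from (config, seed)", {
  sched <- { set.seed(80); mdt_schedule(150) }
  for (ag in c("q-learning", "dyna-q", "meta-dyna", "forward+sarsa")) {
    a <- run_mdt(ag, sched, seed = 81)
    b <- run_mdt(ag, sched, seed = 81)
    expect_identical(a, b)
  }
  for (ag in c("dqn", "meta-dyna")) {
    a <- run_mdt(ag, sched, seed = 82, backend = "network")
    b <- run_mdt(ag, sched, seed = 82, backend = "network")
    expect_identical(a, b)
  }
  a <- run_pong("meta-dyna", n_episodes = 40, seed = 83)
  b <- run_pong("meta-dyna", n_episodes = 40, seed = 83)
  expect_identical(a, b)
})

test_that("network agents learn the stationary task above chance", {
  sched <- flat_mdt_schedule(800, p_intended = 1)
  for (ag in c("dqn", "dyna-q", "meta-dyna")) {
    set.seed(90)
    log <- run_mdt(ag, sched, list(eps_decay = 0.995), backend = "network")
    # random play earns the mean token value 0.4375; optimal earns 1
    expect_gt(mean(log$reward[601:800]), 0.8)
  }
})

test_that("a degenerate DQN (no replay, batch 1, sync 1) still learns online", {
  sched <- flat_mdt_schedule(800, p_intended = 1)
  set.seed(91)
  log <- run_mdt("dqn", sched,
                 list(replay_capacity = 1, batch_size = 1, train_every = 1,
                      target_sync = 1, eps_decay = 0.995),
                 backend = "network")
  expect_gt(mean(log$reward[601:800]), mean(log$reward[1:200]))
  expect_gt(mean(log$reward[601:800]), 0.6)
})
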