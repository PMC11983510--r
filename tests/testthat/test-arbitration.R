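# Arbitration module: prediction errors, reliability trackers, P_MB dynamics.

test_that("the TD reward prediction error matches hand arithmetic", {
  expect_equal(compute_rpe(1, 0, 0, 0.9), 1.0)
  expect_equal(compute_rpe(0.5, 0.5, 0.2, 0.9), 0.75)
  # self-consistent values give (near) zero error as gamma -> 1
  expect_lt(abs(compute_rpe(0, 0.7, 0.7, 0.999)), 1e-3)
  expect_error(compute_rpe(0, 0, 0, 1), "gamma")
})

test_that("discrete SPE is one minus the transition probability", {
  expect_equal(compute_spe_discrete(1), 0)
  expect_equal(compute_spe_discrete(0), 1)
  expect_equal(compute_spe_discrete(0.9), 0.1)
  expect_error(compute_spe_discrete(1.2), "\\[0, 1\\]")
  expect_error(compute_spe_discrete(-0.1), "\\[0, 1\\]")
})

test_that("mixture SPE: zscore deviation and literal mu/sigma modes", {
  p <- gmm_prediction(weights = c(0.7, 0.3),
                      means = cbind(c(1, 2), c(0, 0)),
                      scales = cbind(c(2, 2), c(1, 1)))
  expect_equal(compute_spe_gmm(c(1, 2), p), 0)                  # perfect
  expect_equal(compute_spe_gmm(c(3, 4), p), 1)                  # one sigma off
  expect_equal(compute_spe_gmm(NULL, p, mode = "mu_over_sigma"),
               mean(c(1, 2) / 2))
  p1 <- gmm_prediction(1, matrix(1), matrix(2))
  expect_equal(compute_spe_gmm(NULL, p1, mode = "mu_over_sigma"), 0.5)
  expect_error(compute_spe_gmm(c(1, 2, 3), p), "dimension mismatch")
  expect_error(gmm_prediction(1, matrix(1), matrix(-1)), "positive")
})

test_that("the zero band classifies prediction errors symmetrically", {
  expect_equal(classify_spe(0, 0.1), "zero")
  expect_equal(classify_spe(0.5, 0.1), "positive")
  expect_equal(classify_spe(-0.5, 0.1), "negative")
  # boundary values belong to the zero band
  expect_equal(classify_spe(0.1, 0.1), "zero")
  expect_equal(classify_spe(-0.1, 0.1), "zero")
})

test_that("Pearce-Hall associability maps absolute RPE to reliability", {
  tr <- pearce_hall_tracker(eta = 0.2, rpe_max = 1)
  tr <- update_rel_mf(tr, 0.5)
  expect_equal(tr$assoc, 0.1)
  expect_equal(tr$rel_mf, 0.9)
  # zero error forever -> fully reliable
  tr0 <- pearce_hall_tracker(eta = 0.2, rpe_max = 1, assoc0 = 1)
  for (i in 1:100) tr0 <- update_rel_mf(tr0, 0)
  expect_gt(tr0$rel_mf, 0.999)
  # saturated error forever -> unreliable
  tr1 <- pearce_hall_tracker(eta = 0.2, rpe_max = 1)
  for (i in 1:100) tr1 <- update_rel_mf(tr1, 1)
  expect_lt(tr1$rel_mf, 1e-6)
})

test_that("with constant |RPE| = c the reliability converges geometrically", {
  c0 <- 0.4; eta <- 0.3
  tr <- pearce_hall_tracker(eta = eta, rpe_max = 1)
  gap <- numeric(30)
  for (i in 1:30) {
    tr <- update_rel_mf(tr, c0)
    gap[i] <- abs(tr$rel_mf - (1 - c0))
  }
  ratios <- gap[-1] / gap[-30]
  expect_true(all(abs(ratios - (1 - eta)) < 1e-8))
})

test_that("Dirichlet posterior mean of the zero category is the reliability", {
  tr <- dirichlet_tracker(prior = 1)
  expect_equal(tr$rel_mb, 1 / 3)
  for (i in 1:7) tr <- update_rel_mb(tr, "zero")
  expect_equal(tr$rel_mb, 8 / 10)
  # all non-zero events drive reliability toward 0
  tr2 <- dirichlet_tracker(prior = 1)
  for (i in 1:500) tr2 <- update_rel_mb(tr2, "positive")
  expect_lt(tr2$rel_mb, 0.01)
  # variance-penalised variant is below the posterior mean
  tr3 <- update_rel_mb(dirichlet_tracker(), "zero", variance_penalty = TRUE)
  expect_lt(tr3$rel_mb, update_rel_mb(dirichlet_tracker(), "zero")$rel_mb)
})

test_that("rel_mb converges to the empirical zero-SPE frequency", {
  set.seed(42)
  p_zero <- 0.7
  tr <- dirichlet_tracker(prior = 1, decay = 1)
  cats <- ifelse(runif(1e4) < p_zero, "zero", "positive")
  for (ct in cats) tr <- update_rel_mb(tr, ct)
  expect_lt(abs(tr$rel_mb - p_zero), 0.02)
})

test_that("P_MB dynamics match hand arithmetic on the printed update", {
  # alpha = beta = 1/2 at B = 0, A = 1: p = 0.5 is a fixed point
  st <- arbitration_state(p_mb = 0.5)
  pa <- arbitration_params(A_alpha = 1, B_alpha = 0, A_beta = 1, B_beta = 0)
  expect_equal(update_p_mb(st, pa)$p_mb, 0.5)
  # alpha = 0.5, beta ~ 0: p' = p + 0.5 * (1 - p)
  st2 <- arbitration_state(p_mb = 0.2)
  pa2 <- arbitration_params(A_alpha = 1, B_alpha = 0, A_beta = 1e-12,
                            B_beta = 0)
  expect_equal(update_p_mb(st2, pa2)$p_mb, 0.6, tolerance = 1e-9)
  # vanishing rates freeze P_MB
  pa3 <- arbitration_params(A_alpha = 1e-12, A_beta = 1e-12)
  expect_equal(update_p_mb(st2, pa3)$p_mb, 0.2, tolerance = 1e-9)
})

test_that("P_MB stays in [0, 1] over long random update sequences", {
  set.seed(7)
  p <- 0.5
  ok <- TRUE
  for (i in 1:1e5) {
    p <- cpp_pmb_update(p, runif(1), runif(1), runif(1), runif(1, -5, 5),
                        runif(1), runif(1, -5, 5))
    if (p < 0 || p > 1) { ok <- FALSE; break }
  }
  expect_true(ok)
})

test_that("raising Rel_MF weakly decreases the stationary P_MB", {
  stationary <- function(rel_mf, rel_mb = 0.5) {
    st <- arbitration_state(rel_mf = rel_mf, rel_mb = rel_mb, p_mb = 0.5)
    pa <- arbitration_params(A_alpha = 0.3, B_alpha = 3, A_beta = 0.3,
                             B_beta = 3)
    for (i in 1:3000) st <- update_p_mb(st, pa)
    st$p_mb
  }
  ps <- vapply(seq(0, 1, by = 0.1), stationary, numeric(1))
  expect_true(all(diff(ps) <= 1e-8))
})

test_that("integrated Q is the convex combination, bounded by its inputs", {
  expect_equal(integrate_q(1, 0, 0.7), 0.7)
  expect_equal(integrate_q(5, -3, 1), 5)
  expect_equal(integrate_q(5, -3, 0), -3)
  set.seed(11)
  for (i in 1:50) {
    qmb <- matrix(rnorm(12), 4, 3)
    qmf <- matrix(rnorm(12), 4, 3)
    p <- runif(1)
    q <- integrate_q(qmb, qmf, p)
    expect_true(all(q >= pmin(qmb, qmf) - 1e-12 & q <= pmax(qmb, qmf) + 1e-12))
  }
  expect_error(integrate_q(1, 0, 1.2), "probability")
})
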