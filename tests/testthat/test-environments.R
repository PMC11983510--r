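# The three benchmark environments and their condition schedules.

test_that("MDT stage structure: no stage-1 reward, terminal token outcomes", {
  set.seed(1)
  env <- mdt_env(p_intended = 0.9)
  for (i in 1:50) {
    env$reset()
    o1 <- env$step(sample(2, 1))
    expect_equal(o1$reward, 0)
    expect_false(o1$terminal)
    expect_true(o1$next_state %in% 2:3)
    o2 <- env$step(sample(2, 1))
    expect_true(o2$terminal)
    expect_true(o2$next_state %in% 4:7)
    expect_true(o2$reward %in% c(0, 0.25, 0.5, 1))
  }
  expect_error(env$step(1), "terminated")
})

test_that("specific goals pay 1 for the required token and 0 otherwise", {
  env <- mdt_env(p_intended = 1, goal = goal_condition("specific", target = 1))
  env$reset(); env$step(1)
  expect_equal(env$step(1)$reward, 1)        # deterministic path to token 1
  env$reset(); env$step(1)
  expect_equal(env$step(2)$reward, 0)        # token 2 instead
  set.seed(2)
  env2 <- mdt_env(p_intended = 0.9,
                  goal = goal_condition("specific", target = 3))
  r <- replicate(200, { env2$reset(); env2$step(1); env2$step(2)$reward })
  expect_true(all(r %in% c(0, 1)))
})

test_that("intended-branch frequency matches p_intended (binomial CI)", {
  set.seed(3)
  n <- 1e5
  # raw stepper is 0-based: intermediate state 1, action 0 -> token state 3
  hits <- vapply(seq_len(n), function(i)
    cpp_mdt_step(1L, 0L, 0.9, 0L, -1L, c(0, 0.25, 0.5, 1))$next_state == 3L,
    logical(1))
  expect_lt(abs(mean(hits) - 0.9), 0.01)
  set.seed(4)
  hits5 <- vapply(seq_len(2e4), function(i)
    cpp_mdt_step(0L, 0L, 0.5, 0L, -1L, c(0, 0.25, 0.5, 1))$next_state == 1L,
    logical(1))
  expect_lt(abs(mean(hits5) - 0.5), 0.01)
})

test_that("the MDT schedule has the protocolized block/segment structure", {
  expect_equal(mdt_uncertainty(0), 0.9)
  expect_equal(mdt_uncertainty(499), 0.9)
  expect_equal(mdt_uncertainty(500), 0.5)
  expect_equal(mdt_uncertainty(1000), 0.9)
  set.seed(10)
  s <- mdt_schedule(5000)
  expect_equal(nrow(s), 5000)
  # goal condition is constant within each 125-episode segment
  for (seg in unique(s$segment)) {
    sub <- s[s$segment == seg, ]
    expect_equal(length(unique(sub$goal_kind)), 1)
    expect_true(all(is.na(sub$target)) || length(unique(sub$target)) == 1)
  }
  expect_true(all(is.na(s$target[s$goal_kind == "flexible"])))
  expect_true(all(s$target[s$goal_kind == "specific"] %in% 1:4))
  # identical seeds give identical schedules
  set.seed(10)
  expect_identical(s, mdt_schedule(5000))
})

test_that("gridworld movement: walls block, uncertainty splits as configured", {
  # moving up from the top row leaves the position unchanged, reward 0
  o <- cpp_grid_step(3L, 0L, 1, 8L, 8L, 4, 2)   # row 0, col 3, action up
  expect_equal(o$next_state, 3L)
  expect_equal(o$reward, 0)
  expect_false(o$terminal)
  # p = 0.5: intended direction half the time, the rest uniform (1/6 each)
  set.seed(6)
  dirs <- vapply(1:2e4, function(i)
    cpp_grid_step(8L + 3L, 3L, 0.5, 8L, 8L, 4, 2)$next_state, integer(1))
  # from (1,3): right -> (1,4)=12; up -> 3; down -> 19; left -> 10
  freq <- table(factor(dirs, levels = c(12, 3, 19, 10))) / length(dirs)
  expect_lt(abs(freq[["12"]] - 0.5), 0.015)
  for (nm in c("3", "19", "10")) expect_lt(abs(freq[[nm]] - 1 / 6), 0.015)
})

test_that("deterministic shortest path to the right zone is straight-line", {
  env <- grid_env(p_intended = 1, r_left = 0, r_right = 2)
  set.seed(8)
  env$reset()
  c0 <- (env$state - 1) %% 8
  steps <- 0
  repeat {
    o <- env$step(4)       # right
    steps <- steps + 1
    if (o$terminal) break
  }
  expect_equal(steps, 7 - c0)
  expect_equal(o$reward, 2)
})

test_that("grid states stay within bounds under a random policy", {
  set.seed(12)
  env <- grid_env(p_intended = 0.5)
  for (ep in 1:30) {
    env$reset()
    for (i in 1:50) {
      o <- env$step(sample(4, 1))
      expect_true(o$next_state >= 1 && o$next_state <= 64)
      if (o$terminal) break
    }
  }
})

test_that("the LoCA schedule runs two 3-phase blocks at 3% budget", {
  s <- loca_schedule()
  expect_equal(max(s$phase_global), 6)                    # 2 blocks x 3 phases
  expect_equal(nrow(s), 6 * round(0.03 * 3000))           # 3% of the baseline
  expect_equal(unique(s$p_intended[s$block == 1]), 0.9)
  expect_equal(unique(s$p_intended[s$block == 2]), 0.5)
  # reward layout flips: high zone pays 4 in phase 1, drops to 1 after
  expect_equal(unique(s$r_left[s$phase == 1]), 4)
  expect_equal(unique(s$r_left[s$phase != 1]), 1)
  expect_equal(unique(s$r_right), 2)
  # phase 2 restricts starts next to the changed zone
  expect_equal(unique(s$start_mode[s$phase == 2]), 1L)
  expect_equal(unique(s$start_mode[s$phase != 2]), 0L)
})

test_that("Pong: specific-goal episodes end at first paddle contact", {
  set.seed(14)
  for (tg in 1:4) {
    env <- pong_env(goal = goal_condition("specific", target_segment = tg))
    for (ep in 1:10) {
      env$reset()
      repeat {
        o <- env$step(sample(3, 1))
        if (!is.na(o$info$contact_segment)) {
          expect_true(o$terminal)
          expect_equal(o$reward,
                       as.numeric(o$info$contact_segment == tg))
          break
        }
        if (o$terminal) { expect_equal(o$reward, 0); break }
      }
    }
  }
})

test_that("Pong: flexible play pays +1/-1 and the ball speed stays bounded", {
  set.seed(15)
  env <- pong_env(stochastic = TRUE)
  rewards <- numeric(0)
  for (ep in 1:20) {
    env$reset()
    for (i in 1:2000) {
      o <- env$step(sample(3, 1))
      expect_lte(abs(env$kstate[4]), 3)       # vy bounded
      expect_lte(abs(env$kstate[3]), 3)       # vx bounded
      if (o$terminal) { rewards <- c(rewards, o$reward); break }
    }
  }
  expect_true(all(rewards %in% c(-1, 1)))
})

test_that("Pong trajectories are exactly repeatable under a fixed seed", {
  run_once <- function() {
    set.seed(33)
    env <- pong_env(stochastic = TRUE)
    env$reset()
    acts <- rep(1:3, length.out = 60)
    t(vapply(acts, function(a) env$step(a)$obs, numeric(6)))
  }
  expect_identical(run_once(), run_once())
})

test_that("the Pong schedule alternates configurations every period", {
  set.seed(20)
  s <- pong_schedule(n_segments = 10, period = 1000)
  expect_equal(s$stochastic, rep(c(FALSE, TRUE), 5))
  expect_equal(s$start_timestep, seq(0, 9000, by = 1000))
  expect_true(all(is.na(s$target_segment[s$goal_kind == "flexible"])))
  expect_true(all(s$target_segment[s$goal_kind == "specific"] %in% 1:4))
  set.seed(20)
  expect_identical(s, pong_schedule(n_segments = 10, period = 1000))
})
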