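## The three stochastic benchmark environments and their condition schedules.
## All stochasticity flows through R's RNG, so trajectories are fully
## reproducible from (configuration, seed).

#' Goal condition
#'
#' A task episode either demands one specific outcome (binary reward) or
#' accepts any outcome with graded ("flexible") reward.
#'
#' @param kind `"flexible"` or `"specific"`.
#' @param target Required token (1-based, MDT) under a specific goal.
#' @param target_segment Required paddle quarter (1-4, Pong) under a specific
#'   goal.
#' @return An object of class `"goal_condition"`.
#' @export
goal_condition <- function(kind = c("flexible", "specific"), target = NULL,
                           target_segment = NULL) {
  kind <- match.arg(kind)
  if (kind == "specific" && is.null(target) && is.null(target_segment))
    stop("a specific goal needs `target` (MDT) or `target_segment` (Pong)")
  if (kind == "flexible" && (!is.null(target) || !is.null(target_segment)))
    stop("a flexible goal has no target")
  structure(list(kind = kind, target = target,
                 target_segment = target_segment), class = "goal_condition")
}

#' Two-stage Markov decision task environment
#'
#' A two-choice, two-stage task: the first (root) action leads to one of two
#' intermediate states, the second action to one of four terminal token
#' states. Each stage executes the intended branch with probability
#' `p_intended` (0.9 = low uncertainty, 0.5 = high) and the opposite branch
#' otherwise. Stage-1 steps never pay reward. Under a flexible goal the
#' tokens pay the normalized values `token_values`; under a specific goal the
#' reward is 1 exactly when the required token is obtained.
#'
#' States are numbered 1 (root), 2-3 (intermediate), 4-7 (tokens 1-4, where
#' intermediate state 2 holds tokens 1-2 and state 3 tokens 3-4). Actions are
#' 1 (left) and 2 (right).
#'
#' @param p_intended Probability of the intended branch, in `(0, 1]`.
#' @param goal A [goal_condition()].
#' @param token_values Flexible-goal reward of each token.
#' @return An environment object with `$reset()` and `$step(action)`.
#' @export
mdt_env <- function(p_intended = 0.9, goal = goal_condition("flexible"),
                    token_values = c(0, 0.25, 0.5, 1)) {
  stopifnot(p_intended > 0, p_intended <= 1, length(token_values) == 4,
            inherits(goal, "goal_condition"))
  self <- new.env(parent = emptyenv())
  self$state <- 1L
  self$terminated <- FALSE
  self$n_states <- 7L
  self$n_actions <- 2L
  self$terminal_states <- c(rep(FALSE, 3), rep(TRUE, 4))
  self$goal <- goal
  self$reset <- function() {
    self$state <- 1L
    self$terminated <- FALSE
    self$state
  }
  self$step <- function(action) {
    if (self$terminated) stop("episode has terminated; call $reset()")
    stopifnot(action %in% 1:2)
    tgt <- if (is.null(goal$target)) -1L else goal$target - 1L
    o <- cpp_mdt_step(self$state - 1L, action - 1L, p_intended,
                      if (goal$kind == "specific") 1L else 0L, tgt,
                      token_values)
    self$state <- o$next_state + 1L
    self$terminated <- o$terminal
    list(next_state = self$state, reward = o$reward, terminal = o$terminal,
         info = list(goal = goal, p_intended = p_intended,
                     max_reward = 1.0))
  }
  class(self) <- c("mdt_env", "metadyna_env")
  self
}

#' Uncertainty level of an MDT episode
#'
#' Deterministic part of the task schedule: each block of `block_episodes`
#' episodes spends its first half at low state-transition uncertainty and its
#' second half at high uncertainty.
#'
#' @param episode_index 0-based episode index.
#' @param block_episodes Episodes per block (default 1000).
#' @param p_levels `c(low, high)` intended-branch probabilities.
#' @return `p_intended` for that episode.
#' @export
mdt_uncertainty <- function(episode_index, block_episodes = 1000,
                            p_levels = c(0.9, 0.5)) {
  stopifnot(all(episode_index >= 0))
  within <- episode_index %% block_episodes
  ifelse(within < block_episodes / 2, p_levels[1], p_levels[2])
}

#' Generate the MDT condition schedule
#'
#' The goal condition is resampled uniformly (flexible, or specific with a
#' uniformly drawn target token) at every multiple of `segment_episodes`,
#' using the current RNG state; the uncertainty level follows
#' [mdt_uncertainty()]. The default sizes give the full protocol: 5 blocks of
#' 1,000 episodes, each block 500 low-uncertainty episodes (goal resampled
#' every 125) followed by 500 high-uncertainty episodes.
#'
#' @param n_episodes Total episodes (default 5000).
#' @param block_episodes Episodes per uncertainty block.
#' @param segment_episodes Goal-condition segment length.
#' @param p_levels `c(low, high)` intended-branch probabilities.
#' @return A data.frame with one row per episode: `episode` (0-based),
#'   `p_intended`, `goal_kind`, `target` (NA under flexible goals),
#'   `segment`.
#' @export
mdt_schedule <- function(n_episodes = 5000, block_episodes = 1000,
                         segment_episodes = 125, p_levels = c(0.9, 0.5)) {
  ep <- seq_len(n_episodes) - 1L
  seg <- ep %/% segment_episodes
  n_seg <- max(seg) + 1L
  kind_seg <- sample(c("flexible", "specific"), n_seg, replace = TRUE)
  target_seg <- ifelse(kind_seg == "specific",
                       sample.int(4L, n_seg, replace = TRUE), NA_integer_)
  data.frame(episode = ep,
             p_intended = mdt_uncertainty(ep, block_episodes, p_levels),
             goal_kind = kind_seg[seg + 1L],
             target = target_seg[seg + 1L],
             segment = seg)
}

#' Local-change-adaptation gridworld environment
#'
#' An `rows x cols` gridworld whose leftmost and rightmost columns are
#' terminal reward zones. Movement succeeds in the intended direction with
#' probability `p_intended` and otherwise takes one of the remaining three
#' directions uniformly; walls block. Actions: 1 up, 2 down, 3 left, 4 right.
#' States are numbered row-wise, 1-based.
#'
#' @param rows,cols Grid size (default 8 x 8).
#' @param p_intended Probability of the intended direction.
#' @param r_left,r_right Terminal rewards of the left/right zones.
#' @param start `"uniform"` (any interior column) or `"near_left"`
#'   (column adjacent to the left zone).
#' @return An environment object with `$reset()` and `$step(action)`.
#' @export
grid_env <- function(rows = 8, cols = 8, p_intended = 0.9, r_left = 4,
                     r_right = 2, start = c("uniform", "near_left")) {
  start <- match.arg(start)
  stopifnot(rows >= 2, cols >= 3, p_intended > 0, p_intended <= 1)
  self <- new.env(parent = emptyenv())
  self$n_states <- as.integer(rows * cols)
  self$n_actions <- 4L
  tcol <- ((seq_len(rows * cols) - 1L) %% cols)
  self$terminal_states <- tcol == 0L | tcol == cols - 1L
  self$terminated <- FALSE
  self$reset <- function() {
    r <- sample.int(rows, 1L) - 1L
    cc <- if (start == "near_left") 1L else sample.int(cols - 2L, 1L)
    self$state <- as.integer(r * cols + cc + 1L)
    self$terminated <- FALSE
    self$state
  }
  self$step <- function(action) {
    if (self$terminated) stop("episode has terminated; call $reset()")
    stopifnot(action %in% 1:4)
    o <- cpp_grid_step(self$state - 1L, action - 1L, p_intended, rows, cols,
                       r_left, r_right)
    self$state <- o$next_state + 1L
    self$terminated <- o$terminal
    list(next_state = self$state, reward = o$reward, terminal = o$terminal,
         info = list(p_intended = p_intended,
                     max_reward = max(r_left, r_right)))
  }
  self$reset()
  class(self) <- c("grid_env", "metadyna_env")
  self
}

#' Generate the LoCA-style phase schedule
#'
#' Two blocks of three sequential phases (block 1 at the first `p_order`
#' uncertainty level, block 2 at the second). Phase 1: the left zone pays
#' `reward_high`, the right `reward_low`, starts drawn uniformly. Phase 2:
#' the left zone's reward drops to `reward_drop` (so the optimal policy
#' flips to the right zone) and starts are restricted next to the left zone.
#' Phase 3: same rewards as phase 2 with uniform starts again. The per-phase
#' episode budget is `budget_frac` of `baseline_episodes`.
#'
#' @param p_order Uncertainty levels of the two blocks.
#' @param baseline_episodes Baseline per-phase budget (default 3000).
#' @param budget_frac Fraction of the baseline used per phase (default 0.03).
#' @param reward_high,reward_low,reward_drop Zone rewards (defaults 4, 2, 1).
#' @return A data.frame with one row per episode: `episode`, `block`,
#'   `phase` (1-3), `phase_global` (1-6), `p_intended`, `r_left`, `r_right`,
#'   `start_mode` (0 uniform, 1 near-left), `max_reward`.
#' @export
loca_schedule <- function(p_order = c(0.9, 0.5), baseline_episodes = 3000,
                          budget_frac = 0.03, reward_high = 4,
                          reward_low = 2, reward_drop = 1) {
  per_phase <- max(1L, round(budget_frac * baseline_episodes))
  rows <- do.call(rbind, lapply(seq_along(p_order), function(b) {
    do.call(rbind, lapply(1:3, function(ph) {
      rl <- if (ph == 1) reward_high else reward_drop
      data.frame(block = b, phase = ph,
                 phase_global = (b - 1L) * 3L + ph,
                 p_intended = p_order[b],
                 r_left = rl, r_right = reward_low,
                 start_mode = if (ph == 2) 1L else 0L,
                 max_reward = max(rl, reward_low))[rep(1, per_phase), ]
    }))
  }))
  rows$episode <- seq_len(nrow(rows)) - 1L
  rownames(rows) <- NULL
  rows[, c("episode", "block", "phase", "phase_global", "p_intended",
           "r_left", "r_right", "start_mode", "max_reward")]
}

#' Single-point stochastic Pong environment
#'
#' A lightweight geometric Pong on an 84 x 84 pixel field: the agent's
#' 20-pixel paddle on the right, a ball-tracking opponent with capped speed
#' on the left, and episodes that end at the first point. In the
#' deterministic configuration the reflection angle is a pure function of the
#' contact offset and the paddle moves exactly as commanded; the stochastic
#' configuration adds reflection-angle jitter (about +/-15 degrees) and
#' replaces the commanded paddle move with a random one with probability
#' `1 - paddle_p`. Under a specific goal the episode terminates at the first
#' agent-paddle contact with reward 1 exactly when the contact lies in the
#' scheduled quarter of the paddle; under a flexible goal the reward is +1
#' when the opponent misses and -1 when the agent misses. Actions: 1 stay,
#' 2 up, 3 down. Pixel coordinates are 0-based with y growing downward.
#'
#' @param stochastic Use the stochastic configuration.
#' @param goal A [goal_condition()] (use `target_segment` 1-4 for specific).
#' @param paddle_p Probability of the intended paddle displacement under the
#'   stochastic configuration.
#' @return An environment object with `$reset()` and `$step(action)`;
#'   `$observe()` returns the normalized 6-dimensional state vector
#'   (ball x/y, velocity x/y, both paddle positions).
#' @export
pong_env <- function(stochastic = FALSE,
                     goal = goal_condition("flexible"), paddle_p = 0.9) {
  stopifnot(inherits(goal, "goal_condition"), paddle_p > 0, paddle_p <= 1)
  self <- new.env(parent = emptyenv())
  par <- list(paddle_p = paddle_p)
  self$n_actions <- 3L
  self$terminated <- FALSE
  self$goal <- goal
  self$reset <- function() {
    self$kstate <- cpp_pong_reset(par)
    self$terminated <- FALSE
    invisible(self$observe())
  }
  self$observe <- function() {
    s <- self$kstate
    c(ball_x = s[1] / 84, ball_y = s[2] / 84, vx = (s[3] + 3) / 6,
      vy = (s[4] + 3) / 6, paddle_y = s[5] / 64, opp_y = s[6] / 64)
  }
  self$step <- function(action) {
    if (self$terminated) stop("episode has terminated; call $reset()")
    stopifnot(action %in% 1:3)
    tgt <- if (is.null(goal$target_segment)) -1L else goal$target_segment - 1L
    o <- cpp_pong_step(self$kstate, action - 1L, stochastic,
                       if (goal$kind == "specific") 1L else 0L, tgt, par)
    self$kstate <- o$state
    self$terminated <- o$terminal
    list(obs = o$obs, reward = o$reward, terminal = o$terminal,
         info = list(goal = goal, stochastic = stochastic,
                     contact_segment = if (o$contact_segment >= 0)
                       o$contact_segment + 1L else NA_integer_,
                     max_reward = 1.0))
  }
  self$reset()
  class(self) <- c("pong_env", "metadyna_env")
  self
}

#' Generate the Pong condition schedule
#'
#' Alternates the deterministic/stochastic configuration and resamples the
#' goal condition (with a uniform target quarter when specific) every
#' `period` environment timesteps (agent decisions), using the current RNG.
#'
#' @param n_segments Number of `period`-timestep segments to generate.
#' @param period Timesteps per segment (default 1000).
#' @return A data.frame: `segment` (1-based), `start_timestep`, `stochastic`,
#'   `goal_kind`, `target_segment` (NA when flexible).
#' @export
pong_schedule <- function(n_segments = 20, period = 1000) {
  stopifnot(n_segments >= 1, period >= 1)
  kind <- sample(c("flexible", "specific"), n_segments, replace = TRUE)
  data.frame(segment = seq_len(n_segments),
             start_timestep = (seq_len(n_segments) - 1L) * period,
             stochastic = (seq_len(n_segments) - 1L) %% 2L == 1L,
             goal_kind = kind,
             target_segment = ifelse(kind == "specific",
                                     sample.int(4L, n_segments, replace = TRUE),
                                     NA_integer_))
}
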