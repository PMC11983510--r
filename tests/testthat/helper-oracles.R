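# Independent oracles used across the test files.

# Exact value iteration on an explicit MDP: trans[s, a, s'] transition
# probabilities, rew[s, a] expected immediate reward, terminal[s] flags.
vi_oracle <- function(trans, rew, terminal, gamma = 0.9, iters = 500) {
  S <- dim(trans)[1]; A <- dim(trans)[2]
  q <- matrix(0, S, A)
  for (k in seq_len(iters)) {
    v <- ifelse(terminal, 0, apply(q, 1, max))
    for (s in which(!terminal))
      for (a in seq_len(A))
        q[s, a] <- rew[s, a] + gamma * sum(trans[s, a, ] * v)
  }
  q
}

# Explicit MDP of the two-stage task at a fixed p_intended under a flexible
# goal: states 1 root, 2-3 intermediate, 4-7 tokens (terminal).
mdt_mdp <- function(p, token_values = c(0, 0.25, 0.5, 1)) {
  trans <- array(0, c(7, 2, 7))
  rew <- matrix(0, 7, 2)
  for (a in 1:2) {
    trans[1, a, 1 + a] <- p
    trans[1, a, 4 - a] <- 1 - p
  }
  for (s in 2:3) {
    base <- 2 * (s - 2)
    for (a in 1:2) {
      tok_int <- base + a; tok_oth <- base + (3 - a)
      trans[s, a, 3 + tok_int] <- p
      trans[s, a, 3 + tok_oth] <- 1 - p
      rew[s, a] <- p * token_values[tok_int] + (1 - p) * token_values[tok_oth]
    }
  }
  list(trans = trans, rew = rew, terminal = c(FALSE, FALSE, FALSE, rep(TRUE, 4)))
}

# A constant (no phase switching) gridworld schedule for run_loca().
flat_grid_schedule <- function(n_episodes, p_intended = 1, r_left = 0,
                               r_right = 1, start_mode = 0L) {
  data.frame(episode = seq_len(n_episodes) - 1L, block = 1L, phase = 1L,
             phase_global = 1L, p_intended = p_intended, r_left = r_left,
             r_right = r_right, start_mode = start_mode,
             max_reward = max(r_left, r_right))
}

# A constant MDT schedule (fixed goal and uncertainty).
flat_mdt_schedule <- function(n_episodes, p_intended = 1,
                              goal_kind = "flexible", target = NA_integer_) {
  data.frame(episode = seq_len(n_episodes) - 1L, p_intended = p_intended,
             goal_kind = goal_kind, target = target, segment = 0L)
}
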