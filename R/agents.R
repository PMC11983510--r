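## Agents: granular update operations, the agent registry, and whole-run
## drivers over the compiled episode runners.

.TABULAR_AGENTS <- c("q-learning", "sarsa", "forward", "dyna-q", "meta-dyna",
                     "forward+sarsa", "forward+qlearning")
.NETWORK_AGENTS <- c("dqn", "dyna-q", "meta-dyna")

#' List the available agents
#'
#' @param backend `"tabular"` or `"network"`.
#' @return Character vector of agent names accepted by the run functions.
#' @export
list_agents <- function(backend = c("tabular", "network")) {
  switch(match.arg(backend), tabular = .TABULAR_AGENTS,
         network = .NETWORK_AGENTS)
}

#' Agent configuration
#'
#' Collects every tunable parameter of the agents with its default. Tabular
#' defaults: model-free learning rate `lr_mf = 0.1`, model-based (planning)
#' rate `lr_mb = 0.4` (aggressive steps are safe on model-filtered simulated
#' experience and are needed to track the goal schedule), `gamma = 0.9`,
#' `epsilon = 0.1` (no decay), `n_planning = 10` simulated transitions per
#' episode replayed in reverse chain order with simulation exploration
#' `sim_epsilon = 0.6`, model step `gamma_t = 0.2`, reward step
#' `r_step = 0.4`, Pearce-Hall `ph_eta = 0.2` / `rpe_max = 1`, zero band
#' `omega = 0.2`, Dirichlet `dir_prior = 1` / `dir_decay = 0.98`,
#' arbitration gains `A_alpha = A_beta = 0.3` with slopes `B_alpha = 3`,
#' `B_beta = 15`, initial `p_mb0 = 0.5`. Network keys add the layer sizes
#' (`hidden_q`, `hidden_wm`),
#' mixture size `n_components = 5`, Adam rates (`lr_q`, `lr_wm`), replay
#' settings and the sampling `temperature`. Any subset can be overridden.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `"agent_config"`.
#' @export
agent_config <- function(...) {
  defaults <- list(
    lr_mf = 0.1, lr_mb = 0.4, gamma = 0.9,
    epsilon = 0.1, eps_decay = 1.0, eps_min = 0.0,
    n_planning = 10L, horizon = 30L, vi_sweeps = 1L, max_steps = 100L,
    gamma_t = 0.2, r_step = 0.4, count_mode = FALSE,
    ph_eta = 0.2, rpe_max = 1.0, omega = 0.2,
    dir_prior = 1.0, dir_decay = 0.98, p_mb0 = 0.5,
    A_alpha = 0.3, B_alpha = 3.0, A_beta = 0.3, B_beta = 15.0,
    mf_per_step = FALSE, planning_per_step = FALSE, record_actions = FALSE,
    sim_start = "s0", sim_epsilon = 0.6, wm_train_on_sim = TRUE,
    planning_backup = "sample",
    # network backend
    hidden_q = 32L, hidden_wm = 32L, n_components = 5L,
    lr_q = 1e-3, lr_q_mb = -1, lr_wm = 1e-3, batch_size = 16L,
    train_every = 4L,
    target_sync = 100L, replay_capacity = 10000L,
    wm_seq_len = 16L, wm_reps = 2L, temperature = 1.0)
  overrides <- list(...)
  if (length(overrides) == 1 && is.list(overrides[[1]]) &&
      is.null(names(overrides)))
    overrides <- overrides[[1]]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, overrides)
  # n_planning = 0 is the degenerate "planning disabled" configuration used
  # by the arbitration-equivalence checks; normal operation uses >= 1
  stopifnot(cfg$gamma >= 0, cfg$gamma < 1, cfg$epsilon >= 0, cfg$epsilon <= 1,
            cfg$n_planning >= 0, cfg$A_alpha > 0, cfg$A_alpha <= 1,
            cfg$A_beta > 0, cfg$A_beta <= 1)
  structure(cfg, class = "agent_config")
}

#' One Q-learning update
#'
#' `Q(s,a) <- Q(s,a) + lr * (r + gamma * (1 - terminal) * max_a' Q(s',a')
#' - Q(s,a))`.
#'
#' @param q `n_states x n_actions` value matrix.
#' @param transition A list/row with `s`, `a`, `r`, `s_next`, `terminal`
#'   (1-based indices).
#' @param lr Step size.
#' @param gamma Discount factor.
#' @return The updated matrix.
#' @export
qlearn_update <- function(q, transition, lr = 0.1, gamma = 0.9) {
  tr <- transition
  tgt <- tr$r + if (isTRUE(tr$terminal)) 0 else gamma * max(q[tr$s_next, ])
  q[tr$s, tr$a] <- q[tr$s, tr$a] + lr * (tgt - q[tr$s, tr$a])
  q
}

#' One SARSA update
#'
#' On-policy TD target `r + gamma * Q(s', a_next)`.
#'
#' @param q Value matrix.
#' @param transition As in [qlearn_update()].
#' @param a_next The action actually selected in `s_next` (ignored at
#'   terminals).
#' @param lr Step size.
#' @param gamma Discount factor.
#' @return The updated matrix.
#' @export
sarsa_update <- function(q, transition, a_next, lr = 0.1, gamma = 0.9) {
  tr <- transition
  tgt <- tr$r + if (isTRUE(tr$terminal)) 0 else gamma * q[tr$s_next, a_next]
  q[tr$s, tr$a] <- q[tr$s, tr$a] + lr * (tgt - q[tr$s, tr$a])
  q
}

#' One FORWARD (pure model-based) update
#'
#' Learns the tabular world model from the real transition, then refreshes
#' the model-based values with one sweep of value iteration (Bellman
#' optimality backup through the learned transition and reward estimates).
#'
#' @param model A [tabular_model()].
#' @param q_mb Value matrix to refresh.
#' @param transition As in [qlearn_update()].
#' @param terminal_states Logical vector marking terminal states.
#' @param gamma Discount factor.
#' @param sweeps Value-iteration sweeps (default 1).
#' @return `list(model, q_mb)`.
#' @export
forward_update <- function(model, q_mb, transition, terminal_states,
                           gamma = 0.9, sweeps = 1) {
  stopifnot(inherits(model, "tabular_model"))
  tr <- transition
  model <- tabular_update(model, tr$s, tr$a, tr$s_next, tr$r)
  S <- model$n_states; A <- model$n_actions
  for (k in seq_len(sweeps)) {
    v <- ifelse(terminal_states, 0, apply(q_mb, 1, max))
    for (s in which(!terminal_states)) {
      for (a in seq_len(A)) {
        sa <- (s - 1L) * A + a
        q_mb[s, a] <- model$r_est[sa] + gamma * sum(model$t_est[sa, ] * v)
      }
      v[s] <- max(q_mb[s, ])   # in-place (Gauss-Seidel) backup
    }
  }
  list(model = model, q_mb = q_mb)
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` the greedy action (ties broken uniformly at
#' random through the session RNG), otherwise a uniform action.
#'
#' @param q_values Per-action values for the current state.
#' @param epsilon Exploration rate in `[0, 1]`.
#' @return 1-based action index.
#' @export
select_action <- function(q_values, epsilon = 0.1) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  cpp_eps_greedy(as.numeric(q_values), epsilon) + 1L
}

.as_cfg_list <- function(config) {
  cfg <- unclass(agent_config(config))
  cfg$gamma_t <- if (isTRUE(cfg$count_mode) || is.na(cfg$gamma_t)) 0.0
                 else cfg$gamma_t
  cfg$count_mode <- isTRUE(cfg$count_mode) || is.na(config$gamma_t %||% 0.2)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# network-backend defaults where the discrete-SPE scale or tabular step sizes
# do not transfer: the z-scored SPE lives on a different scale (omega), Adam
# replaces constant steps (lr_q, lr_wm), and the arbitration slope is matched
# to the flatter Rel_MB range of the mixture model
.net_config <- function(config) {
  for (nm in names(.NET_DEFAULTS))
    if (!(nm %in% names(config))) config[[nm]] <- .NET_DEFAULTS[[nm]]
  config
}
.NET_DEFAULTS <- list(omega = 0.5, lr_q = 3e-3, lr_q_mb = 9e-3, lr_wm = 3e-3,
                      B_beta = 8)

#' Run an agent on the two-stage MDT
#'
#' Executes the full episode loop of the named agent against an MDT condition
#' schedule. The Meta-Dyna agent follows its canonical per-episode cadence:
#' act epsilon-greedily on the integrated values, store real transitions in
#' the model-free replay buffer and the world-model buffer, then train the
#' model-free values, train the world model, run `n_planning` simulated
#' transitions of mental simulation into the model-based values, update both
#' reliabilities and P_MB, and recombine the values.
#'
#' @param agent Agent name (see [list_agents()]).
#' @param schedule A data.frame from [mdt_schedule()].
#' @param config An [agent_config()] or named list of overrides.
#' @param backend `"tabular"` or `"network"`.
#' @param seed Optional integer seed (calls `set.seed()`).
#' @param token_values Flexible-goal token rewards.
#' @param details If `TRUE`, also return final value tables, the learned
#'   model and diagnostics.
#' @return A data.frame with one row per episode (`episode`, `reward`,
#'   `optimal`, `steps`, `p_mb`, `rel_mf`, `rel_mb` plus the schedule
#'   columns), or a list when `details = TRUE`.
#' @export
run_mdt <- function(agent, schedule = NULL, config = list(),
                    backend = c("tabular", "network"), seed = NULL,
                    token_values = c(0, 0.25, 0.5, 1), details = FALSE) {
  backend <- match.arg(backend)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) schedule <- mdt_schedule()
  agent <- match.arg(agent, list_agents(backend))
  if (backend == "network") config <- .net_config(as.list(config))
  cfg <- .as_cfg_list(config)
  goal_kind <- ifelse(schedule$goal_kind == "specific", 1L, 0L)
  target <- ifelse(is.na(schedule$target), -1L, schedule$target - 1L)
  res <- if (backend == "tabular") {
    run_mdt_tabular_cpp(agent, schedule$p_intended, goal_kind, target,
                        token_values, cfg)
  } else {
    run_mdt_net_cpp(agent, schedule$p_intended, goal_kind, target,
                    token_values, cfg)
  }
  log <- data.frame(schedule, reward = res$reward, optimal = res$optimal,
                    steps = res$steps, p_mb = res$p_mb, rel_mf = res$rel_mf,
                    rel_mb = res$rel_mb, agent = agent,
                    max_reward = 1.0)
  if (!details) return(log)
  c(list(log = log), res[setdiff(names(res), c("reward", "optimal", "steps",
                                               "p_mb", "rel_mf", "rel_mb"))])
}

#' Run a tabular agent on the LoCA gridworld protocol
#'
#' @param agent Agent name (tabular registry).
#' @param schedule A data.frame from [loca_schedule()].
#' @param config An [agent_config()] or named list of overrides.
#' @param rows,cols Grid size.
#' @param seed Optional integer seed.
#' @param details As in [run_mdt()].
#' @return A per-episode data.frame (schedule columns plus `reward`,
#'   `optimal`, `steps`, `p_mb`, `rel_mf`, `rel_mb`, `norm_return`).
#' @export
run_loca <- function(agent, schedule = NULL, config = list(), rows = 8,
                     cols = 8, seed = NULL, details = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) schedule <- loca_schedule()
  agent <- match.arg(agent, .TABULAR_AGENTS)
  cfg <- .as_cfg_list(config)
  res <- run_grid_tabular_cpp(agent, rows, cols, schedule$p_intended,
                              schedule$r_left, schedule$r_right,
                              schedule$start_mode, cfg)
  log <- data.frame(schedule, reward = res$reward, optimal = res$optimal,
                    steps = res$steps, p_mb = res$p_mb, rel_mf = res$rel_mf,
                    rel_mb = res$rel_mb, agent = agent)
  log$norm_return <- log$reward / log$max_reward
  if (!details) return(log)
  c(list(log = log), res[setdiff(names(res), c("reward", "optimal", "steps",
                                               "p_mb", "rel_mf", "rel_mb"))])
}

#' Run a network agent on stochastic Pong
#'
#' @param agent Agent name (network registry: `"meta-dyna"`, `"dyna-q"`,
#'   `"dqn"`).
#' @param n_episodes Episodes to run.
#' @param schedule A data.frame from [pong_schedule()] (regenerated from the
#'   current RNG when `NULL`).
#' @param config An [agent_config()] or named list of overrides.
#' @param period Timesteps per schedule segment.
#' @param paddle_p Intended paddle-displacement probability (stochastic
#'   configuration).
#' @param seed Optional integer seed.
#' @return A per-episode data.frame (`episode`, `reward`, `optimal`, `steps`,
#'   `interactions` cumulative real steps, `p_mb`, `rel_mf`, `rel_mb`,
#'   `goal_kind`, `stochastic`).
#' @export
run_pong <- function(agent, n_episodes = 1000, schedule = NULL,
                     config = list(), period = 1000, paddle_p = 0.9,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  agent <- match.arg(agent, .NETWORK_AGENTS)
  cfg <- .as_cfg_list(.net_config(as.list(config)))
  if (is.null(cfg$max_steps) || cfg$max_steps == 100L) cfg$max_steps <- 600L
  if (is.null(schedule)) {
    # generous upper bound on segments reached within the run
    schedule <- pong_schedule(n_segments = max(20L,
      ceiling(n_episodes * cfg$max_steps / period) + 1L), period = period)
  }
  res <- run_pong_cpp(agent, n_episodes, schedule$stochastic,
                      ifelse(schedule$goal_kind == "specific", 1L, 0L),
                      ifelse(is.na(schedule$target_segment), -1L,
                             schedule$target_segment - 1L),
                      period, paddle_p, cfg)
  seg_at_start <- pmin(findInterval(c(0, cumsum(res$steps))[seq_len(n_episodes)],
                                    schedule$start_timestep),
                       nrow(schedule))
  data.frame(episode = seq_len(n_episodes) - 1L, reward = res$reward,
             optimal = res$optimal, steps = res$steps,
             interactions = res$interactions, p_mb = res$p_mb,
             rel_mf = res$rel_mf, rel_mb = res$rel_mb,
             goal_kind = schedule$goal_kind[seg_at_start],
             stochastic = schedule$stochastic[seg_at_start],
             agent = agent, max_reward = 1.0)
}
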