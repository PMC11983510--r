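## World models: tabular transition/reward estimation, the recurrent
## mixture-density network, and mental-simulation rollouts.

#' Tabular world model
#'
#' Per-(s, a) transition-probability rows learned with the two-branch rule
#' (matched successor: `t <- t + g * (1 - t)`; others: `t <- t * (1 - g)`;
#' row renormalised), plus an expected-reward estimate and visit counts.
#'
#' `gamma_t` is the model step size. With a fixed `gamma_t` in `(0, 1]` the
#' estimates track non-stationary dynamics (exponential forgetting); with
#' `gamma_t = NA` the step decays as `1 / n(s, a)` and the rows converge to
#' the empirical transition frequencies (stationary estimation).
#'
#' @param n_states,n_actions State/action space sizes.
#' @param gamma_t Model step size in `[0, 1]`, or `NA` for `1/n` steps.
#' @param r_step Reward estimate step size (ignored when `gamma_t` is `NA`).
#' @return An object of class `"tabular_model"`.
#' @export
tabular_model <- function(n_states, n_actions, gamma_t = 0.2, r_step = 0.2) {
  stopifnot(n_states >= 2, n_actions >= 1,
            is.na(gamma_t) || (gamma_t >= 0 && gamma_t <= 1))
  structure(list(
    n_states = as.integer(n_states), n_actions = as.integer(n_actions),
    t_est = matrix(1 / n_states, n_states * n_actions, n_states),
    r_est = numeric(n_states * n_actions),
    visit_counts = integer(n_states * n_actions),
    gamma_t = gamma_t, r_step = r_step), class = "tabular_model")
}

.sa_index <- function(model, s, a) {
  if (s < 1 || s > model$n_states) stop("unknown state index: ", s)
  if (a < 1 || a > model$n_actions) stop("unknown action index: ", a)
  (s - 1L) * model$n_actions + a
}

#' Update a tabular model from one observed transition
#'
#' @param model A [tabular_model()].
#' @param s,a,s_next 1-based state/action indices of the observed transition.
#' @param reward Observed reward (updates the running reward estimate).
#' @return The updated model.
#' @export
tabular_update <- function(model, s, a, s_next, reward = 0) {
  stopifnot(inherits(model, "tabular_model"))
  sa <- .sa_index(model, s, a)
  if (s_next < 1 || s_next > model$n_states)
    stop("unknown state index: ", s_next)
  n <- model$visit_counts[sa] + 1L
  g <- if (is.na(model$gamma_t)) 1 / n else model$gamma_t
  rs <- if (is.na(model$gamma_t)) 1 / n else model$r_step
  model$t_est[sa, ] <- cpp_trans_row_update(model$t_est[sa, ], s_next - 1L, g)
  model$r_est[sa] <- model$r_est[sa] + rs * (reward - model$r_est[sa])
  model$visit_counts[sa] <- n
  model
}

#' Predict the successor distribution and expected reward
#'
#' @param model A [tabular_model()].
#' @param s,a 1-based state/action indices.
#' @return `list(probs, reward, cold)`; for a never-visited (s, a) the
#'   distribution is uniform, the reward 0 and `cold = TRUE`.
#' @export
tabular_predict <- function(model, s, a) {
  stopifnot(inherits(model, "tabular_model"))
  sa <- .sa_index(model, s, a)
  list(probs = model$t_est[sa, ], reward = model$r_est[sa],
       cold = model$visit_counts[sa] == 0L)
}

#' Rollout (mental simulation) configuration
#'
#' @param n_steps Simulated transitions per planning call (>= 1, default 10).
#' @param temperature Sampling temperature for mixture world models (> 0).
#' @param horizon Maximum chain depth per simulated trajectory.
#' @return An object of class `"rollout_config"`.
#' @export
rollout_config <- function(n_steps = 10, temperature = 1, horizon = 30) {
  if (!is.numeric(n_steps) || n_steps < 1)
    stop("`n_steps` must be a positive integer (>= 1)")
  stopifnot(temperature > 0, horizon >= 1)
  structure(list(n_steps = as.integer(n_steps), temperature = temperature,
                 horizon = as.integer(horizon)), class = "rollout_config")
}

#' Generate simulated experience from a learned world model
#'
#' Chains up to `config$n_steps` simulated transitions from `s0`, choosing
#' actions epsilon-greedily on `q`, sampling successors from the model
#' (categorical for a tabular model; mixture sampling with temperature for a
#' network model) and stopping at a predicted terminal or the horizon. A cold
#' (never-trained) model yields an empty rollout - simulated experience is
#' never fabricated from an unfit model. All transitions are tagged
#' `simulated = TRUE`; in the Meta-Dyna agent they train only the model-based
#' value function.
#'
#' @param model A [tabular_model()] or [mdn_world_model()].
#' @param q For a tabular model, an `n_states x n_actions` value matrix; for a
#'   network model, a Q-network handle as used by the network agents.
#' @param s0 Start state (1-based index, or state vector for network models).
#' @param config A [rollout_config()].
#' @param terminal_states Logical vector marking terminal states (tabular).
#' @param epsilon Exploration rate of the simulated policy.
#' @return A data.frame of simulated transitions (tabular), or a list with
#'   state matrices (network models).
#' @export
rollout <- function(model, q, s0, config = rollout_config(),
                    terminal_states = NULL, epsilon = 0.1) {
  stopifnot(inherits(config, "rollout_config"))
  if (inherits(model, "tabular_model")) {
    if (is.null(terminal_states))
      stop("`terminal_states` is required for tabular rollouts")
    stopifnot(is.matrix(q), nrow(q) == model$n_states,
              ncol(q) == model$n_actions,
              length(terminal_states) == model$n_states)
    out <- cpp_tab_rollout(model$t_est, model$r_est, model$visit_counts,
                           terminal_states, q, s0 - 1L, config$n_steps,
                           config$horizon, epsilon)
    data.frame(s = out$s + 1L, a = out$a + 1L, r = out$r,
               s_next = out$s_next + 1L, terminal = out$terminal,
               simulated = out$simulated)
  } else if (inherits(model, "mdn_world_model")) {
    cpp_mdn_rollout(model$ptr, q$ptr, s0, config$n_steps, config$horizon,
                    epsilon, config$temperature)
  } else {
    stop("`model` must be a tabular_model or mdn_world_model")
  }
}

#' Gaussian-mixture prediction of the next state and reward
#'
#' Container for one world-model prediction: `K` mixture weights (summing to
#' one), per-component mean and scale vectors over the state dimensions, and
#' a Gaussian reward head.
#'
#' @param weights Mixture weights (length `K`, non-negative, sum 1).
#' @param means,scales `D x K` matrices (scales strictly positive).
#' @param reward_mean,reward_scale Reward head parameters.
#' @param p_terminal Predicted termination probability.
#' @return An object of class `"gmm_prediction"`.
#' @export
gmm_prediction <- function(weights, means, scales, reward_mean = 0,
                           reward_scale = 1, p_terminal = 0) {
  means <- as.matrix(means)
  scales <- as.matrix(scales)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
    stop("mixture weights must be non-negative and sum to 1 (tolerance 1e-6)")
  if (any(scales <= 0)) stop("all component scales must be positive")
  if (!all(dim(means) == dim(scales)))
    stop("`means` and `scales` must have identical dimensions")
  if (ncol(means) != length(weights))
    stop("number of components must match length(weights)")
  if (reward_scale <= 0) stop("`reward_scale` must be positive")
  structure(list(weights = weights, means = means, scales = scales,
                 reward_mean = reward_mean, reward_scale = reward_scale,
                 p_terminal = p_terminal), class = "gmm_prediction")
}

#' Negative log-likelihood of a target under a mixture prediction
#'
#' Diagonal-Gaussian mixture NLL of the next state, plus (optionally) the
#' Gaussian NLL of the reward.
#'
#' @param prediction A [gmm_prediction()].
#' @param target_state Observed next-state vector.
#' @param target_reward Observed reward, or `NULL` to score the state only.
#' @return Scalar loss (can be negative for very sharp correct predictions).
#' @export
mdn_nll <- function(prediction, target_state, target_reward = NULL) {
  stopifnot(inherits(prediction, "gmm_prediction"))
  if (length(target_state) != nrow(prediction$means))
    stop("dimension mismatch between target and prediction")
  K <- length(prediction$weights)
  ll <- vapply(seq_len(K), function(k) {
    log(prediction$weights[k] + 1e-300) +
      sum(stats::dnorm(target_state, prediction$means[, k],
                       prediction$scales[, k], log = TRUE))
  }, numeric(1))
  m <- max(ll)
  out <- -(m + log(sum(exp(ll - m))))
  if (!is.null(target_reward))
    out <- out - stats::dnorm(target_reward, prediction$reward_mean,
                              prediction$reward_scale, log = TRUE)
  out
}

#' Recurrent mixture-density world model
#'
#' A single-layer gated recurrent network whose output head parameterises a
#' diagonal Gaussian mixture over the next state, a Gaussian reward and a
#' Bernoulli terminal flag. Inputs per step are the state vector, a one-hot
#' action and the previous step's state/reward prediction errors. The hidden
#' state is reset at episode boundaries; training runs backpropagation
#' through time over episode-ordered sequences.
#'
#' @param state_dim State vector dimension.
#' @param n_actions Number of discrete actions.
#' @param hidden Recurrent units (default 128).
#' @param n_components Mixture components `K` (default 5).
#' @param lr Adam learning rate.
#' @return An object of class `"mdn_world_model"` (holds the network handle).
#' @export
mdn_world_model <- function(state_dim, n_actions, hidden = 128,
                            n_components = 5, lr = 1e-3) {
  stopifnot(state_dim >= 1, n_actions >= 2, hidden >= 1, n_components >= 1)
  structure(list(ptr = cpp_mdn_new(state_dim, n_actions, hidden, n_components, lr),
                 state_dim = as.integer(state_dim),
                 n_actions = as.integer(n_actions),
                 hidden = as.integer(hidden),
                 n_components = as.integer(n_components)),
            class = "mdn_world_model")
}

.mdn_inputs <- function(model, episode) {
  D <- model$state_dim
  nA <- model$n_actions
  Tn <- nrow(episode$states)
  X <- matrix(0, D + nA + 2, Tn)
  X[seq_len(D), ] <- t(episode$states)
  for (t in seq_len(Tn)) {
    X[D + episode$actions[t], t] <- 1
    if (t > 1) {
      X[D + nA + 1, t] <- if (is.null(episode$spe)) 0 else episode$spe[t - 1]
      X[D + nA + 2, t] <- if (is.null(episode$rpe)) 0 else episode$rpe[t - 1]
    }
  }
  X
}

#' Predict next-state mixtures along an episode
#'
#' Runs the recurrent model over one episode-ordered sequence (hidden state
#' reset at the start) and returns the per-step [gmm_prediction()]s.
#'
#' @param object An [mdn_world_model()].
#' @param episode A list with `states` (`T x D` matrix of visited states, in
#'   order), `actions` (1-based), and optionally `spe`, `rpe` vectors.
#' @param temperature Softmax temperature on the mixture weights.
#' @param ... Unused.
#' @return A list of `gmm_prediction` objects, one per step.
#' @export
predict.mdn_world_model <- function(object, episode, temperature = 1, ...) {
  X <- .mdn_inputs(object, episode)
  preds <- cpp_mdn_predict(object$ptr, X, temperature)
  lapply(preds, function(p)
    gmm_prediction(p$weights, p$means, p$scales, p$reward_mean,
                   p$reward_scale, p$p_terminal))
}

#' Train a world model from a buffer of experience
#'
#' For a tabular model the buffer is a data.frame of transitions (columns
#' `s`, `a`, `s_next`, `r`) replayed through [tabular_update()]. For the
#' recurrent model the buffer must be a *list of episodes*, each a list with
#' `states` (`T x D`, in within-episode order), `actions`, `rewards`,
#' `next_states` (`T x D`) and `terminal`; flat or shuffled input is rejected
#' because the recurrent model is only defined on episode-ordered sequences.
#'
#' @param model The model to train.
#' @param buffer Experience as described above (must be non-empty).
#' @param epochs Training passes over the buffer.
#' @return For tabular models the updated model; for network models the
#'   (invisible) model, with the per-sequence loss trace in
#'   `attr(, "loss_trace")`.
#' @export
train_world_model <- function(model, buffer, epochs = 1) {
  if (inherits(model, "tabular_model")) {
    if (!is.data.frame(buffer) || nrow(buffer) == 0)
      stop("`buffer` must be a non-empty data.frame of transitions")
    for (e in seq_len(epochs))
      for (i in seq_len(nrow(buffer)))
        model <- tabular_update(model, buffer$s[i], buffer$a[i],
                                buffer$s_next[i], buffer$r[i])
    model
  } else if (inherits(model, "mdn_world_model")) {
    if (!is.list(buffer) || length(buffer) == 0 || is.data.frame(buffer))
      stop("the recurrent model trains on a non-empty *list of episodes* ",
           "(within-episode order matters); got ", class(buffer)[1])
    ok <- vapply(buffer, function(ep)
      is.list(ep) && !is.null(ep$states) && !is.null(ep$actions) &&
        !is.null(ep$next_states), logical(1))
    if (!all(ok))
      stop("each episode needs `states`, `actions` and `next_states`")
    losses <- numeric(0)
    for (e in seq_len(epochs)) {
      for (ep in buffer) {
        X <- .mdn_inputs(model, ep)
        loss <- cpp_mdn_train_seq(model$ptr, X, t(ep$next_states),
                                  as.numeric(ep$rewards),
                                  as.numeric(ep$terminal))
        losses <- c(losses, loss)
      }
    }
    attr(model, "loss_trace") <- losses
    invisible(model)
  } else {
    stop("unsupported model class")
  }
}
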