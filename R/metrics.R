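## Evaluation metrics.

#' Mean normalized reward
#'
#' Arithmetic mean of per-episode total rewards (the tasks pay rewards on a
#' normalized `[0, 1]` scale; Pong is signed).
#'
#' @param records A per-episode data.frame with a `reward` column, or a
#'   numeric vector of episode rewards.
#' @return Scalar mean reward.
#' @export
mean_normalized_reward <- function(records) {
  x <- if (is.data.frame(records)) records$reward else records
  if (length(x) == 0) stop("no episode records")
  mean(x)
}

#' Choice optimality
#'
#' The fraction of episodes in which the agent obtained the maximum reward
#' achievable under the episode's goal condition.
#'
#' @param records A per-episode data.frame with either an `optimal` flag or
#'   both `reward` and `max_reward` columns.
#' @return Ratio in `[0, 1]`.
#' @export
choice_optimality <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("no episode records")
  if (!is.null(records$optimal)) return(mean(records$optimal))
  if (is.null(records$max_reward))
    stop("records need an `optimal` flag or a `max_reward` column")
  mean(records$reward >= records$max_reward - 1e-9)
}

#' Number of trials for success (sample-efficiency index)
#'
#' `NTS = R_max / N_env_interactions`: the maximum reward achieved divided by
#' the number of real environment interactions spent.
#'
#' @param r_max Maximum achieved reward.
#' @param n_interactions Positive count of real environment interactions.
#' @return Scalar index (higher is more sample-efficient).
#' @export
nts <- function(r_max, n_interactions) {
  if (!is.numeric(n_interactions) || n_interactions <= 0)
    stop("`n_interactions` must be positive")
  r_max / n_interactions
}

#' Exponentially smoothed episode-reward trace
#'
#' The "exponential reward": an exponentially weighted moving average of the
#' per-episode reward, `y_t = smoothing * y_{t-1} + (1 - smoothing) * r_t`,
#' initialised at the first episode's reward.
#'
#' @param rewards Numeric vector of per-episode rewards.
#' @param smoothing Smoothing factor in `[0, 1)` (default 0.99).
#' @return Numeric vector of the smoothed trace.
#' @export
smoothed_reward <- function(rewards, smoothing = 0.99) {
  stopifnot(smoothing >= 0, smoothing < 1, length(rewards) >= 1)
  y <- numeric(length(rewards))
  y[1] <- rewards[1]
  if (length(rewards) > 1)
    for (t in 2:length(rewards))
      y[t] <- smoothing * y[t - 1] + (1 - smoothing) * rewards[t]
  y
}
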