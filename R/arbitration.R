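## Arbitration between model-based and model-free control: prediction errors,
## reliability trackers, P_MB dynamics and Q-value integration.

#' Temporal-difference reward prediction error
#'
#' Computes the reward prediction error (RPE) of the model-free learner,
#' `r + gamma * q_next - q_curr`.
#'
#' @param r Received reward.
#' @param q_next Value of the successor state-action (0 at terminals).
#' @param q_curr Value of the current state-action.
#' @param gamma Discount factor in `[0, 1)`.
#' @return Signed prediction error.
#' @examples
#' compute_rpe(0.5, q_next = 0.5, q_curr = 0.2, gamma = 0.9)  # 0.75
#' @export
compute_rpe <- function(r, q_next, q_curr, gamma) {
  stopifnot(is.numeric(gamma), gamma >= 0, gamma < 1)
  cpp_compute_rpe(r, q_next, q_curr, gamma)
}

#' State prediction error in discrete state spaces
#'
#' The surprise about an observed transition under the learned transition
#' model: `1 - T(s, a, s')`.
#'
#' @param t_val Estimated probability of the observed transition, in `[0, 1]`.
#' @return SPE in `[0, 1]`.
#' @export
compute_spe_discrete <- function(t_val) {
  if (!is.numeric(t_val) || any(t_val < 0 | t_val > 1))
    stop("`t_val` must be a transition probability in [0, 1]")
  1 - t_val
}

#' State prediction error from a mixture prediction
#'
#' In continuous state spaces the world model emits a Gaussian mixture over the
#' next state. The default `"zscore"` mode measures the deviation of the
#' observed next state from the dominant mixture component in units of its
#' scale: `mean_d |obs_d - mu_d| / sigma_d`, which is 0 for a perfect
#' prediction and grows with surprise. The `"mu_over_sigma"` mode returns the
#' literal ratio `mean_d mu_d / sigma_d` of the dominant component.
#'
#' @param observation Observed next-state vector.
#' @param prediction A [gmm_prediction()].
#' @param mode `"zscore"` (default) or `"mu_over_sigma"`.
#' @return Non-negative SPE.
#' @export
compute_spe_gmm <- function(observation, prediction,
                            mode = c("zscore", "mu_over_sigma")) {
  mode <- match.arg(mode)
  stopifnot(inherits(prediction, "gmm_prediction"))
  k <- which.max(prediction$weights)
  mu <- prediction$means[, k]
  sigma <- prediction$scales[, k]
  if (any(sigma <= 0)) stop("all component scales must be positive")
  if (mode == "zscore") {
    if (length(observation) != length(mu))
      stop("dimension mismatch between observation and component mean")
    mean(abs(observation - mu) / sigma)
  } else {
    mean(mu / sigma)
  }
}

#' Classify a prediction error against the zero-band tolerance
#'
#' Signed errors below `-omega` are negative, above `omega` positive, and
#' anything inside the symmetric band `[-omega, omega]` counts as a zero
#' prediction error.
#'
#' @param spe Signed (or non-negative) prediction error.
#' @param omega Zero-band tolerance, `>= 0`.
#' @return One of `"negative"`, `"zero"`, `"positive"`.
#' @export
classify_spe <- function(spe, omega) {
  stopifnot(omega >= 0)
  c("negative", "zero", "positive")[cpp_classify_pe(spe, omega) + 1L]
}

#' Pearce-Hall reliability tracker for the model-free system
#'
#' Tracks a running mean of absolute RPEs (the "associability") and maps it
#' linearly to a reliability in `[0, 1]`:
#' `assoc <- (1 - eta) * assoc + eta * |RPE|`,
#' `Rel_MF = clamp(1 - assoc / rpe_max, 0, 1)`.
#'
#' @param eta Tracker learning rate in `(0, 1]`.
#' @param rpe_max Normalisation bound (reward units, > 0).
#' @param assoc0 Initial associability (>= 0).
#' @return An object of class `"ph_tracker"`.
#' @export
pearce_hall_tracker <- function(eta = 0.2, rpe_max = 1, assoc0 = 0) {
  stopifnot(eta > 0, eta <= 1, rpe_max > 0, assoc0 >= 0)
  structure(list(assoc = assoc0, eta = eta, rpe_max = rpe_max,
                 rel_mf = min(1, max(0, 1 - assoc0 / rpe_max))),
            class = "ph_tracker")
}

#' Update the model-free reliability from a reward prediction error
#'
#' @param tracker A [pearce_hall_tracker()].
#' @param rpe Signed reward prediction error.
#' @return The updated tracker; the current reliability is `tracker$rel_mf`.
#' @export
update_rel_mf <- function(tracker, rpe) {
  stopifnot(inherits(tracker, "ph_tracker"))
  upd <- cpp_ph_update(tracker$assoc, tracker$eta, rpe, tracker$rpe_max)
  tracker$assoc <- upd$assoc
  tracker$rel_mf <- upd$rel_mf
  tracker
}

#' Dirichlet reliability tracker for the model-based system
#'
#' Maintains pseudo-counts over the three SPE categories (negative, zero,
#' positive). The model-based reliability is the posterior mean of the
#' zero-error category, `E(Dir_zero) = (c_zero + prior) / (sum(c) + 3 prior)`;
#' an optional variance-penalised variant subtracts `sqrt(V(Dir_zero))`.
#' `decay < 1` forgets old evidence exponentially so the reliability can track
#' non-stationary environments; `decay = 1` is the plain conjugate posterior.
#'
#' @param prior Per-category prior pseudo-count (> 0).
#' @param decay Forgetting factor in `(0, 1]`.
#' @return An object of class `"dirichlet_tracker"`.
#' @export
dirichlet_tracker <- function(prior = 1, decay = 1) {
  stopifnot(prior > 0, decay > 0, decay <= 1)
  structure(list(counts = c(negative = 0, zero = 0, positive = 0),
                 prior = prior, decay = decay,
                 rel_mb = 1 / 3, var_zero = NA_real_),
            class = "dirichlet_tracker")
}

#' Update the model-based reliability from an SPE category
#'
#' @param tracker A [dirichlet_tracker()].
#' @param category `"negative"`, `"zero"` or `"positive"` (see
#'   [classify_spe()]).
#' @param variance_penalty If `TRUE`, report
#'   `E(Dir_zero) - sqrt(V(Dir_zero))` instead of the posterior mean.
#' @return The updated tracker; the reliability is `tracker$rel_mb`.
#' @export
update_rel_mb <- function(tracker, category, variance_penalty = FALSE) {
  stopifnot(inherits(tracker, "dirichlet_tracker"))
  cat_i <- match(match.arg(category, c("negative", "zero", "positive")),
                 c("negative", "zero", "positive")) - 1L
  upd <- cpp_dir_update(unname(tracker$counts), tracker$prior, cat_i,
                        tracker$decay)
  tracker$counts <- setNames(upd$counts, c("negative", "zero", "positive"))
  tracker$var_zero <- upd$var_zero
  rel <- upd$mean_zero
  if (variance_penalty) rel <- max(0, rel - sqrt(upd$var_zero))
  tracker$rel_mb <- rel
  tracker
}

#' Arbitration parameters
#'
#' Parameters of the P_MB dynamics
#' `alpha = A_alpha / (1 + exp(B_alpha * Rel_MF))`,
#' `beta  = A_beta  / (1 + exp(B_beta  * Rel_MB))`,
#' `P_MB <- P_MB + alpha * (1 - P_MB) - beta * P_MB`.
#' With `A_alpha, A_beta` in `(0, 1]` the update cannot leave `[0, 1]`.
#'
#' @param A_alpha,A_beta Transition-rate gains in `(0, 1]`.
#' @param B_alpha,B_beta Reliability slopes (>= 0 for the intended
#'   monotonicity: a more reliable MF system slows the MF-to-MB drift).
#' @param omega Zero-band tolerance used by [classify_spe()].
#' @param gamma MDP discount factor in `[0, 1)`.
#' @return An object of class `"arbitration_params"`.
#' @export
arbitration_params <- function(A_alpha = 0.3, B_alpha = 3, A_beta = 0.3,
                               B_beta = 3, omega = 0.2, gamma = 0.9) {
  stopifnot(A_alpha > 0, A_alpha <= 1, A_beta > 0, A_beta <= 1,
            omega >= 0, gamma >= 0, gamma < 1)
  structure(list(A_alpha = A_alpha, B_alpha = B_alpha, A_beta = A_beta,
                 B_beta = B_beta, omega = omega, gamma = gamma),
            class = "arbitration_params")
}

#' Live state of the arbitrator
#'
#' @param rel_mf,rel_mb,p_mb Initial values in `[0, 1]`.
#' @return An object of class `"arbitration_state"`.
#' @export
arbitration_state <- function(rel_mf = 1, rel_mb = 1 / 3, p_mb = 0.5) {
  stopifnot(rel_mf >= 0, rel_mf <= 1, rel_mb >= 0, rel_mb <= 1,
            p_mb >= 0, p_mb <= 1)
  structure(list(rel_mf = rel_mf, rel_mb = rel_mb, p_mb = p_mb),
            class = "arbitration_state")
}

#' One step of the P_MB dynamics
#'
#' @param state An [arbitration_state()].
#' @param params An [arbitration_params()].
#' @return The state with `p_mb` advanced by one update (clamped to `[0, 1]`).
#' @export
update_p_mb <- function(state, params) {
  stopifnot(inherits(state, "arbitration_state"),
            inherits(params, "arbitration_params"))
  state$p_mb <- cpp_pmb_update(state$p_mb, state$rel_mf, state$rel_mb,
                               params$A_alpha, params$B_alpha,
                               params$A_beta, params$B_beta)
  state
}

#' Integrate model-based and model-free values
#'
#' The convex combination `p_mb * q_mb + (1 - p_mb) * q_mf`, applied
#' elementwise (tables or network outputs alike).
#'
#' @param q_mb,q_mf Values (scalars, vectors or matrices of equal shape).
#' @param p_mb Probability of model-based control in `[0, 1]`.
#' @return Integrated values, bounded by the two inputs elementwise.
#' @export
integrate_q <- function(q_mb, q_mf, p_mb) {
  if (!is.numeric(p_mb) || p_mb < 0 || p_mb > 1)
    stop("`p_mb` must be a probability in [0, 1]")
  p_mb * q_mb + (1 - p_mb) * q_mf
}

#' @export
print.ph_tracker <- function(x, ...) {
  cat(sprintf("Pearce-Hall tracker: assoc = %.4f, eta = %.2f, Rel_MF = %.4f\n",
              x$assoc, x$eta, x$rel_mf))
  invisible(x)
}

#' @export
print.dirichlet_tracker <- function(x, ...) {
  cat(sprintf(
    "Dirichlet tracker: counts (n/z/p) = %.1f/%.1f/%.1f, Rel_MB = %.4f\n",
    x$counts[1], x$counts[2], x$counts[3], x$rel_mb))
  invisible(x)
}
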