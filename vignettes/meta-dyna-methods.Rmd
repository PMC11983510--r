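---
title: "Meta-control reinforcement learning with mental simulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-control reinforcement learning with mental simulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadyna)
```

## The model

`metadyna` implements a reinforcement-learning agent that maintains two value
systems and arbitrates between them the way prefrontal meta-control is
thought to: a *model-free* (MF) system that learns habitual values from real
experience by temporal-difference updates, and a *model-based* (MB) system
that learns goal-directed values from *simulated* experience generated by a
learned world model. Control is shared through a single scalar, the
probability of model-based control $P_{MB}$, and the behavioural values are
the convex combination

$$Q(s,a) = P_{MB}\, Q_{MB}(s,a) + (1 - P_{MB})\, Q_{MF}(s,a),$$

with an $\varepsilon$-greedy policy on $Q$. The same combination applies
elementwise to tables and to network outputs; we deliberately integrate
*outputs*, never parameters, because averaging the weights of independently
trained networks has no well-defined semantics.

### Reliability tracking

Each system's influence follows the reliability of its own prediction
errors.

* **MF reliability** uses the reward prediction error
  $\delta = r + \gamma Q_{MF}(s',a') - Q_{MF}(s,a)$ through a Pearce–Hall
  associability: a running mean of $|\delta|$,
  $\bar a \leftarrow (1-\eta)\bar a + \eta |\delta|$, mapped linearly to
  $\mathrm{Rel}_{MF} = \mathrm{clip}(1 - \bar a / \delta_{\max}, 0, 1)$.
  Only the associability *form* is canonical; the linear map to $[0,1]$ is
  our choice and requires a reward-scale bound $\delta_{\max}$ (default 1,
  matching the tasks' normalized rewards).
* **MB reliability** uses the state prediction error (SPE). In discrete
  tasks $\mathrm{SPE} = 1 - T(s,a,s')$, the learned improbability of the
  observed transition. In continuous tasks the world model emits a Gaussian
  mixture over the next state and the default SPE is the z-scored deviation
  of the observation from the dominant component,
  $\frac{1}{D}\sum_d |o_d - \mu_d| / \sigma_d$. A literal
  $\mu/\sigma$-ratio mode is also shipped (`compute_spe_gmm(mode =
  "mu_over_sigma")`) because the two readings cannot be reconciled: a wider
  $\sigma$ means *more* uncertainty, yet the ratio *decreases* with
  $\sigma$. The z-score mode is the default precisely because it grows with
  surprise; the ratio mode is retained for comparison only.
  SPEs are classified against a symmetric zero band: $|PE| \le \omega$
  counts as a *zero* error, beyond the band as *positive* (or *negative*
  for signed errors; the discrete SPE is non-negative, so its negative
  category stays empty by construction). A Dirichlet tracker accumulates
  pseudo-counts over the three categories and
  $\mathrm{Rel}_{MB} = E(\mathrm{Dir}_{zero})$, the posterior mean of the
  zero-error category; a variance-penalised variant
  $E - \sqrt{V}$ sits behind a flag.

The zero band is applied to the absolute error because the text that the
categorisation follows is self-contradictory about one-sided readings; the
symmetric band is the only reading under which the three categories
partition the real line.

### $P_{MB}$ dynamics

$$\alpha = \frac{A_\alpha}{1 + e^{B_\alpha \mathrm{Rel}_{MF}}},\qquad
  \beta = \frac{A_\beta}{1 + e^{B_\beta \mathrm{Rel}_{MB}}},\qquad
  P_{MB} \leftarrow P_{MB} + \alpha (1 - P_{MB}) - \beta P_{MB}.$$

An unreliable MF system accelerates the drift toward MB control and vice
versa. With $A_\alpha, A_\beta \in (0,1]$ the update provably stays in
$[0,1]$; we clamp after every update anyway so that misconfigured gains
degrade gracefully instead of leaving the unit interval. The update runs
once per episode, after both reliabilities have absorbed the episode's
prediction errors.

### Mental simulation

After each episode the agent runs $n$ simulated transitions (default
$n = 10$): chains start at the episode's start state (configurable to
uniformly remembered states via `sim_start = "visited"`), choose actions
$\varepsilon$-greedily on the integrated values with a *simulation*
exploration rate `sim_epsilon`, sample successors and rewards from the
world model, and stop at predicted terminals. Each chain is then replayed
in *reverse* order into $Q_{MB}$ — the analogue of hippocampal reverse
replay — so that a single chain propagates terminal reward all the way back
to its start. Two properties are enforced: a world model that has never
seen a real transition produces an empty rollout (simulated experience is
never fabricated), and simulated transitions train only $Q_{MB}$, never
$Q_{MF}$ (asserted by provenance flags in the test suite).

Simulated transitions are also appended to the world-model buffer, whose
training set is therefore a superset of real experience; a
`wm_train_on_sim = FALSE` switch restricts model training to real
transitions (measured effects of the superset were small in both
directions, so the superset is the default).

An expectation-style planning backup (TD target through the model's full
successor distribution rather than the sampled successor) is available as
`planning_backup = "expected"`; sampled backups with reverse replay
measured better on the dynamic two-stage task and remain the default.

### World models

*Tabular.* Per state–action transition rows learn by the two-branch rule —
matched successor $t \leftarrow t + \gamma_t (1 - t)$, all others
$t \leftarrow t(1-\gamma_t)$, row renormalised — which we read as
"the row's successor matches the observation"; the literal alternative
(comparing two probabilities for equality) is degenerate. The step size
$\gamma_t$ is a *model* step size, deliberately distinct from the MDP
discount $\gamma$. With fixed $\gamma_t$ the rows track non-stationary
dynamics; with `gamma_t = NA` the step decays as $1/n$ and the rows
converge to empirical frequencies (used by the parameter-recovery tests).
The reward estimate is an exponentially weighted running mean with step
`r_step`; a cumulative $1/n$ mean cannot track tasks whose rewards are
relocated every 125 episodes, which these benchmarks do by design.

*Recurrent mixture-density network.* For vector observations the world
model is a single-layer gated recurrent network whose head parameterises a
diagonal-covariance Gaussian mixture over the next state
($K = 5$ components by default), a Gaussian reward and a Bernoulli
terminal flag. The terminal head is an addition of ours: rollouts must
stop at episode ends, and nothing else in the architecture carries that
information. Inputs per step are the state, a one-hot action and the
previous step's SPE and RPE, so the model consumes its own errors.
Training is backpropagation through time over episode-ordered sequences
(hidden state reset at episode starts; shuffled input is rejected), with
Adam and global gradient-norm clipping at 5. Log-scales are clamped to
$[-4, 3]$ before exponentiation. Sampling applies the temperature to the
mixture-weight logits and scales $\sigma$ by $\sqrt{\tau}$; $\tau = 1$
(no distortion) is the default. The analytic gradients are verified
against finite differences in the test suite.

## Agents

The registry (`list_agents()`) covers the meta-control agent and every
baseline: `q-learning`, `sarsa` (on-policy TD), `forward` (pure MB:
per-step model learning plus one value-iteration sweep per episode),
`dyna-q` (single value table, learned model, $n$ planning updates from
randomly revisited state–actions), `meta-dyna`, the hybrids
`forward+sarsa` and `forward+qlearning` (value-iteration MB values under
the identical arbitration machinery), and `dqn` (replay buffer plus target
network) for the network backend. The meta-control agent trains $Q_{MF}$
per episode-batch by default, matching its canonical per-episode cadence;
an online per-step mode (`mf_per_step = TRUE`) is available and is used by
the equivalence tests, which check that the agent with $P_{MB}$ pinned to 0
and planning disabled reproduces plain Q-learning *step for step*, and
that $P_{MB}$ pinned to 1 with a learned model recovers the
dynamic-programming policy.

## The benchmark environments

All three environments are generated by the package itself; configuration
and a seed are the only inputs, and identical seeds give identical
trajectories (the compiled code draws exclusively from R's RNG).

* **Two-stage task** — binary root choice to one of two intermediate
  states, binary second choice to one of four terminal tokens; each stage
  takes the intended branch with probability $p$ (0.9 low / 0.5 high
  uncertainty) and the opposite branch otherwise. Stage-1 steps pay
  nothing. Flexible goals pay the token values $\{0, 1/4, 1/2, 1\}$;
  specific goals pay 1 for one required token. The protocol interleaves
  five 1,000-episode blocks: 500 low-uncertainty episodes with the goal
  condition resampled uniformly every 125 episodes, then 500
  high-uncertainty episodes. Token values are attached in increasing order
  (state 2 holds tokens 1–2, state 3 tokens 3–4) and the target is held
  fixed within each 125-episode segment.
* **Gridworld adaptation protocol** — an 8×8 grid whose left and right
  edge columns are terminal reward zones (4 and 2 points; grid size and
  magnitudes are configuration keys). Two three-phase blocks at movement
  reliability 0.9 then 0.5: phase 1 rewards the left zone highest with
  uniform starts; phase 2 drops the left zone to 1 point — flipping the
  optimal policy — while starts are restricted next to the changed zone;
  phase 3 restores uniform starts. Per-phase budget is 3% of a
  3,000-episode baseline (both configurable), i.e. 90 episodes: the point
  of the benchmark is adaptation under severely limited sampling.
* **Single-point Pong** — a bespoke geometric simulator (84×84 field,
  20-pixel paddles, ball-tracking opponent with capped speed), not an
  emulation of the arcade original: episodes end at the first point. The
  deterministic configuration reflects the ball as a pure function of the
  contact offset; the stochastic configuration adds roughly ±15° of
  reflection jitter and executes the commanded paddle move with
  probability 0.9. Specific goals terminate at the first agent-paddle
  contact and pay 1 exactly when the contact lies in the scheduled quarter
  of the paddle; flexible goals pay +1/−1 at the first point. The
  configuration and goal are resampled every 1,000 agent decisions.
  Observations are the normalized 6-dimensional kinematic state; the
  environments expose the raw state so that frame rendering can be built
  on top, but the shipped agents consume the state vector.

### What the generators do and do not emulate

The environments reproduce the *structural* properties the agent is meant
to cope with — reward relocation on a fixed timetable, controlled
transition stochasticity, goal conditions that switch between graded and
all-or-nothing payoffs — under full experimenter control and exact
reproducibility. They do not emulate pixel observations, reaction-time
constraints, or the idiosyncrasies of the arcade Pong physics. Tests that
pass on them certify the learning and arbitration machinery under the
stated dynamics, not performance on raw-pixel tasks.

## Parameter defaults

Learning: `lr_mf = 0.1`, `gamma = 0.9`, `epsilon = 0.1` without decay.
Planning: `n_planning = 10`, `lr_mb = 0.4`, `sim_epsilon = 0.6`
(`0.2` in the gridworld preset, where simulation noise wastes the
10-transition budget on a 64-state space), chains restart at the episode
start state. Model: `gamma_t = 0.2`, `r_step = 0.4`. Arbitration:
`ph_eta = 0.2`, `rpe_max = 1`, `omega = 0.2` (discrete SPE scale),
`dir_prior = 1`, `dir_decay = 0.98`, `A_alpha = A_beta = 0.3`,
`B_alpha = 3`, `B_beta = 15`, `p_mb0 = 0.5`. Network backend:
hidden sizes 32 (64 on Pong), `K = 5`, Adam rates `lr_q = 3e-3`
(`lr_q_mb = 9e-3` for the purely-simulation-trained MB network, which can
afford larger steps on model-filtered data), `lr_wm = 3e-3`,
`omega = 0.5` on the z-scored SPE scale, `B_beta = 8`.

Two defaults deserve justification because they depart from the most
conservative choices. `lr_mb = 0.4` is four times the MF rate: $Q_{MB}$
sees only ten simulated transitions per episode, already smoothed through
the learned model, and at 0.1 it cannot track a reward layout that moves
every 125 episodes — the agent would carry a stale plan for most of each
segment. `dir_decay = 0.98` gives the Dirichlet tracker an effective
memory of roughly fifty transitions; without forgetting the posterior mean
converges to the long-run zero-SPE frequency (which the property tests
verify) and cannot follow the 500-episode uncertainty switches that the
arbitration exists to detect. The arbitration gains were calibrated so
that $P_{MB}$ rises into the 0.9 range within a few episodes of entering a
low-uncertainty phase and falls below 0.5 under high uncertainty, while
the remaining parameters were chosen once for adaptivity on the dynamic
schedule and left alone.

## Numerical choices and degenerate inputs

Ties in every argmax are broken uniformly at random through the session
RNG, so greedy policies are exchangeable across equal-valued actions and
reproducible under a seed. Never-visited state–action pairs predict a
uniform successor distribution with a `cold` flag and zero reward;
rollouts from an entirely cold model return empty. Transition rows are
renormalised after every update, and the suite asserts row sums of one
after arbitrary update sequences. $P_{MB}$ and both reliabilities are
clamped to $[0,1]$ after every update. Episode caps (2 steps on the
two-stage task, 100 on the grid, 600 on Pong) guarantee termination under
any policy.

## Evaluation metrics

Mean normalized reward (episode rewards averaged over episodes and seeds),
choice optimality (the fraction of episodes achieving the maximum
achievable reward, computed analytically per goal condition so no oracle
agent is needed), and trials-for-success
$\mathrm{NTS} = R_{\max} / N_{\text{interactions}}$, where $R_{\max}$ is
taken as the maximum of the exponentially smoothed (0.99) episode-reward
trace — the smoothed trace is our defined reading of an "exponential
reward", and the unsmoothed cumulative mean is always reported alongside.
Group comparisons use Welch's two-sample t-test on per-seed means.
`run_experiment()` writes `episodes.csv` and `summary.json`;
`report_experiment()` recomputes every summary from the CSV, and the tests
assert the round trip is lossless.

## Problem sizes

The shipped experiment presets run the full 5,000-episode two-stage
protocol (10 seeds tabular, 5 seeds network), ten iterations of the
six-phase gridworld protocol, and 1,000-episode Pong runs at 3 seeds with
the simulation-count sweep $n \in \{10, 20, 50, 100\}$. These sizes were
chosen so a complete evaluation runs in minutes on a single core while
keeping per-seed standard errors a fraction of the effect sizes of
interest.

## Known limitations

* On tasks where policy quality is irrelevant under high uncertainty
  (both stages stochastic at 0.5), arbitration cannot raise reward there;
  differences between agents then concentrate entirely in the
  low-uncertainty phases, compressing effect sizes between the
  model-based family members. A purely value-iteration MB baseline is a
  near-ceiling on such tasks, and the sampling-based planner approaches
  but does not exceed it.
* Network rollouts restart with a zero hidden state; the model's
  recurrent context from real experience is not carried into simulation.
* The world model for Pong is trained at desk scale; large simulation
  counts amplify residual model error rather than improving values
  monotonically.
* The DQN baseline consumes the low-dimensional state vector and is
  correspondingly strong; no convolutional pixel pathway is included.
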