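## Experiment presets, multi-seed runners, significance tests and result
## serialisation.

.PRESETS <- c("mdt", "loca", "pong", "pong-simcount")

#' Run a multi-seed experiment preset
#'
#' Executes one of the benchmark protocols for a set of agents across seeds,
#' computes the evaluation metrics and Welch two-sample t-tests against a
#' reference agent, and (optionally) writes `episodes.csv` and
#' `summary.json` to `out_dir`.
#'
#' Presets:
#' * `"mdt"`: the full two-stage MDT protocol (default 5,000 episodes: five
#'   1,000-episode blocks, each 500 low-uncertainty episodes with the goal
#'   condition resampled every 125 episodes followed by 500 high-uncertainty
#'   episodes). Tabular backend by default; `backend = "network"` runs the
#'   network variant (Meta-Dyna, Dyna-Q, DQN).
#' * `"loca"`: the gridworld adaptation protocol (two 3-phase blocks at
#'   intended-move probabilities 0.9 then 0.5; per-phase budget 3% of a
#'   3,000-episode baseline); each seed is one complete iteration.
#' * `"pong"`: stochastic Pong (default 1,000 episodes; deterministic and
#'   stochastic configurations alternating with the goal condition every
#'   1,000 timesteps).
#' * `"pong-simcount"`: Pong sweep over the mental-simulation count
#'   `n_planning` in `planning_steps` at a fixed episode budget.
#'
#' @param preset One of `"mdt"`, `"loca"`, `"pong"`, `"pong-simcount"`.
#' @param agents Agent names (preset default when `NULL`).
#' @param seeds Either a number of seeds (uses `1:seeds`) or an integer
#'   vector of seeds.
#' @param episodes Episodes per run (preset default when `NULL`).
#' @param config Named [agent_config()] overrides applied to every agent.
#' @param backend `"tabular"` or `"network"` (MDT only).
#' @param planning_steps Simulation counts swept by `"pong-simcount"`.
#' @param reference Reference agent for the pairwise t-tests.
#' @param out_dir Output directory (created), or `NULL` to skip writing.
#' @param verbose Print progress.
#' @return An object of class `"metadyna_summary"`; the raw per-episode log
#'   is in `$episodes`.
#' @export
run_experiment <- function(preset = .PRESETS, agents = NULL, seeds = 3,
                           episodes = NULL, config = list(),
                           backend = NULL, planning_steps = c(10, 20, 50, 100),
                           reference = "meta-dyna", out_dir = NULL,
                           verbose = FALSE) {
  preset <- match.arg(preset)
  if (length(seeds) == 1 && seeds >= 1) seeds <- seq_len(seeds)
  seeds <- as.integer(seeds)
  runs <- list()
  k <- 0L

  if (preset == "mdt") {
    backend <- backend %||% "tabular"
    agents <- agents %||% if (backend == "tabular")
      c("meta-dyna", "dyna-q", "q-learning", "forward")
    else c("meta-dyna", "dyna-q", "dqn")
    episodes <- episodes %||% 5000L
    cfg <- config
    for (seed in seeds) {
      set.seed(seed)
      sched <- mdt_schedule(n_episodes = episodes)
      for (ag in agents) {
        set.seed(seed)
        log <- run_mdt(ag, sched, cfg, backend = backend)
        log$seed <- seed
        runs[[k <- k + 1L]] <- log
        if (verbose) message(sprintf("mdt/%s seed %d done", ag, seed))
      }
    }
  } else if (preset == "loca") {
    agents <- agents %||% c("meta-dyna", "dyna-q", "sarsa", "forward",
                            "forward+sarsa", "forward+qlearning")
    # on the gridworld, concentrated mental simulation (low simulated
    # exploration) uses the 10-transition planning budget best
    if (!("sim_epsilon" %in% names(config))) config$sim_epsilon <- 0.2
    sched <- loca_schedule()
    for (seed in seeds) {
      for (ag in agents) {
        set.seed(seed)
        log <- run_loca(ag, sched, config)
        log$seed <- seed
        runs[[k <- k + 1L]] <- log
        if (verbose) message(sprintf("loca/%s seed %d done", ag, seed))
      }
    }
  } else if (preset == "pong") {
    agents <- agents %||% c("meta-dyna", "dyna-q", "dqn")
    episodes <- episodes %||% 1000L
    cfg <- .pong_config(config)
    for (seed in seeds) {
      for (ag in agents) {
        log <- run_pong(ag, n_episodes = episodes, config = cfg, seed = seed)
        log$seed <- seed
        log$n_planning <- cfg$n_planning %||% 10L
        runs[[k <- k + 1L]] <- log
        if (verbose) message(sprintf("pong/%s seed %d done", ag, seed))
      }
    }
  } else {  # pong-simcount
    agents <- agents %||% c("meta-dyna", "dyna-q")
    episodes <- episodes %||% 1000L
    for (n in planning_steps) {
      cfg <- .pong_config(config)
      cfg$n_planning <- as.integer(n)
      for (seed in seeds) {
        for (ag in agents) {
          log <- run_pong(ag, n_episodes = episodes, config = cfg, seed = seed)
          log$seed <- seed
          log$n_planning <- as.integer(n)
          runs[[k <- k + 1L]] <- log
          if (verbose) message(sprintf("pong-simcount/%s n=%d seed %d done",
                                       ag, n, seed))
        }
      }
    }
  }

  eps <- do.call(rbind, runs)
  out <- summarize_experiment(eps, preset = preset, reference = reference)
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

.pong_config <- function(config) {
  cfg <- config
  if (!("hidden_q" %in% names(cfg))) cfg$hidden_q <- 64L
  if (!("hidden_wm" %in% names(cfg))) cfg$hidden_wm <- 64L
  if (!("max_steps" %in% names(cfg))) cfg$max_steps <- 600L
  cfg
}

#' Summarise a per-episode experiment log
#'
#' Computes, per agent: the mean normalized reward (over episodes and seeds),
#' choice optimality, per-seed means and their across-seed variance, plus
#' Welch t-tests of the per-seed mean rewards against the reference agent.
#' LoCA logs additionally get per-phase average normalized returns and
#' trials-to-success; Pong logs get smoothed-reward and NTS summaries.
#'
#' @param episodes Per-episode data.frame (`agent`, `seed`, `reward`, ...).
#' @param preset Preset name recorded in the summary.
#' @param reference Reference agent for t-tests.
#' @return An object of class `"metadyna_summary"`.
#' @export
summarize_experiment <- function(episodes, preset = "custom",
                                 reference = "meta-dyna") {
  stopifnot(is.data.frame(episodes), nrow(episodes) > 0)
  agents <- unique(episodes$agent)
  per_seed <- aggregate(reward ~ agent + seed, episodes, mean)
  agent_stats <- lapply(agents, function(ag) {
    sub <- episodes[episodes$agent == ag, ]
    ps <- per_seed$reward[per_seed$agent == ag]
    list(agent = ag,
         mean_reward = mean_normalized_reward(sub),
         choice_optimality = choice_optimality(sub),
         seed_means = ps,
         var_across_seeds = if (length(ps) > 1) var(ps) else NA_real_,
         n_seeds = length(ps), n_episodes = nrow(sub))
  })
  names(agent_stats) <- agents

  tests <- list()
  if (reference %in% agents && length(agents) > 1) {
    ref <- per_seed$reward[per_seed$agent == reference]
    for (ag in setdiff(agents, reference)) {
      x <- per_seed$reward[per_seed$agent == ag]
      tests[[ag]] <- if (length(ref) > 1 && length(x) > 1) {
        tt <- t.test(ref, x)   # Welch by default
        list(comparison = paste(reference, "vs", ag),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value,
             mean_diff = mean(ref) - mean(x))
      } else list(comparison = paste(reference, "vs", ag),
                  t = NA_real_, df = NA_real_, p_value = NA_real_,
                  mean_diff = mean(ref) - mean(x))
    }
  }

  extras <- list()
  if (!is.null(episodes$phase_global)) {
    nr <- episodes$reward / episodes$max_reward
    phase_means <- aggregate(
      list(norm_return = nr),
      by = list(agent = episodes$agent, seed = episodes$seed,
                phase_global = episodes$phase_global), FUN = mean)
    extras$phase_returns <- phase_means
    # trials-to-success: first episode within the phase reaching the phase
    # optimum (budget + 1 when never reached)
    tts <- do.call(rbind, lapply(split(
      episodes, list(episodes$agent, episodes$seed, episodes$phase_global),
      drop = TRUE), function(sub) {
        hit <- which(sub$optimal == 1)
        data.frame(agent = sub$agent[1], seed = sub$seed[1],
                   phase_global = sub$phase_global[1],
                   trials_to_success = if (length(hit)) hit[1]
                                       else nrow(sub) + 1L)
      }))
    rownames(tts) <- NULL
    extras$trials_to_success <- tts
    # across-run (seed) variance of per-phase average normalized returns
    vars <- aggregate(norm_return ~ agent + phase_global, phase_means, var)
    extras$phase_return_variance <- aggregate(norm_return ~ agent, vars, mean)
    names(extras$phase_return_variance)[2] <- "variance"
  }
  if (!is.null(episodes$interactions)) {
    key <- c("agent", "seed",
             if (!is.null(episodes$n_planning)) "n_planning")
    sp <- split(episodes, episodes[key], drop = TRUE)
    nts_tab <- do.call(rbind, lapply(sp, function(sub) {
      sm <- smoothed_reward(sub$reward)
      data.frame(agent = sub$agent[1], seed = sub$seed[1],
                 n_planning = if (!is.null(sub$n_planning))
                   sub$n_planning[1] else NA_integer_,
                 r_max = max(sm),
                 interactions = max(sub$interactions),
                 nts = nts(max(sm), max(sub$interactions)),
                 final_smoothed = sm[length(sm)])
    }))
    rownames(nts_tab) <- NULL
    extras$nts <- nts_tab
  }

  structure(list(preset = preset, reference = reference,
                 agents = agent_stats, tests = tests, extras = extras,
                 episodes = episodes),
            class = "metadyna_summary")
}

#' @export
print.metadyna_summary <- function(x, ...) {
  cat(sprintf("metadyna experiment summary - preset '%s'\n", x$preset))
  for (ag in names(x$agents)) {
    s <- x$agents[[ag]]
    cat(sprintf("  %-20s mean reward %.4f  optimality %.4f  (%d seeds, %d episodes)\n",
                ag, s$mean_reward, s$choice_optimality, s$n_seeds,
                s$n_episodes))
  }
  if (length(x$tests)) {
    cat(sprintf("Welch t-tests vs '%s':\n", x$reference))
    for (ag in names(x$tests)) {
      tt <- x$tests[[ag]]
      cat(sprintf("  vs %-18s diff %+0.4f  t = %6.2f  p = %.3g\n", ag,
                  tt$mean_diff, tt$t, tt$p_value))
    }
  }
  invisible(x)
}

#' Write an experiment's episode log and summary to disk
#'
#' Writes `episodes.csv` (one row per episode) and `summary.json` (metrics,
#' t-tests and preset metadata, without the raw episodes).
#'
#' @param summary A [summarize_experiment()] result.
#' @param out_dir Output directory (created if missing).
#' @return The output directory, invisibly.
#' @export
write_experiment <- function(summary, out_dir) {
  stopifnot(inherits(summary, "metadyna_summary"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(summary$episodes, file.path(out_dir, "episodes.csv"),
            row.names = FALSE)
  slim <- summary[c("preset", "reference", "agents", "tests", "extras")]
  jsonlite::write_json(slim, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", dataframe = "columns")
  invisible(out_dir)
}

#' Recompute a summary from a written episode log
#'
#' Re-reads `episodes.csv` from a run directory, recomputes all metrics and
#' rewrites `summary.json`; used to verify that the summary round-trips
#' losslessly through the CSV.
#'
#' @param run_dir Directory written by [write_experiment()].
#' @param reference Reference agent for t-tests.
#' @return The recomputed `"metadyna_summary"`.
#' @export
report_experiment <- function(run_dir, reference = "meta-dyna") {
  f <- file.path(run_dir, "episodes.csv")
  if (!file.exists(f)) stop("no episodes.csv under ", run_dir)
  eps <- read.csv(f, stringsAsFactors = FALSE)
  out <- summarize_experiment(eps, preset = "report", reference = reference)
  write_experiment(out, run_dir)
  out
}

#' Read a plain-text configuration file
#'
#' YAML-style key/value files; every [agent_config()] default is a valid key.
#'
#' @param path File path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration file must contain key/value pairs")
  cfg
}
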