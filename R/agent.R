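#' Stimulus-to-drive rescaling
#'
#' Stimulus values (container fill fractions in \[0, 1\]) are mapped to
#' pool input intensities by the linear transformation
#' `lambda = alpha + beta * s`. A non-negative `beta` preserves the order
#' of the two stimuli; in the intended operating regime the resulting
#' drives are positive for the stimuli in use.
#'
#' @param alpha offset (drive units).
#' @param beta gain, in `[0, 0.1]`.
#' @return an object of class `rescale_params`.
#' @export
rescale_params <- function(alpha = -0.018, beta = 0.05) {
  stop_if_not_scalar(alpha, "alpha")
  stop_if_not_scalar(beta, "beta", 0, 0.1)
  structure(list(alpha = alpha, beta = beta), class = "rescale_params")
}

#' Rescale stimulus values to drives
#'
#' @param s stimulus value(s) in \[0, 1\].
#' @param rescale a [rescale_params()].
#' @return drive intensities `alpha + beta * s`.
#' @export
rescale_stimuli <- function(s, rescale = rescale_params()) {
  rescale$alpha + rescale$beta * s
}

#' Bundle a full three-layer agent
#'
#' @param neural a [neural_params()].
#' @param intention an [intention_params()].
#' @param learning a [learning_params()].
#' @param rescale a [rescale_params()].
#' @param rt_shift constant offset (ms) added to the decision time to form
#'   the reported RT, modelling anticipation of the GO signal (may be
#'   negative); 0 for synthetic agents, estimated when fitting.
#' @param final_reward terminal-reward rule; see [reward_signal()].
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(neural = neural_params(),
                         intention = intention_params(),
                         learning = learning_params(),
                         rescale = rescale_params(),
                         rt_shift = 0,
                         final_reward = c("gain", "half_delta")) {
  stopifnot(inherits(neural, "neural_params"),
            inherits(intention, "intention_params"),
            inherits(learning, "learning_params"),
            inherits(rescale, "rescale_params"))
  stop_if_not_scalar(rt_shift, "rt_shift")
  structure(list(neural = neural, intention = intention,
                 learning = learning, rescale = rescale,
                 rt_shift = rt_shift,
                 final_reward = match.arg(final_reward)),
            class = "agent_params")
}

# Expand a (possibly scalar) phi0 to one entry per within-episode position.
phi0_for_horizon <- function(agent, horizon) {
  phi0 <- agent$learning$phi0
  n <- horizon + 1L
  if (length(phi0) == 1L) phi0 <- rep(phi0, n)
  if (length(phi0) != n)
    stop(sprintf("phi0 has length %d but horizon %d needs %d positions",
                 length(phi0), horizon, n))
  phi0
}

# Shared assembly of a behavioral log from the C++ closed-loop simulator.
assemble_log <- function(sim, block, horizon, G, delta, big_left,
                         shown_first, session_episode_offset = 0L) {
  tr <- sim$trials
  per <- horizon + 1L
  sides <- c("left", "right")
  log <- data.frame(
    block = block, horizon = horizon,
    episode = tr$episode,
    session_episode = tr$episode + session_episode_offset,
    trial_in_episode = tr$trial_in_episode,
    delta = rep(delta, each = per), gain = G,
    M = tr$M, s_left = tr$s_left, s_right = tr$s_right,
    shown_first = shown_first,
    side_of_big = ifelse(big_left == 1L, "left", "right"),
    psi0 = tr$psi0, psi_tilde = tr$psi_tilde,
    chosen_side = ifelse(is.na(tr$chosen_left), NA_character_,
                         sides[2L - tr$chosen_left]),
    chosen_value = tr$chosen_value,
    choice_class = ifelse(is.na(tr$chosen_big), NA_character_,
                          ifelse(tr$chosen_big == 1L, "big", "small")),
    reward = tr$reward,
    decision_time = tr$decision_time, rt = tr$rt,
    no_decision = tr$no_decision == 1L,
    stringsAsFactors = FALSE)
  class(log) <- c("conseq_log", "data.frame")
  attr(log, "phi_path") <- list(sim$phi_path)
  names(attr(log, "phi_path")) <- as.character(block)
  log
}

#' Simulate a freshly generated block
#'
#' Samples `n_episodes` episodes for the given horizon from the task
#' configuration and runs the closed agent loop on them: at each trial the
#' strategy seeds the intention process, the intention gates the
#' mean-field race, the realized choice shifts the next trial's stimulus
#' mean, and the strategy is updated from the subjective reward. Trials in
#' which the race does not reach threshold before the response window
#' elapses are logged as no-decision trials: they trigger no strategy
#' update and the episode's mean chain continues unshifted.
#'
#' @param horizon episode depth of the block.
#' @param n_episodes number of episodes.
#' @param agent an [agent_params()].
#' @param cfg a [task_config()] (supplies G, difficulty levels, mean
#'   bounds).
#' @param fixed_psi optional 0 or 1: clamp the intended decision instead
#'   of running the intention process (used for perceptual-only
#'   simulations, e.g. when fitting reaction times).
#' @param block block index recorded in the log.
#' @return a `conseq_log` data frame, one row per trial, with the strategy
#'   trajectory (episode-by-position matrix) in attribute `"phi_path"`.
#' @export
simulate_block <- function(horizon, n_episodes, agent = agent_params(),
                           cfg = task_config(), fixed_psi = NULL,
                           block = 1L) {
  horizon <- as.integer(horizon)
  n_episodes <- as.integer(n_episodes)
  stopifnot(n_episodes >= 1)
  G <- horizon_gain(cfg, horizon)
  b <- mean_bounds(horizon, G, cfg$delta_max)
  delta <- cfg$delta_levels[sample.int(length(cfg$delta_levels), n_episodes,
                                       replace = TRUE)]
  M1 <- runif(n_episodes, b[1], b[2])
  n_tr <- n_episodes * (horizon + 1L)
  big_left <- as.integer(runif(n_tr) < 0.5)
  first_left <- as.integer(runif(n_tr) < 0.5)
  sim <- cpp_simulate_block(
    horizon, G, delta, M1, big_left, first_left,
    unclass(agent$neural), unclass(agent$intention),
    agent$learning$k, phi0_for_horizon(agent, horizon),
    agent$rescale$alpha, agent$rescale$beta, agent$rt_shift,
    if (agent$final_reward == "gain") 1L else 2L,
    if (is.null(fixed_psi)) -1L else as.integer(fixed_psi))
  assemble_log(sim, block, horizon, G, delta, big_left,
               ifelse(first_left == 1L, "left", "right"))
}

#' Run an agent on one planned block
#'
#' Like [simulate_block()], but uses the episodes (difficulties, base
#' means, side/order coin flips) pre-sampled in a [build_session()] plan,
#' so the behavioral log is replayable from the plan's seed.
#'
#' @param plan a `session_plan`.
#' @param block block number within the plan.
#' @param agent an [agent_params()].
#' @return a `conseq_log` for that block.
#' @export
run_block <- function(plan, block, agent = agent_params()) {
  stopifnot(inherits(plan, "session_plan"))
  tr <- plan$trials[plan$trials$block == block, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no such block in the plan: ", block)
  horizon <- tr$horizon[1]
  G <- tr$gain[1]
  first <- tr$trial_in_episode == 1L
  sim <- cpp_simulate_block(
    horizon, G, tr$delta[first], tr$M1[first],
    as.integer(tr$side_of_big == "left"),
    as.integer(tr$shown_first == "left"),
    unclass(agent$neural), unclass(agent$intention),
    agent$learning$k, phi0_for_horizon(agent, horizon),
    agent$rescale$alpha, agent$rescale$beta, agent$rt_shift,
    if (agent$final_reward == "gain") 1L else 2L, -1L)
  assemble_log(sim, block, horizon, G, tr$delta[first],
               as.integer(tr$side_of_big == "left"), tr$shown_first,
               session_episode_offset = tr$session_episode[1] - 1L)
}

#' Run an agent over a whole session
#'
#' Blocks are executed in the plan's order; the strategy vector is
#' re-initialized from the agent's `phi0` at every block boundary (the
#' initial bias is a per-block quantity).
#'
#' @inheritParams run_block
#' @return a `conseq_log` covering every block, with one strategy
#'   trajectory per block in attribute `"phi_path"`.
#' @export
run_session <- function(plan, agent = agent_params()) {
  stopifnot(inherits(plan, "session_plan"))
  logs <- lapply(plan$blocks$block, run_block, plan = plan, agent = agent)
  out <- do.call(rbind, lapply(logs, as.data.frame))
  class(out) <- c("conseq_log", "data.frame")
  attr(out, "phi_path") <- do.call(c, lapply(logs, attr, "phi_path"))
  out
}

#' Parameter-space sweep
#'
#' Crosses the supplied parameter grids, simulates `reps` fresh blocks per
#' cell and tabulates reaction-time and learning summaries, suitable for
#' heat-map style summaries of how the time constant, threshold and noise
#' shape RT, and how the learning rate and decisional uncertainty shape
#' the learning time.
#'
#' @param grid named list of parameter value vectors; recognized names:
#'   `tau`, `sigma`, `delta_thr` (neural), `sigma_psi` (intention), `k`
#'   (learning), `beta` (rescaling).
#' @param base agent whose remaining parameters are held fixed.
#' @param cfg task configuration.
#' @param horizon horizon of the simulated blocks.
#' @param n_episodes episodes per block.
#' @param reps blocks per grid cell.
#' @return data frame: one row per cell with `mean_rt`, `sd_rt`,
#'   `mean_t_l` (not-learned runs imputed at `n_episodes + 1`),
#'   `frac_learned` and `mean_pf`.
#' @export
sweep_parameter_space <- function(grid, base = agent_params(),
                                  cfg = task_config(), horizon = 1L,
                                  n_episodes = 50L, reps = 20L) {
  known <- c("tau", "sigma", "delta_thr", "sigma_psi", "k", "beta")
  if (is.null(names(grid)) || !all(names(grid) %in% known))
    stop("grid names must be among: ", paste(known, collapse = ", "))
  cells <- do.call(expand.grid, c(grid, KEEP.OUT.ATTRS = FALSE))
  out <- cells
  out$mean_rt <- out$sd_rt <- out$mean_t_l <- out$frac_learned <-
    out$mean_pf <- NA_real_
  for (i in seq_len(nrow(cells))) {
    a <- base
    for (p in names(cells)) {
      v <- cells[i, p]
      switch(p,
             tau = { a$neural$tau <- v },
             sigma = { a$neural$sigma <- v },
             delta_thr = { a$neural$delta_thr <- v },
             sigma_psi = { a$intention$sigma_psi <- v },
             k = { a$learning$k <- v },
             beta = { a$rescale$beta <- v })
    }
    rts <- numeric(0)
    tls <- pfs <- numeric(reps)
    for (r in seq_len(reps)) {
      log <- simulate_block(horizon, n_episodes, a, cfg)
      rts <- c(rts, log$rt[!log$no_decision])
      la <- learning_time(log)
      tls[r] <- if (is.na(la$t_L)) n_episodes + 1L else la$t_L
      pfs[r] <- mean(episode_performance(log)$PF)
    }
    out$mean_rt[i] <- mean(rts)
    out$sd_rt[i] <- sd(rts)
    out$mean_t_l[i] <- mean(tls)
    out$frac_learned[i] <- mean(tls <= n_episodes)
    out$mean_pf[i] <- mean(pfs)
  }
  out
}
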