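# Fixture builders shared across test files.  Everything is generated in
# code; no stored data.

# A hand-constructed behavioral log with fully specified choices, so the
# metric functions can be checked against hand arithmetic.  `choices` is a
# list with one character vector ("small"/"big"/NA) per episode; the mean
# chain and stimulus values follow the task rule (big always shown left,
# RTs default to 500 ms).
synthetic_log <- function(horizon, G, delta, M1, choices, block = 1L,
                          rt = 500, session_episode_offset = 0L) {
  n_per <- horizon + 1L
  delta <- rep_len(delta, length(choices))
  M1 <- rep_len(M1, length(choices))
  rows <- list()
  for (e in seq_along(choices)) {
    ch <- choices[[e]]
    stopifnot(length(ch) == n_per)
    M <- M1[e]
    for (te in seq_len(n_per)) {
      s_small <- M - delta[e] / 2
      s_big <- M + delta[e] / 2
      nd <- is.na(ch[te])
      rows[[length(rows) + 1L]] <- data.frame(
        block = block, horizon = horizon, episode = e,
        session_episode = e + session_episode_offset,
        trial_in_episode = te, delta = delta[e], gain = G, M = M,
        s_left = s_big, s_right = s_small, shown_first = "left",
        side_of_big = "left", psi0 = 0.5,
        psi_tilde = if (nd) NA_integer_ else as.integer(ch[te] == "big"),
        chosen_side = if (nd) NA_character_ else
          ifelse(ch[te] == "big", "left", "right"),
        chosen_value = if (nd) NA_real_ else
          ifelse(ch[te] == "big", s_big, s_small),
        choice_class = if (nd) NA_character_ else ch[te],
        reward = NA_real_, decision_time = rt, rt = rt,
        no_decision = nd, stringsAsFactors = FALSE)
      if (!nd && te < n_per)
        M <- M + if (ch[te] == "small") G else -G
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("conseq_log", "data.frame")
  out
}

# Repeat one choice pattern over n episodes.
rep_episodes <- function(pattern, n) rep(list(pattern), n)

# A small, fast agent for closed-loop tests.
test_agent <- function(k = 0.4, sigma_psi = 0.4, tau = 80, sigma = 0.006,
                       delta_thr = hz(25), beta = 0.05, phi0 = 0.5,
                       rt_shift = 0, final_reward = "gain") {
  agent_params(
    neural = neural_params(tau = tau, sigma = sigma, delta_thr = delta_thr),
    intention = intention_params(sigma_psi = sigma_psi),
    learning = learning_params(k = k, phi0 = phi0),
    rescale = rescale_params(beta = beta),
    rt_shift = rt_shift, final_reward = final_reward)
}

# Reference noiseless integrator for the mean-field equations, written
# independently of the package's C++ path (plain R, selectable step).
oracle_mf_crossing <- function(lambda_L, lambda_R, p, dt) {
  f <- function(x) p$f_max / (1 + exp(-(x - p$theta) / p$k_sig))
  rL <- rR <- 0
  t <- 0
  while (t < p$t_max) {
    dL <- (-rL + f(lambda_L + p$w_plus * rL - p$w_minus * rR)) / p$tau
    dR <- (-rR + f(lambda_R + p$w_plus * rR - p$w_minus * rL)) / p$tau
    rL <- rL + dt * dL
    rR <- rR + dt * dR
    t <- t + dt
    if (abs(rL - rR) > p$delta_thr)
      return(list(winner = if (rL > rR) "left" else "right", time = t))
  }
  list(winner = "none", time = NA_real_)
}
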