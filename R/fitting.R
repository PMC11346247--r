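#' Kolmogorov-Smirnov distance between two samples
#'
#' Sup-norm distance between the empirical CDFs, evaluated over the union
#' of the two samples' points; always in \[0, 1\].
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return the KS distance.
#' @examples
#' ksd(c(1, 2, 3), c(1, 2, 4))  # 1/3
#' @export
ksd <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty")
  x <- sort(unique(c(sample_a, sample_b)))
  max(abs(ecdf(sample_a)(x) - ecdf(sample_b)(x)))
}

#' Threshold tied to the time constant
#'
#' Reaction times depend on the time constant and the decision threshold
#' in a largely interchangeable way, so the fit explores that parameter
#' plane along one line, `delta_thr = 2.57e-4 * tau + 0.0076` (ms^-1).
#'
#' @param tau time constant (ms).
#' @return decision threshold (ms^-1).
#' @export
fitting_line_delta <- function(tau) 2.57e-4 * tau + 0.0076

# Default neural-layer noise used throughout the fitting pipeline: RT is
# insensitive to sigma over its plausible range, so it is held fixed.
FIT_SIGMA <- 0.001

# KS distance between two right-censored RT samples: trials that never
# reached a decision stay in the denominator, so each empirical CDF
# plateaus at its decided fraction and a model that times out far more
# (or less) often than the data pays for it directly.
ksd_censored <- function(a, n_a, b, n_b) {
  x <- sort(unique(c(a, b)))
  fa <- ecdf(a)(x) * length(a) / n_a
  fb <- ecdf(b)(x) * length(b) / n_b
  max(abs(fa - fb), abs(length(a) / n_a - length(b) / n_b))
}

fit_agent <- function(tau, beta, k = 0, phi0 = 0.5, sigma_psi = 0.6,
                      rt_shift = 0, sigma = FIT_SIGMA) {
  agent_params(
    neural = neural_params(tau = tau, sigma = sigma,
                           delta_thr = fitting_line_delta(tau)),
    intention = intention_params(sigma_psi = sigma_psi),
    learning = learning_params(k = k, phi0 = phi0),
    rescale = rescale_params(beta = beta),
    rt_shift = rt_shift)
}

#' Fit the perceptual layer to reaction times and visual discrimination
#'
#' Grid search over the time constant `tau` (threshold tied to it via
#' [fitting_line_delta()], noise fixed at 0.001 ms^-1) and the rescaling
#' gain `beta` (offset fixed at `alpha`). For every grid point a
#' horizon-0 block of `n_trials` trials is simulated with the intention
#' clamped at "big"; the simulated RT distribution is aligned to the
#' observed one by a median shift — the anticipation offset, constrained
#' to `shift_range` since anticipating (or reacting late to) a GO signal
#' is a sub-second affair — and compared
#' by KS distance between the two RT distributions, computed over all
#' trials (a trial without a decision keeps its mass at infinity, so a
#' model that times out more or less often than the data is penalized),
#' while the simulated visual discrimination at the
#' hardest difficulty (from `n_vd` dedicated race simulations) is
#' compared to the observed one. Both fit jointly through the composite
#' error `M = KSD + c_vd * |VD_sim - VD_obs|`; the grid argmin is
#' returned, ties broken toward the smallest `tau`, then `beta`. Should
#' the log lack usable hardest-difficulty trials (e.g. every such race
#' timed out), the VD term is dropped with a warning and the fit rests on
#' the RT distance alone.
#'
#' @param log a `conseq_log` with a horizon-0 block containing decided
#'   trials and trials at the hardest difficulty.
#' @param tau_grid,beta_grid grid values for `tau` (ms) and `beta`.
#' @param alpha fixed rescaling offset.
#' @param sigma fixed neural noise (ms^-1).
#' @param c_vd weight of the VD term in the composite error.
#' @param n_trials simulated horizon-0 trials per grid point (RT arm).
#' @param n_vd Monte-Carlo races per grid point (VD arm).
#' @param shift_range admissible anticipation window (ms) for the RT
#'   shift.
#' @param hardest difficulty level at which VD is measured.
#' @param cfg task configuration used for the simulated blocks.
#' @return a `neural_fit`: `tau`, `beta`, `delta_thr`, `rt_shift`,
#'   `m_hat`, `ksd`, `vd_sim`, `vd_obs`, and the full grid `surface`.
#' @export
fit_neural <- function(log, tau_grid = seq(25, 95, by = 2),
                       beta_grid = seq(0, 0.1, by = 0.005),
                       alpha = -0.018, sigma = FIT_SIGMA, c_vd = 0.4,
                       n_trials = 100, n_vd = 500, hardest = 0.01,
                       shift_range = c(-200, 200), cfg = task_config()) {
  h0 <- log[log$horizon == 0L, , drop = FALSE]
  rts <- h0$rt[!h0$no_decision & !is.na(h0$rt)]
  n_obs <- nrow(h0)
  if (length(rts) == 0L)
    stop("the log has no decided horizon-0 trials to fit RTs on")
  vd_obs <- suppressWarnings(visual_discrimination(log, hardest = hardest))
  if (is.na(vd_obs)) {
    warning("no usable hardest-difficulty trials in the log; ",
            "fitting on the RT distance alone")
    c_vd <- 0
    vd_obs <- NA_real_
  }

  surface <- expand.grid(tau = tau_grid, beta = beta_grid,
                         KEEP.OUT.ATTRS = FALSE)
  surface <- surface[order(surface$tau, surface$beta), , drop = FALSE]
  surface$ksd <- surface$vd_sim <- surface$shift <- surface$m_hat <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(surface))) {
    tau <- surface$tau[i]
    beta <- surface$beta[i]
    np <- neural_params(tau = tau, sigma = sigma,
                        delta_thr = fitting_line_delta(tau))
    rp <- rescale_params(alpha = alpha, beta = beta)
    sim <- simulate_block(0L, n_trials,
                          agent_params(neural = np, rescale = rp,
                                       learning = learning_params(k = 0)),
                          cfg, fixed_psi = 1L)
    dt_sim <- sim$decision_time[!sim$no_decision]
    if (length(dt_sim) == 0L) {
      surface$ksd[i] <- 1          # nothing ever crossed threshold
      surface$shift[i] <- NA_real_
      k_i <- 1
    } else {
      surface$shift[i] <- min(max(median(rts) - median(dt_sim),
                                  shift_range[1]), shift_range[2])
      k_i <- ksd_censored(dt_sim + surface$shift[i], nrow(sim),
                          rts, n_obs)
      surface$ksd[i] <- k_i
    }
    vd_i <- estimate_vd(hardest, np, rp, n_runs = n_vd)
    if (is.na(vd_i)) vd_i <- 0.5   # undiscriminating network
    surface$vd_sim[i] <- vd_i
    surface$m_hat[i] <- k_i +
      if (c_vd > 0) c_vd * abs(vd_i - vd_obs) else 0
    if (is.null(best) || surface$m_hat[i] < best$m_hat)
      best <- list(i = i, m_hat = surface$m_hat[i])
  }
  i <- best$i
  structure(list(tau = surface$tau[i], beta = surface$beta[i],
                 delta_thr = fitting_line_delta(surface$tau[i]),
                 rt_shift = surface$shift[i], sigma = sigma, alpha = alpha,
                 m_hat = surface$m_hat[i], ksd = surface$ksd[i],
                 vd_sim = surface$vd_sim[i], vd_obs = vd_obs,
                 surface = surface),
            class = "neural_fit")
}

#' @export
print.neural_fit <- function(x, ...) {
  cat(sprintf(paste0("perceptual-layer fit: tau = %g ms, beta = %g ",
                     "(delta_thr = %.4g ms^-1, rt shift = %.0f ms)\n",
                     "composite error M = %.3f (KSD %.3f, VD %.2f vs %.2f)\n"),
              x$tau, x$beta, x$delta_thr, x$rt_shift, x$m_hat, x$ksd,
              x$vd_sim, x$vd_obs))
  invisible(x)
}

#' Initial preferential bias from early episodes
#'
#' For each within-episode position, `f` is the frequency with which the
#' larger stimulus was selected over that position's first `n_episodes`
#' decided trials (on human-style logs without timeouts these are simply
#' the block's first `n_episodes` episodes). To keep the bias away from
#' the absorbing basins the frequency is rescaled toward 0.5, by default
#' `phi0 = (1 + f) / 3` (range \[1/3, 2/3\]).
#'
#' @param log a `conseq_log`.
#' @param block block to estimate from; defaults to the log's first
#'   block with horizon >= 1, or its first block.
#' @param n_episodes number of early episodes to use per position.
#' @param rescale_f rescaling applied to the raw frequency.
#' @return numeric vector of `phi0`, one per within-episode position.
#' @export
estimate_initial_bias <- function(log, block = NULL, n_episodes = 3,
                                  rescale_f = function(f) (1 + f) / 3) {
  if (is.null(block)) {
    cand <- unique(log$block[log$horizon >= 1L])
    block <- if (length(cand)) cand[1] else log$block[1]
  }
  b <- log[log$block == block, , drop = FALSE]
  b <- b[order(b$episode, b$trial_in_episode), , drop = FALSE]
  per <- b$horizon[1] + 1L
  f <- rep(NA_real_, per)
  for (te in seq_len(per)) {
    cls <- b$choice_class[b$trial_in_episode == te]
    cls <- cls[!is.na(cls)]
    if (length(cls) < n_episodes)
      stop(sprintf(
        "need at least %d decided trials at position %d of block %s",
        n_episodes, te, block))
    f[te] <- mean(head(cls, n_episodes) == "big")
  }
  rescale_f(f)
}

#' Fit the learning rate
#'
#' With the perceptual parameters and the initial bias fixed (and the
#' decisional uncertainty held at `sigma_psi`), the learning rate is the
#' grid value whose simulated performance trajectory best matches the
#' log's: for every `k` the block is re-simulated `reps` times and the
#' objective `L + 0.1 * I` is evaluated, where `L` is the absolute
#' difference between the log's learning time and the median simulated
#' one (not-learned runs imputed at one past the block length; the
#' median is insensitive to the imputed value while a minority of runs
#' fail to learn) and `I` is the
#' mean-square error of per-episode performance over the first
#' `n_initial` episodes. Ties break toward the smallest `k`.
#'
#' @param log a `conseq_log`.
#' @param block block to fit (default: first block with horizon >= 1).
#' @param tau,beta,rt_shift perceptual parameters, typically from
#'   [fit_neural()].
#' @param phi0 initial-bias vector, typically from
#'   [estimate_initial_bias()].
#' @param k_grid learning-rate grid.
#' @param reps simulations per grid value.
#' @param sigma_psi fixed decisional uncertainty.
#' @param n_initial episodes entering the initial-condition term `I`.
#' @param exclude_delta difficulty excluded from learning-time scoring.
#' @param cfg task configuration for the simulated blocks.
#' @return a `learning_fit`: `k`, `sigma_psi`, the objective `table`, the
#'   target learning time `t_L_obs` and the best `k`'s median simulated
#'   learning time `t_L_sim`.
#' @export
fit_learning_rate <- function(log, block = NULL, tau, beta, rt_shift = 0,
                              phi0, k_grid = seq(0, 2.5, by = 0.1),
                              reps = 50, sigma_psi = 0.6, n_initial = 5,
                              exclude_delta = 0.01, cfg = task_config()) {
  if (is.null(block)) {
    cand <- unique(log$block[log$horizon >= 1L])
    block <- if (length(cand)) cand[1] else log$block[1]
  }
  b <- log[log$block == block, , drop = FALSE]
  horizon <- b$horizon[1]
  perf <- episode_performance(b)
  n_ep <- nrow(perf)
  la <- learning_time(b, exclude_delta = exclude_delta)
  tl_obs <- if (la$learned) la$t_L_block else n_ep + 1L
  pf_obs <- perf$PF[seq_len(min(n_initial, n_ep))]

  tab <- data.frame(k = sort(k_grid), L = NA_real_, I = NA_real_,
                    objective = NA_real_, t_L_sim = NA_real_)
  best <- NULL
  for (i in seq_len(nrow(tab))) {
    agent <- fit_agent(tau, beta, k = tab$k[i], phi0 = phi0,
                       sigma_psi = sigma_psi, rt_shift = rt_shift)
    tls <- numeric(reps)
    pfm <- matrix(NA_real_, reps, length(pf_obs))
    for (r in seq_len(reps)) {
      sim <- simulate_block(horizon, n_ep, agent, cfg)
      sla <- learning_time(sim, exclude_delta = exclude_delta)
      tls[r] <- if (sla$learned) sla$t_L_block else n_ep + 1L
      pfm[r, ] <- episode_performance(sim)$PF[seq_along(pf_obs)]
    }
    tab$t_L_sim[i] <- median(tls)
    tab$L[i] <- abs(median(tls) - tl_obs)
    tab$I[i] <- mean((colMeans(pfm) - pf_obs)^2)
    tab$objective[i] <- tab$L[i] + 0.1 * tab$I[i]
    if (is.null(best) || tab$objective[i] < best$obj)
      best <- list(i = i, obj = tab$objective[i])
  }
  structure(list(k = tab$k[best$i], sigma_psi = sigma_psi,
                 objective = tab$objective[best$i],
                 t_L_obs = tl_obs, t_L_sim = tab$t_L_sim[best$i],
                 block = block, table = tab),
            class = "learning_fit")
}

#' Sequential three-step fit of a behavioral log
#'
#' Runs the full pipeline: (1) perceptual layer (`tau`, `beta`, RT shift)
#' from the horizon-0 block's reaction times and visual discrimination;
#' (2) initial bias `phi0` from the first episodes of the target block;
#' (3) learning rate `k` from the target block's performance trajectory.
#' Later steps never alter earlier estimates.
#'
#' @param log a `conseq_log` with a horizon-0 block and at least one
#'   block of horizon >= 1.
#' @param behavior_block block used for steps 2-3 (default: first block
#'   with horizon >= 1).
#' @param gf_reps simulations for the goodness-of-fit triple; set to 0 to
#'   skip it.
#' @param cfg task configuration.
#' @param ... passed to [fit_neural()] (grids, Monte-Carlo sizes) and
#'   `k_grid`/`reps`/`sigma_psi` to [fit_learning_rate()].
#' @inheritParams fit_neural
#' @inheritParams fit_learning_rate
#' @return a `conseq_fit`: the fitted `tau`, `beta`, `delta_thr`,
#'   `rt_shift`, `phi0`, `k`, the sub-fit objects, and (unless skipped)
#'   the goodness-of-fit triple `gf`.
#' @export
fit_model <- function(log, behavior_block = NULL,
                      tau_grid = seq(25, 95, by = 2),
                      beta_grid = seq(0, 0.1, by = 0.005),
                      n_trials = 100, n_vd = 500,
                      k_grid = seq(0, 2.5, by = 0.1),
                      reps = 50, sigma_psi = 0.6, gf_reps = 50,
                      cfg = task_config()) {
  nf <- fit_neural(log, tau_grid = tau_grid, beta_grid = beta_grid,
                   n_trials = n_trials, n_vd = n_vd, cfg = cfg)
  phi0 <- estimate_initial_bias(log, block = behavior_block)
  lf <- fit_learning_rate(log, block = behavior_block, tau = nf$tau,
                          beta = nf$beta, rt_shift = nf$rt_shift,
                          phi0 = phi0, k_grid = k_grid, reps = reps,
                          sigma_psi = sigma_psi, cfg = cfg)
  fit <- structure(list(tau = nf$tau, beta = nf$beta,
                        delta_thr = nf$delta_thr, rt_shift = nf$rt_shift,
                        phi0 = phi0, k = lf$k, sigma_psi = sigma_psi,
                        neural_fit = nf, learning_fit = lf,
                        block = lf$block, gf = NULL),
                   class = "conseq_fit")
  if (gf_reps > 0)
    fit$gf <- goodness_of_fit(log, fit, reps = gf_reps, cfg = cfg)
  fit
}

#' @export
print.conseq_fit <- function(x, ...) {
  cat(sprintf("sequential model fit (block %s):\n", x$block))
  cat(sprintf("  tau = %g ms, beta = %g, rt shift = %.0f ms\n", x$tau,
              x$beta, x$rt_shift))
  cat(sprintf("  phi0 = {%s}, k = %g (sigma_psi fixed at %g)\n",
              paste(sprintf("%.2f", x$phi0), collapse = ", "), x$k,
              x$sigma_psi))
  if (!is.null(x$gf))
    cat(sprintf("  goodness of fit (RT, PF_i, t_L) = {%.2f, %.2f, %.2f}\n",
                x$gf["RT"], x$gf["PF_i"], x$gf["t_L"]))
  invisible(x)
}

#' Goodness-of-fit triple
#'
#' Simulates the fitted block `reps` times with the fitted parameters and
#' scores, each clamped to \[0, 1\]: `RT = 1 - KSD` between the observed
#' and simulated reaction-time CDFs; `PF_i = 1 -` mean-square error of
#' per-episode performance over the first five episodes (model mean vs
#' observed); `t_L = 1 -` the absolute difference between the observed
#' learning time and the model's mean, divided by the number of episodes.
#'
#' @param log a `conseq_log`.
#' @param fit a `conseq_fit` (or any list with `tau`, `beta`, `rt_shift`,
#'   `phi0`, `k`, `sigma_psi`, `block`).
#' @param reps number of simulations.
#' @param n_initial episodes entering the `PF_i` term.
#' @param exclude_delta difficulty excluded from learning-time scoring.
#' @param cfg task configuration.
#' @return named numeric triple `c(RT, PF_i, t_L)`.
#' @export
goodness_of_fit <- function(log, fit, reps = 50, n_initial = 5,
                            exclude_delta = 0.01, cfg = task_config()) {
  b <- log[log$block == fit$block, , drop = FALSE]
  horizon <- b$horizon[1]
  perf <- episode_performance(b)
  n_ep <- nrow(perf)
  la <- learning_time(b, exclude_delta = exclude_delta)
  tl_obs <- if (la$learned) la$t_L_block else n_ep + 1L
  pf_obs <- perf$PF[seq_len(min(n_initial, n_ep))]
  rts_obs <- b$rt[!b$no_decision & !is.na(b$rt)]

  agent <- fit_agent(fit$tau, fit$beta, k = fit$k, phi0 = fit$phi0,
                     sigma_psi = fit$sigma_psi, rt_shift = fit$rt_shift)
  rts_sim <- numeric(0)
  tls <- numeric(reps)
  pfm <- matrix(NA_real_, reps, length(pf_obs))
  for (r in seq_len(reps)) {
    sim <- simulate_block(horizon, n_ep, agent, cfg)
    rts_sim <- c(rts_sim, sim$rt[!sim$no_decision])
    sla <- learning_time(sim, exclude_delta = exclude_delta)
    tls[r] <- if (sla$learned) sla$t_L_block else n_ep + 1L
    pfm[r, ] <- episode_performance(sim)$PF[seq_along(pf_obs)]
  }
  c(RT = clamp01(1 - ksd(rts_sim, rts_obs)),
    PF_i = clamp01(1 - mean((colMeans(pfm) - pf_obs)^2)),
    t_L = clamp01(1 - abs(mean(tls) - tl_obs) / n_ep))
}
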