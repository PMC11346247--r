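#' Simulate-then-refit parameter recovery
#'
#' Validates the sequential fitting pipeline on synthetic ground truth:
#' `n_agents` agents are drawn from uniform priors over the fitting
#' ranges, each simulates one horizon-0 block (for the perceptual fit)
#' and one deeper-horizon block (for the bias and learning-rate fits),
#' and the full three-step fit is run on every synthetic log. The
#' generating agents share the fitting pipeline's structural constraints
#' (threshold on the [fitting_line_delta()] line, neural noise and
#' decisional uncertainty fixed), so each parameter is identified by the
#' same evidence the fit uses.
#'
#' The default grids and Monte-Carlo sizes are coarser than
#' [fit_neural()]'s defaults; recovery quality is assessed by
#' correlation, which tolerates grid resolution.
#'
#' @param n_agents number of synthetic agents.
#' @param tau_range,beta_range,k_range,phi0_range uniform prior ranges.
#'   The defaults stay inside the network's workable regime — drives near
#'   the sigmoid's sensitive range and races fast enough to finish within
#'   the response window — which is also where the reference fits to
#'   human data landed; outside it most trials time out and a single
#'   block carries little information about the parameters. The
#'   `phi0_range` default leans toward the larger stimulus, the a-priori
#'   preference participants actually show; an agent that starts with the
#'   first-trial preference already below 0.5 behaves optimally almost
#'   immediately, its learning time saturates at one or two episodes, and
#'   the learning rate becomes unidentifiable from a single block.
#' @param horizon horizon of the behavioral block.
#' @param n_episodes episodes of the behavioral block.
#' @param n_h0_trials trials of the horizon-0 block.
#' @param tau_grid,beta_grid,k_grid fitting grids.
#' @param n_fit_trials simulated horizon-0 trials per grid point in the
#'   perceptual fit (a larger value than the observed block smooths the
#'   fit's KS surface).
#' @param n_vd Monte-Carlo races per grid point for the VD arm.
#' @param reps simulations per `k` grid value.
#' @param sigma_psi decisional uncertainty (generation and fit).
#' @param cfg task configuration.
#' @return a `recovery_result`: data frame `agents` with true and
#'   recovered values, plus `correlations` and mean `bias` per parameter,
#'   and `n_redrawn`, the number of discarded draws whose synthetic
#'   sessions could not support the fit (excluded like unusable
#'   participants).
#' @export
parameter_recovery <- function(n_agents = 20,
                               tau_range = c(30, 85),
                               beta_range = c(0.04, 0.062),
                               k_range = c(0.2, 2.4),
                               phi0_range = c(0.5, 0.65),
                               horizon = 1L, n_episodes = 50L,
                               n_h0_trials = 200L,
                               tau_grid = seq(25, 95, by = 4),
                               beta_grid = seq(0.01, 0.1, by = 0.01),
                               k_grid = seq(0, 2.5, by = 0.1),
                               n_fit_trials = 200, n_vd = 200, reps = 20,
                               sigma_psi = 0.6,
                               cfg = task_config()) {
  per <- horizon + 1L
  agents <- data.frame(agent = seq_len(n_agents), tau = NA_real_,
                       beta = NA_real_, k = NA_real_,
                       tau_hat = NA_real_, beta_hat = NA_real_,
                       k_hat = NA_real_)
  phi0_true <- phi0_hat <- matrix(NA_real_, n_agents, per)
  n_redrawn <- 0L

  for (i in seq_len(n_agents)) {
    for (attempt in 1:10) {
      tau <- runif(1, tau_range[1], tau_range[2])
      beta <- runif(1, beta_range[1], beta_range[2])
      k <- runif(1, k_range[1], k_range[2])
      phi0 <- runif(per, phi0_range[1], phi0_range[2])
      truth <- fit_agent(tau, beta, k = k, phi0 = phi0,
                         sigma_psi = sigma_psi)
      h1 <- simulate_block(horizon, n_episodes, truth, cfg, block = 2L)
      truth$learning$phi0 <- phi0[1]
      h0 <- simulate_block(0L, n_h0_trials, truth, cfg, block = 1L)
      log <- rbind(as.data.frame(h0), as.data.frame(h1))
      class(log) <- c("conseq_log", "data.frame")

      # a draw whose synthetic session cannot support the fit — lapsing
      # (timing out) on a substantial share of either block's trials, or
      # violating the fit's preconditions — is discarded and redrawn, as
      # an experimenter would exclude an unusable participant; no human
      # session with this many lapses would be analyzed either
      if (mean(h0$no_decision) > 0.15 || mean(h1$no_decision) > 0.15) {
        n_redrawn <- n_redrawn + 1L
        fit <- NULL
        next
      }
      fit <- tryCatch(
        fit_model(log, behavior_block = 2L, tau_grid = tau_grid,
                  beta_grid = beta_grid, n_trials = n_fit_trials,
                  n_vd = n_vd, k_grid = k_grid,
                  reps = reps, sigma_psi = sigma_psi, gf_reps = 0,
                  cfg = cfg),
        error = function(e) NULL)
      if (!is.null(fit)) break
      n_redrawn <- n_redrawn + 1L
    }
    if (is.null(fit))
      stop("could not generate a fittable synthetic session for agent ", i)
    agents$tau[i] <- tau
    agents$beta[i] <- beta
    agents$k[i] <- k
    phi0_true[i, ] <- phi0
    agents$tau_hat[i] <- fit$tau
    agents$beta_hat[i] <- fit$beta
    agents$k_hat[i] <- fit$k
    phi0_hat[i, ] <- fit$phi0
  }
  for (j in seq_len(per)) {
    agents[[paste0("phi0_", j)]] <- phi0_true[, j]
    agents[[paste0("phi0_", j, "_hat")]] <- phi0_hat[, j]
  }
  pars <- c("tau", "beta", "k")
  correlations <- vapply(pars, function(p)
    cor(agents[[p]], agents[[paste0(p, "_hat")]]), numeric(1))
  bias <- vapply(pars, function(p)
    mean(agents[[paste0(p, "_hat")]] - agents[[p]]), numeric(1))
  structure(list(agents = agents, correlations = correlations,
                 bias = bias, n_redrawn = n_redrawn),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("parameter recovery over %d synthetic agents\n",
              nrow(x$agents)))
  cat("Pearson correlation (true vs recovered):\n")
  print(round(x$correlations, 3))
  cat("mean bias (recovered - true):\n")
  print(signif(x$bias, 3))
  invisible(x)
}
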