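#' Parameters of the two-population mean-field decision network
#'
#' Two pools of excitatory neurons, selective for the left and right
#' stimulus, compete through mutual inhibition (`w_minus`) while exciting
#' themselves (`w_plus`). The firing rates follow
#' `tau * dr = (-r + f(input)) dt + sigma dW`, with the sigmoid transfer
#' `f(x) = f_max / (1 + exp(-(x - theta)/k_sig))`. A perceptual decision is
#' committed the first time `|r_L - r_R|` strictly exceeds `delta_thr`.
#'
#' All rates are in ms^-1 (use [hz()] to convert, e.g. `hz(25)` for a
#' 25 Hz threshold); times are in ms.
#'
#' @param tau population time constant (ms).
#' @param sigma noise amplitude (ms^-1).
#' @param delta_thr decision threshold on the rate difference (ms^-1).
#' @param w_plus recurrent excitation weight.
#' @param w_minus mutual inhibition weight.
#' @param f_max firing-rate saturation (ms^-1).
#' @param theta sigmoid midpoint (ms^-1).
#' @param k_sig sigmoid slope scale (ms^-1).
#' @param dt Euler-Maruyama step (ms); must be small relative to `tau`.
#' @param t_max trial cutoff (ms), mirroring the task's 4 s response
#'   window; a trial with no crossing before `t_max` yields no decision.
#' @return an object of class `neural_params`.
#' @export
neural_params <- function(tau = 80, sigma = 0.003, delta_thr = hz(25),
                          w_plus = 1.4, w_minus = 1.5, f_max = 0.04,
                          theta = 0.015, k_sig = 0.022, dt = 0.5,
                          t_max = 4000) {
  stop_if_not_scalar(tau, "tau", 0, strict_lower = TRUE)
  stop_if_not_scalar(sigma, "sigma", 0)
  stop_if_not_scalar(f_max, "f_max", 0, strict_lower = TRUE)
  stop_if_not_scalar(delta_thr, "delta_thr", 0, strict_lower = TRUE)
  if (delta_thr >= f_max)
    stop("delta_thr must be strictly below f_max")
  stop_if_not_scalar(dt, "dt", 0, strict_lower = TRUE)
  stop_if_not_scalar(t_max, "t_max", 0, strict_lower = TRUE)
  if (dt > tau / 10)
    stop("integration step dt must be much smaller than tau (dt <= tau/10)")
  structure(list(tau = tau, sigma = sigma, delta_thr = delta_thr,
                 w_plus = w_plus, w_minus = w_minus, f_max = f_max,
                 theta = theta, k_sig = k_sig, dt = dt, t_max = t_max),
            class = "neural_params")
}

#' Sigmoid transfer function of the mean-field pools
#'
#' `f(x) = f_max / (1 + exp(-(x - theta)/k_sig))`: strictly increasing and
#' bounded in `(0, f_max)`, with `f(theta) = f_max/2`.
#'
#' @param x net input (ms^-1); vectorized.
#' @param params a [neural_params()].
#' @return firing rate(s) in ms^-1.
#' @export
transfer <- function(x, params = neural_params()) {
  params$f_max / (1 + exp(-(x - params$theta) / params$k_sig))
}

#' Stimulus drive pair
#'
#' Input intensities for the left and right pool, usually obtained from
#' stimulus values through the linear rescaling of [rescale_params()]. In
#' the intended operating regime both drives are positive; weak (even
#' non-positive) drives are tolerated and simply produce little input.
#'
#' @param lambda_L,lambda_R input intensities (ms^-1).
#' @return an object of class `stimulus_drive`.
#' @export
stimulus_drive <- function(lambda_L, lambda_R) {
  stop_if_not_scalar(lambda_L, "lambda_L")
  stop_if_not_scalar(lambda_R, "lambda_R")
  structure(list(lambda_L = lambda_L, lambda_R = lambda_R),
            class = "stimulus_drive")
}

#' Integrate one perceptual decision
#'
#' Runs the stochastic mean-field race until the rate difference strictly
#' crosses the decision threshold or the trial cutoff is reached. The
#' intended decision `psi_tilde` gates the inputs: with `psi_tilde = 1`
#' pool L receives `lambda_L` and pool R `lambda_R` (the larger stimulus is
#' favored); with `psi_tilde = 0` the drives are swapped, so the network
#' races toward the smaller stimulus. Both pools start at rate 0.
#'
#' @param drive a [stimulus_drive()] (or a length-2 numeric
#'   `c(lambda_L, lambda_R)`).
#' @param psi_tilde intended decision, 0 (small) or 1 (big).
#' @param params a [neural_params()].
#' @param keep_trace logical; keep the sampled `(t, r_L, r_R)` path.
#' @return a `dynamics_result`: `winner` (`"left"`, `"right"` or `"none"`),
#'   `decision_time` (ms, `NA` when no crossing occurred) and optionally
#'   `trace`.
#' @export
simulate_trial <- function(drive, psi_tilde, params = neural_params(),
                           keep_trace = FALSE) {
  if (is.numeric(drive) && length(drive) == 2L)
    drive <- stimulus_drive(drive[1], drive[2])
  stopifnot(inherits(drive, "stimulus_drive"))
  if (!psi_tilde %in% c(0, 1)) stop("psi_tilde must be 0 or 1")
  res <- cpp_mf_trial(drive$lambda_L, drive$lambda_R, psi_tilde,
                      unclass(params), keep_trace)
  structure(list(winner = c("none", "left", "right")[res$winner + 1L],
                 decision_time = res$time,
                 trace = res$trace),
            class = "dynamics_result")
}

#' @export
print.dynamics_result <- function(x, ...) {
  if (x$winner == "none") cat("no decision before the trial cutoff\n")
  else cat(sprintf("decision: %s pool, at %.1f ms\n", x$winner,
                   x$decision_time))
  invisible(x)
}

#' Monte-Carlo visual discrimination of the network
#'
#' Fraction of simulated trials — intended decision clamped at "big", pair
#' means drawn uniformly from `m_range`, stimuli `M +/- delta/2` rescaled
#' to drives — in which the pool encoding the larger stimulus wins the
#' race.
#'
#' Races without a threshold crossing before the cutoff are judged by
#' which pool's firing rate is larger at the cutoff, so every run casts a
#' verdict; a network whose races mostly stall therefore scores near
#' chance rather than being silently dropped.
#'
#' @param delta stimulus difference (difficulty) to probe.
#' @param params a [neural_params()].
#' @param rescale a [rescale_params()].
#' @param n_runs number of Monte-Carlo trials.
#' @param m_range range for the pair mean; the default matches the
#'   horizon-0 uniform bounds with `delta_max = 0.2`.
#' @return fraction in \[0, 1\]. Attribute `"n_decided"` reports how many
#'   runs crossed the threshold.
#' @export
estimate_vd <- function(delta, params = neural_params(),
                        rescale = rescale_params(), n_runs = 500,
                        m_range = c(0.1, 0.9)) {
  stopifnot(n_runs >= 1)
  M <- runif(n_runs, m_range[1], m_range[2])
  big_left <- runif(n_runs) < 0.5
  s_big <- M + delta / 2
  s_small <- M - delta / 2
  lam_big <- rescale$alpha + rescale$beta * s_big
  lam_small <- rescale$alpha + rescale$beta * s_small
  lam_L <- ifelse(big_left, lam_big, lam_small)
  lam_R <- ifelse(big_left, lam_small, lam_big)
  res <- cpp_mf_batch(lam_L, lam_R, rep(1, n_runs), unclass(params))
  left_ahead <- ifelse(res$winner != 0L, res$winner == 1L,
                       res$r_L > res$r_R)
  structure(mean(left_ahead == big_left),
            n_decided = sum(res$winner != 0L))
}
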