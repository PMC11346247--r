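#' Parameters of the intended-decision process
#'
#' The intention to aim for the smaller (0) or bigger (1) stimulus evolves
#' in the double-well energy landscape `E(psi) = psi^2 (psi - 1)^2`, whose
#' basins of attraction at 0 and 1 encode the two intentions:
#' `tau_psi * dpsi = -4 psi (psi - 1)(psi - 1/2) dt + sigma_psi g(t) dW`.
#' The Gaussian noise is strongest at onset and decays quadratically with
#' elapsed time, `g(t) = (1 + t/tau_psi)^-2`, so late dynamics are
#' quasi-deterministic; `sigma_psi` is the decisional uncertainty: the
#' larger it is, the weaker the hold of the initial bias.
#'
#' @param tau_psi time constant (ms). It also sets the time scale of the
#'   noise decay, the only time scale available in the equation.
#' @param sigma_psi decisional uncertainty (noise amplitude).
#' @param dt integration step (ms).
#' @param eps basin tolerance: the process settles once psi enters
#'   `[0, eps]` or `[1 - eps, 1]`.
#' @param t_max cutoff (ms); unsettled runs are classified by the nearest
#'   basin.
#' @return an object of class `intention_params`.
#' @export
intention_params <- function(tau_psi = 10, sigma_psi = 0.4, dt = 0.1,
                             eps = 0.02, t_max = 500) {
  stop_if_not_scalar(tau_psi, "tau_psi", 0, strict_lower = TRUE)
  stop_if_not_scalar(sigma_psi, "sigma_psi", 0)
  stop_if_not_scalar(dt, "dt", 0, strict_lower = TRUE)
  stop_if_not_scalar(eps, "eps", 0, 0.5, strict_lower = TRUE)
  if (eps >= 0.5) stop("eps must be below 0.5")
  stop_if_not_scalar(t_max, "t_max", 0, strict_lower = TRUE)
  structure(list(tau_psi = tau_psi, sigma_psi = sigma_psi, dt = dt,
                 eps = eps, t_max = t_max),
            class = "intention_params")
}

#' Simulate one intended decision
#'
#' Integrates the double-well process from the initial bias `psi0` until a
#' basin is reached. With `sigma_psi = 0` the outcome is exactly
#' `sign(psi0 - 1/2)`; the degenerate noiseless start at exactly 0.5 sits
#' on the separatrix and is resolved by a fair (seeded) coin flip at the
#' cutoff.
#'
#' @param psi0 initial bias in \[0, 1\], typically the strategy value
#'   [seed_intention()] returns.
#' @param params an [intention_params()].
#' @param keep_trace logical; keep the sampled `psi(t)` path.
#' @return an `intention_result`: `psi_tilde` (0 or 1), `settle_time`
#'   (ms), `settled` (FALSE when classified at cutoff) and optionally
#'   `trace`.
#' @export
simulate_intention <- function(psi0, params = intention_params(),
                               keep_trace = FALSE) {
  stop_if_not_scalar(psi0, "psi0", 0, 1)
  res <- cpp_intention_trial(psi0, unclass(params), keep_trace)
  structure(res, class = "intention_result")
}

#' @export
print.intention_result <- function(x, ...) {
  cat(sprintf("intended decision: %s (psi = %d) after %.1f ms%s\n",
              if (x$psi_tilde == 1) "big" else "small", x$psi_tilde,
              x$settle_time,
              if (x$settled) "" else " [classified at cutoff]"))
  invisible(x)
}

#' Empirical probability of intending "big"
#'
#' Monte-Carlo estimate of `P(psi_tilde = 1 | psi0)`. Non-decreasing in
#' `psi0`; its slope around 0.5 flattens as the decisional uncertainty
#' grows.
#'
#' @inheritParams simulate_intention
#' @param n_runs number of independent realizations.
#' @return fraction in \[0, 1\].
#' @export
intention_probability <- function(psi0, params = intention_params(),
                                  n_runs = 1000) {
  stop_if_not_scalar(psi0, "psi0", 0, 1)
  stopifnot(n_runs >= 1)
  mean(cpp_intention_batch(as.integer(n_runs), psi0, unclass(params)))
}
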