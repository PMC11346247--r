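#' Strategy-learning parameters
#'
#' The strategy function `phi(E, T_E)` holds, for every within-episode
#' trial position, the current preference in \[0, 1\] for intending the
#' bigger stimulus. After each episode it is updated position by position
#' with the reinforcement-comparison rule
#' `phi' = phi + k * R * (2 psi_tilde - 1) * (phi - 1)^2 * phi^2`,
#' where `R` is the subjective reward of that trial. The quartic factor
#' shrinks the increment near the bounds, which keeps `phi` in \[0, 1\]
#' and makes 0 and 1 absorbing. With `k = 0` there is no learning.
#'
#' @param k learning rate (>= 0).
#' @param phi0 vector of initial biases, one per within-episode position
#'   (a scalar is recycled to the horizon's length when the agent runs).
#' @return an object of class `learning_params`.
#' @export
learning_params <- function(k = 0.4, phi0 = 0.5) {
  stop_if_not_scalar(k, "k", 0)
  if (!is.numeric(phi0) || any(!is.finite(phi0)) ||
      any(phi0 < 0 | phi0 > 1))
    stop("phi0 values must lie in [0, 1]")
  structure(list(k = k, phi0 = phi0), class = "learning_params")
}

#' Subjective reward of a trial
#'
#' Between consecutive trials of an episode the reward is the change in
#' stimulus-pair mean caused by the choice,
#' `R(E, T_E) = M(E, T_E + 1) - M(E, T_E)`: `+G` after choosing small,
#' `-G` after choosing big. No next trial exists at the episode's last
#' position, so the terminal reward is an interpretation (see Details).
#'
#' @details Two terminal-reward rules are provided. `"gain"` (default)
#'   assigns `+G` if the bigger stimulus was chosen and `-G` otherwise —
#'   the final choice's perceived advantage expressed at the same gain
#'   scale `G` that the within-episode mean shifts make salient; in
#'   independent-trial blocks (`G = 0`) it reduces to the chosen value
#'   minus the pair mean, `+/- delta/2`. `"half_delta"` uses
#'   `+/- delta/2` everywhere. Both are positive exactly when the bigger
#'   stimulus was chosen, so the update pushes the final position's
#'   preference toward "big"; they differ only in magnitude, i.e. in how
#'   fast the last position is learned.
#'
#' @param episode an `episode_state` whose choice at position `t_e` has
#'   been recorded (see [advance_episode()]).
#' @param t_e trial position within the episode (1-based).
#' @param final_reward terminal-reward rule, `"gain"` or `"half_delta"`.
#' @return signed reward; `NA` if the trial had no recorded choice.
#' @export
reward_signal <- function(episode, t_e,
                          final_reward = c("gain", "half_delta")) {
  stopifnot(inherits(episode, "episode_state"))
  final_reward <- match.arg(final_reward)
  t_e <- as.integer(t_e)
  if (t_e < 1L || t_e > length(episode$choices))
    stop("no recorded choice at position ", t_e)
  choice <- episode$choices[t_e]
  if (is.na(choice)) return(NA_real_)
  big <- choice == "big"
  if (t_e < episode$n_trials) {
    if (big) -episode$G else episode$G
  } else if (final_reward == "half_delta" || episode$G == 0) {
    if (big) episode$delta / 2 else -episode$delta / 2
  } else {
    if (big) episode$G else -episode$G
  }
}

#' Apply one reinforcement-comparison update
#'
#' `phi' = phi + k * R * (2 psi_tilde - 1) * (phi - 1)^2 * phi^2` at the
#' given position. A positive reward strengthens the intention that was
#' taken (`psi_tilde = 1` raises `phi`, `psi_tilde = 0` lowers it); a
#' negative reward weakens it. The bounds 0 and 1 are fixed points.
#'
#' @param phi numeric vector, the strategy state (one value per
#'   within-episode position), each in \[0, 1\].
#' @param psi_tilde the trial's intended decision, 0 or 1.
#' @param reward the trial's subjective reward (see [reward_signal()]).
#' @param t_e position to update (1-based).
#' @param params a [learning_params()] (only `k` is used).
#' @return the updated strategy vector.
#' @examples
#' update_strategy(0.5, psi_tilde = 0, reward = 0.3, t_e = 1,
#'                 params = learning_params(k = 0.4))  # 0.4925
#' @export
update_strategy <- function(phi, psi_tilde, reward, t_e,
                            params = learning_params()) {
  if (!psi_tilde %in% c(0, 1)) stop("psi_tilde must be 0 or 1")
  t_e <- as.integer(t_e)
  if (t_e < 1L || t_e > length(phi)) stop("invalid trial position")
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  f <- phi[t_e]
  phi[t_e] <- f + params$k * reward * (2 * psi_tilde - 1) *
    (f - 1)^2 * f^2
  phi
}

#' Seed the intention process from the strategy
#'
#' The strategy value at the current position is used as the initial
#' condition of the intended-decision process, `psi(0) = phi(T_E)`.
#'
#' @inheritParams update_strategy
#' @return the initial bias `psi0` for [simulate_intention()].
#' @export
seed_intention <- function(phi, t_e) {
  t_e <- as.integer(t_e)
  if (t_e < 1L || t_e > length(phi)) stop("invalid trial position")
  phi[t_e]
}
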