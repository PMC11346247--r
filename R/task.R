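#' Configure a consequential-task session
#'
#' A session is a sequence of blocks; each block contains whole episodes of
#' `horizon + 1` dependent trials. Within an episode the two stimuli of a
#' trial are `M - delta/2` and `M + delta/2`; after a "small" choice the
#' next trial's mean increases by the gain `G`, after a "big" choice it
#' decreases by `G`. Stimuli are fractions of a full container, so every
#' value must stay in \[0, 1\]: first-trial means are drawn uniformly from
#' `[n_H * G + delta_max/2, 1 - n_H * G - delta_max/2]`.
#'
#' The default layout reproduces the reference design: one 100-trial block
#' at horizon 0, two 100-trial blocks at horizon 1, and three horizon-2
#' blocks of 105, 105 and 90 trials — 100 episodes per horizon — with gains
#' G = 0.3 (horizon 1) and G = 0.19 (horizon 2) and five difficulty levels
#' `delta` between 0.01 and 0.2. For other values of `episodes_per_horizon`
#' a single block per horizon is used unless `block_layout` is supplied.
#'
#' @param horizon_set integer vector of horizon depths to include.
#' @param episodes_per_horizon episodes per horizon when `block_layout` is
#'   not given.
#' @param block_layout data frame with columns `horizon` and `n_trials`,
#'   one row per block in presentation order (before horizon reordering).
#'   Every `n_trials` must divide into whole episodes.
#' @param G_by_horizon named numeric vector mapping horizon to gain G.
#' @param delta_levels ordered difficulty levels (stimulus differences).
#' @param delta_max largest difficulty; defaults to `max(delta_levels)`.
#' @param horizon_order optional explicit horizon presentation order; by
#'   default [build_session()] draws a random permutation.
#' @param seed optional integer; when set, [build_session()] is
#'   reproducible independently of the caller's RNG state.
#' @return an object of class `task_config`.
#' @seealso [build_session()], [sample_episode()]
#' @export
task_config <- function(horizon_set = c(0L, 1L, 2L),
                        episodes_per_horizon = 100L,
                        block_layout = NULL,
                        G_by_horizon = c("0" = 0, "1" = 0.3, "2" = 0.19),
                        delta_levels = c(0.01, 0.05, 0.1, 0.15, 0.2),
                        delta_max = max(delta_levels),
                        horizon_order = NULL,
                        seed = NULL) {
  horizon_set <- as.integer(horizon_set)
  if (any(horizon_set < 0)) stop("horizons must be non-negative")
  if (!all(delta_levels > 0 & delta_levels < 1))
    stop("all delta levels must lie in (0, 1)")
  if (abs(delta_max - max(delta_levels)) > 1e-12)
    stop("delta_max must equal max(delta_levels)")
  if (is.null(names(G_by_horizon)))
    names(G_by_horizon) <- as.character(seq_along(G_by_horizon) - 1L)

  if (is.null(block_layout)) {
    if (identical(as.integer(episodes_per_horizon), 100L) &&
        setequal(horizon_set, c(0L, 1L, 2L))) {
      block_layout <- data.frame(horizon = c(0L, 1L, 1L, 2L, 2L, 2L),
                                 n_trials = c(100L, 100L, 100L, 105L, 105L, 90L))
    } else {
      block_layout <- data.frame(
        horizon = horizon_set,
        n_trials = as.integer(episodes_per_horizon) * (horizon_set + 1L))
    }
  }
  block_layout <- as.data.frame(block_layout)
  if (!all(c("horizon", "n_trials") %in% names(block_layout)))
    stop("block_layout needs columns 'horizon' and 'n_trials'")
  block_layout$horizon <- as.integer(block_layout$horizon)
  block_layout$n_trials <- as.integer(block_layout$n_trials)
  if (any(block_layout$n_trials %% (block_layout$horizon + 1L) != 0L))
    stop("block trial counts must divide into whole episodes ",
         "(episodes never span blocks and are never truncated)")

  cfg <- structure(
    list(horizon_set = sort(unique(block_layout$horizon)),
         episodes_per_horizon = as.integer(episodes_per_horizon),
         block_layout = block_layout,
         G_by_horizon = G_by_horizon,
         delta_levels = sort(delta_levels),
         delta_max = delta_max,
         horizon_order = horizon_order,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "task_config")

  for (h in cfg$horizon_set) {
    G <- horizon_gain(cfg, h)
    b <- mean_bounds(h, G, delta_max)
    if (b[1] >= b[2])
      stop(sprintf(paste0("degenerate first-trial mean bounds for horizon %d: ",
                          "[%g, %g]; reduce G or delta_max"), h, b[1], b[2]))
  }
  cfg
}

horizon_gain <- function(cfg, horizon) {
  key <- as.character(horizon)
  if (horizon == 0L) return(0)
  if (!key %in% names(cfg$G_by_horizon))
    stop(sprintf("no gain G configured for horizon %d", horizon))
  G <- unname(cfg$G_by_horizon[[key]])
  if (G < 0 || G >= 1) stop("G must lie in [0, 1)")
  G
}

mean_bounds <- function(horizon, G, delta_max) {
  c(horizon * G + delta_max / 2, 1 - horizon * G - delta_max / 2)
}

#' Draw a fresh episode
#'
#' Samples a first-trial mean uniformly from the horizon's admissible range
#' and a difficulty level from the configured set; the difficulty stays
#' constant across the episode's trials.
#'
#' @param horizon episode depth (number of dependent trials after the
#'   first).
#' @param cfg a [task_config()].
#' @param delta optional fixed difficulty; drawn from
#'   `cfg$delta_levels` when `NULL`.
#' @param episode episode index recorded on the state (bookkeeping only).
#' @return an `episode_state` holding the horizon, gain, difficulty, base
#'   mean, current (running) mean, current trial index and choices so far.
#' @export
sample_episode <- function(horizon, cfg = task_config(), delta = NULL,
                           episode = 1L) {
  horizon <- as.integer(horizon)
  G <- horizon_gain(cfg, horizon)
  b <- mean_bounds(horizon, G, cfg$delta_max)
  if (b[1] >= b[2])
    stop(sprintf("degenerate mean bounds [%g, %g] for horizon %d", b[1], b[2],
                 horizon))
  if (is.null(delta)) {
    delta <- cfg$delta_levels[sample.int(length(cfg$delta_levels), 1L)]
  } else if (!delta %in% cfg$delta_levels) {
    stop("delta must be one of the configured difficulty levels")
  }
  structure(list(horizon = horizon, n_trials = horizon + 1L, G = G,
                 delta = delta, M1 = runif(1, b[1], b[2]),
                 M_t = NULL, trial = 1L, choices = character(0),
                 episode = as.integer(episode)),
            class = "episode_state") -> st
  st$M_t <- st$M1
  st
}

#' Stimulus pair shown on the current trial of an episode
#'
#' The two stimuli are `M_t - delta/2` (small) and `M_t + delta/2` (big);
#' the screen side of the bigger stimulus and which side is presented
#' first are independent fair coin flips, drawn here.
#'
#' @param state an `episode_state`.
#' @return a `stimulus_pair` with fields `s_small`, `s_big`, `M`, `delta`,
#'   `side_of_big`, `shown_first`, `episode`, `trial_in_episode`.
#' @export
trial_stimuli <- function(state) {
  stopifnot(inherits(state, "episode_state"))
  if (state$trial > state$n_trials)
    stop("episode is finished; no further trials can be generated")
  sides <- c("left", "right")
  structure(list(s_small = state$M_t - state$delta / 2,
                 s_big = state$M_t + state$delta / 2,
                 M = state$M_t, delta = state$delta,
                 side_of_big = sides[sample.int(2L, 1L)],
                 shown_first = sides[sample.int(2L, 1L)],
                 episode = state$episode,
                 trial_in_episode = state$trial),
            class = "stimulus_pair")
}

#' Advance an episode by recording a choice
#'
#' Applies the consequence rule: the running mean increases by `G` after a
#' "small" choice and decreases by `G` after a "big" choice. A missing
#' choice (`NA`, a lapsed response window) advances the trial counter
#' without shifting the mean.
#'
#' @param state an `episode_state` with at least one trial remaining.
#' @param choice `"small"`, `"big"`, or `NA`.
#' @return the updated `episode_state`.
#' @export
advance_episode <- function(state, choice) {
  stopifnot(inherits(state, "episode_state"))
  if (length(state$choices) >= state$n_trials)
    stop("episode is finished; no further trials can be generated")
  if (!is.na(choice) && !choice %in% c("small", "big"))
    stop("choice must be \"small\", \"big\" or NA")
  state$choices <- c(state$choices, as.character(choice))
  if (!is.na(choice))
    state$M_t <- state$M_t + if (choice == "small") state$G else -state$G
  state$trial <- state$trial + 1L
  state
}

#' Stimuli of the next trial, given the previous choice
#'
#' Convenience wrapper around [advance_episode()] plus [trial_stimuli()].
#' The updated episode state is attached as attribute `"state"`.
#'
#' @inheritParams advance_episode
#' @return a `stimulus_pair` for the next trial.
#' @examples
#' cfg <- task_config()
#' st <- sample_episode(1, cfg, delta = 0.2)
#' p <- next_trial_stimuli(st, "small")   # mean raised by G
#' @export
next_trial_stimuli <- function(state, prev_choice) {
  ns <- advance_episode(state, prev_choice)
  pair <- trial_stimuli(ns)
  attr(pair, "state") <- ns
  pair
}

#' Enumerate every choice sequence of an episode
#'
#' Exhaustively lists the `2^(horizon + 1)` small/big sequences with their
#' cumulative reward values, ordered from best to worst. For horizon 1 the
#' cumulative value takes the four distinct values `2M + G`, `2M + G - delta`,
#' `2M - G + delta` and `2M - G`. Used as the oracle for performance
#' normalization.
#'
#' @param horizon episode depth (>= 0).
#' @param M first-trial mean.
#' @param delta stimulus difference.
#' @param G gain/loss applied to the mean after each choice.
#' @return data frame with columns `sequence` (comma-separated choices) and
#'   `total`, sorted by decreasing total; attribute `"distinct"` holds the
#'   sorted distinct totals.
#' @export
enumerate_episode_outcomes <- function(horizon, M, delta, G) {
  n <- as.integer(horizon) + 1L
  grids <- rep(list(c("small", "big")), n)
  seqs <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  totals <- apply(seqs, 1L, function(ch) {
    m <- M
    tot <- 0
    for (c_t in ch) {
      tot <- tot + m + if (c_t == "big") delta / 2 else -delta / 2
      m <- m + if (c_t == "big") -G else G
    }
    tot
  })
  out <- data.frame(sequence = apply(seqs, 1L, paste, collapse = ","),
                    total = totals, stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "distinct") <- sort(unique(round(out$total, 12)),
                                decreasing = TRUE)
  out
}

#' Build a replayable session plan
#'
#' Orders the configured blocks with a random permutation of horizons
#' (blocks of the same horizon stay together), pre-samples every episode's
#' difficulty and first-trial mean, and pre-draws the per-trial side and
#' presentation-order coin flips, so that the plan — and any simulation run
#' on it — is fully determined by `cfg$seed`.
#'
#' @param cfg a [task_config()].
#' @return a `session_plan`: list with elements `config`, `blocks` (one row
#'   per block) and `trials` (one row per planned trial).
#' @export
build_session <- function(cfg = task_config()) {
  stopifnot(inherits(cfg, "task_config"))
  with_seed(cfg$seed, {
    horizons <- unique(cfg$block_layout$horizon)
    ord <- if (!is.null(cfg$horizon_order)) as.integer(cfg$horizon_order)
           else sample(horizons)
    if (!setequal(ord, horizons))
      stop("horizon_order must be a permutation of the configured horizons")
    layout <- do.call(rbind, lapply(ord, function(h)
      cfg$block_layout[cfg$block_layout$horizon == h, , drop = FALSE]))
    layout$block <- seq_len(nrow(layout))
    layout$n_episodes <- layout$n_trials %/% (layout$horizon + 1L)

    trials <- vector("list", nrow(layout))
    ep_offset <- 0L
    for (i in seq_len(nrow(layout))) {
      h <- layout$horizon[i]
      n_ep <- layout$n_episodes[i]
      G <- horizon_gain(cfg, h)
      b <- mean_bounds(h, G, cfg$delta_max)
      delta <- cfg$delta_levels[sample.int(length(cfg$delta_levels), n_ep,
                                           replace = TRUE)]
      M1 <- runif(n_ep, b[1], b[2])
      per <- h + 1L
      n_tr <- n_ep * per
      sides <- c("left", "right")
      trials[[i]] <- data.frame(
        block = layout$block[i], horizon = h,
        episode = rep(seq_len(n_ep), each = per),
        session_episode = rep(ep_offset + seq_len(n_ep), each = per),
        trial_in_episode = rep(seq_len(per), times = n_ep),
        delta = rep(delta, each = per), M1 = rep(M1, each = per),
        gain = G,
        side_of_big = sides[sample.int(2L, n_tr, replace = TRUE)],
        shown_first = sides[sample.int(2L, n_tr, replace = TRUE)],
        stringsAsFactors = FALSE)
      ep_offset <- ep_offset + n_ep
    }
    structure(list(config = cfg,
                   blocks = layout[, c("block", "horizon", "n_trials",
                                       "n_episodes")],
                   trials = do.call(rbind, trials)),
              class = "session_plan")
  })
}

#' @export
print.session_plan <- function(x, ...) {
  cat("Consequential-task session plan\n")
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Flatten a session plan to a trial schedule
#'
#' One row per planned trial. Stimulus values are only known in advance for
#' the first trial of each episode (later trials depend on the choices
#' made); dependent trials carry `NA` stimuli.
#'
#' @param x a `session_plan`.
#' @param row.names,optional,... ignored; present for compatibility with
#'   the generic.
#' @return data frame with columns `block`, `horizon`, `episode`,
#'   `trial_in_episode`, `s_left`, `s_right`, `shown_first`, `delta`, `M`.
#' @export
as.data.frame.session_plan <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  tr <- x$trials
  first <- tr$trial_in_episode == 1L
  M <- ifelse(first, tr$M1, NA_real_)
  s_big <- M + tr$delta / 2
  s_small <- M - tr$delta / 2
  left_big <- tr$side_of_big == "left"
  data.frame(block = tr$block, horizon = tr$horizon, episode = tr$episode,
             trial_in_episode = tr$trial_in_episode,
             s_left = ifelse(left_big, s_big, s_small),
             s_right = ifelse(left_big, s_small, s_big),
             shown_first = tr$shown_first, delta = tr$delta, M = M,
             stringsAsFactors = FALSE)
}
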