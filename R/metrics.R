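#' Per-episode performance
#'
#' Performance (PF) is the min-max normalized cumulative reward value of
#' an episode: 1 when the best attainable choice sequence was taken, 0
#' when the worst was. The attainable range comes from exhaustively
#' enumerating the episode's choice sequences
#' ([enumerate_episode_outcomes()]) from its first-trial mean. Trials
#' without a decision contribute no reward; the resulting value is clamped
#' to \[0, 1\]. Episodes with missing trials are dropped with a warning.
#'
#' @param log a `conseq_log` (simulated or read with [read_log()]).
#' @return data frame with one row per complete episode: `block`,
#'   `horizon`, `episode`, `session_episode`, `delta`, `PF` and `optimal`
#'   (logical: every decided trial took the optimal choice and none was
#'   missed).
#' @export
episode_performance <- function(log) {
  stopifnot(inherits(log, "data.frame"))
  log <- log[order(log$block, log$episode, log$trial_in_episode), ,
             drop = FALSE]
  key <- log$block * 1e7 + log$episode
  n_exp <- log$horizon + 1L
  cnt <- stats::ave(rep(1L, nrow(log)), key, FUN = sum)
  ok_idx <- stats::ave(log$trial_in_episode, key,
                       FUN = function(x) all(x == seq_along(x)))
  bad <- cnt != n_exp | ok_idx == 0
  if (any(bad)) {
    warning(sprintf("%d incomplete episode(s) excluded",
                    length(unique(key[bad]))))
    log <- log[!bad, , drop = FALSE]
    key <- key[!bad]
  }
  first <- log$trial_in_episode == 1L
  ep <- data.frame(block = log$block[first], horizon = log$horizon[first],
                   episode = log$episode[first],
                   session_episode = log$session_episode[first],
                   delta = log$delta[first], gain = log$gain[first],
                   M1 = log$M[first])
  n <- ep$horizon + 1L
  achieved <- rowsum(ifelse(is.na(log$chosen_value), 0, log$chosen_value),
                     key)[, 1]
  ind <- optimal_choice_indicator(log)
  n_opt <- rowsum(ifelse(is.na(ind), 0L, ind), key)[, 1]
  n_dec <- rowsum(as.integer(!is.na(ind)), key)[, 1]

  hi <- lo <- rep(NA_real_, nrow(ep))
  for (h in unique(ep$horizon)) {
    sel <- ep$horizon == h
    cf <- seq_coefs(h + 1L)
    extra <- lapply(seq_len(nrow(cf)), function(j)
      cf[j, "a"] * ep$gain[sel] + cf[j, "b"] * ep$delta[sel])
    hi[sel] <- (h + 1L) * ep$M1[sel] + do.call(pmax, extra)
    lo[sel] <- (h + 1L) * ep$M1[sel] + do.call(pmin, extra)
  }
  pf <- ifelse(hi - lo < 1e-12, 1, clamp01((achieved - lo) / (hi - lo)))
  data.frame(block = ep$block, horizon = ep$horizon, episode = ep$episode,
             session_episode = ep$session_episode, delta = ep$delta,
             PF = pf, optimal = n_dec == n & n_opt == n)
}

# Cumulative-value coefficients of every choice sequence of an n-trial
# episode: total = n*M1 + a*G + b*delta.  Cached per n.
.coef_cache <- new.env(parent = emptyenv())
seq_coefs <- function(n) {
  k <- as.character(n)
  if (!is.null(.coef_cache[[k]])) return(.coef_cache[[k]])
  seqs <- as.matrix(do.call(expand.grid, rep(list(c(0, 1)), n)))  # 1 = big
  a <- apply(seqs, 1L, function(s) {
    shift <- cumsum(ifelse(s == 1, -1, 1))   # net mean shifts, in units of G
    sum(c(0, shift[-n]))
  })
  b <- rowSums(seqs) / 2 - (n - rowSums(seqs)) / 2
  .coef_cache[[k]] <- cbind(a = a, b = b)
}

#' Optimal-choice indicator per trial
#'
#' The optimal policy is to choose the smaller stimulus on every trial of
#' an episode except the last, and the bigger one on the last trial (for
#' horizon 0, every trial is last). The per-trial indicator is the datum
#' of the probability of optimal choice; no-decision trials yield `NA`.
#'
#' @param log a `conseq_log` (or any subset of its rows).
#' @return integer vector of 0/1/`NA`, one per row of `log`.
#' @export
optimal_choice_indicator <- function(log) {
  final <- log$trial_in_episode == log$horizon + 1L
  ifelse(is.na(log$choice_class), NA_integer_,
         as.integer(ifelse(final, log$choice_class == "big",
                           log$choice_class == "small")))
}

#' Visual discrimination
#'
#' Fraction of the hardest trials (smallest configured stimulus
#' difference) in which the larger stimulus was selected, over the last
#' `n_last` episodes of the horizon-0 block. This isolates perceptual
#' resolution from strategy, because in independent trials the larger
#' stimulus is unambiguously the correct target.
#'
#' @param log a `conseq_log` containing a horizon-0 block.
#' @param n_last number of trailing episodes to use.
#' @param hardest difficulty level defining "most difficult" trials.
#' @return fraction in \[0, 1\], or `NA` with a warning when no
#'   qualifying trial exists.
#' @export
visual_discrimination <- function(log, n_last = 80, hardest = 0.01) {
  h0 <- log[log$horizon == 0L, , drop = FALSE]
  if (nrow(h0) == 0L) {
    warning("log contains no horizon-0 block; VD is undefined")
    return(NA_real_)
  }
  b0 <- h0$block[1]
  h0 <- h0[h0$block == b0, , drop = FALSE]
  h0 <- h0[h0$episode > max(h0$episode) - n_last, , drop = FALSE]
  sel <- abs(h0$delta - hardest) < 1e-9 & !h0$no_decision
  if (!any(sel)) {
    warning("no decided trials at the hardest difficulty; VD is undefined")
    return(NA_real_)
  }
  mean(h0$choice_class[sel] == "big")
}

#' Learning time of a session
#'
#' An episode counts as "optimal" when every decided trial took the
#' optimal choice and no trial was missed. Episodes at the excluded
#' (hardest) difficulty are removed first, so perceptual lapses on
#' near-identical stimuli do not mask strategy knowledge. The learning
#' time `t_L` is the first optimal episode from which the optimal
#' strategy is employed in at least `hits` of the following `window`
#' episodes (counted from `t_L` itself) and in
#' at least `tail_frac` of the remaining episodes until the end of the
#' block (windows truncated by the block end are judged proportionally).
#' Blocks are scanned in presentation order and the first block meeting
#' the criterion fixes the session's single learning time, expressed as a
#' session-wide episode index.
#'
#' @param log a `conseq_log`.
#' @param window,hits window criterion: `hits` out of `window` episodes.
#' @param tail_frac required fraction of optimal episodes in the tail.
#' @param exclude_delta difficulty level excluded from the assessment.
#' @param tail_from where the tail starts: after the window (default) or
#'   immediately after the candidate episode.
#' @return a `learning_assessment`: list with `t_L` (session episode
#'   index, `NA` when never learned), `learned`, `block`, `t_L_block`
#'   (index within that block), and `n_episodes` (session total).
#' @export
learning_time <- function(log, window = 10L, hits = 9L, tail_frac = 0.75,
                          exclude_delta = 0.01,
                          tail_from = c("window", "t_L")) {
  tail_from <- match.arg(tail_from)
  perf <- episode_performance(log)
  blocks <- unique(perf$block)
  total_eps <- nrow(perf)
  res <- list(t_L = NA_integer_, learned = FALSE, block = NA_integer_,
              t_L_block = NA_integer_, n_episodes = total_eps,
              window = window, hits = hits, tail_frac = tail_frac)
  offset <- 0L
  for (b in blocks) {
    pb <- perf[perf$block == b, , drop = FALSE]
    keep <- abs(pb$delta - exclude_delta) >= 1e-9
    ind <- as.integer(pb$optimal[keep])
    pos <- which(keep)               # episode index within the block
    n <- length(ind)
    found <- NA_integer_
    for (e in seq_len(n)) {
      if (ind[e] != 1L) next     # t_L is an episode that is itself optimal
      w <- ind[e:min(e + window - 1L, n)]
      need <- ceiling(hits / window * length(w))
      if (sum(w) < need) next
      tail_start <- if (tail_from == "window") e + window else e + 1L
      tl <- if (tail_start > n) integer(0) else ind[tail_start:n]
      if (length(tl) == 0L || mean(tl) >= tail_frac) {
        found <- pos[e]
        break
      }
    }
    if (!is.na(found)) {
      res$t_L <- offset + found
      res$learned <- TRUE
      res$block <- b
      res$t_L_block <- found
      break
    }
    offset <- offset + nrow(pb)
  }
  structure(res, class = "learning_assessment")
}

#' @export
print.learning_assessment <- function(x, ...) {
  if (x$learned)
    cat(sprintf("optimal strategy learned at episode %d (block %d, episode %d of the block)\n",
                x$t_L, x$block, x$t_L_block))
  else
    cat("optimal strategy not learned within the session\n")
  invisible(x)
}

#' Label learning speed within a cohort
#'
#' Splits learned sessions into fast/medium/slow groups at configurable
#' quantile cut points of the learning-time distribution; sessions that
#' never met the criterion are labelled `"NL"`.
#'
#' @param t_l vector of learning times (`NA` = never learned).
#' @param probs two quantile probabilities delimiting fast/medium/slow.
#' @return factor with levels `fast`, `medium`, `slow`, `NL`.
#' @export
learning_groups <- function(t_l, probs = c(1/3, 2/3)) {
  lv <- c("fast", "medium", "slow", "NL")
  out <- rep("NL", length(t_l))
  ok <- !is.na(t_l)
  if (any(ok)) {
    qs <- quantile(t_l[ok], probs, names = FALSE, type = 1)
    out[ok] <- ifelse(t_l[ok] <= qs[1], "fast",
                      ifelse(t_l[ok] <= qs[2], "medium", "slow"))
  }
  factor(out, levels = lv)
}

#' Reaction-time summaries
#'
#' Mean, standard deviation and count of reaction times over decided
#' trials, grouped by the requested log columns. Negative RTs are
#' legitimate (anticipation of the GO signal).
#'
#' @param log a `conseq_log`.
#' @param by grouping columns.
#' @return data frame of per-cell `n`, `mean_rt`, `sd_rt`.
#' @export
rt_summaries <- function(log, by = c("horizon", "trial_in_episode",
                                     "delta")) {
  d <- log[!log$no_decision & !is.na(log$rt), , drop = FALSE]
  if (nrow(d) == 0L) stop("no decided trials with reaction times")
  g <- d[, by, drop = FALSE]
  agg <- aggregate(d$rt, by = g,
                   FUN = function(x) c(n = length(x), mean = mean(x),
                                       sd = sd(x)))
  out <- cbind(agg[, by, drop = FALSE], as.data.frame(agg$x))
  names(out) <- c(by, "n", "mean_rt", "sd_rt")
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Empirical RT distribution
#'
#' @param log a `conseq_log`.
#' @param ... optional logical subset expressions are not supported; pass
#'   a pre-filtered log instead.
#' @return the [stats::ecdf()] of the decided trials' reaction times.
#' @export
rt_ecdf <- function(log, ...) {
  d <- log$rt[!log$no_decision & !is.na(log$rt)]
  if (length(d) == 0L) stop("no decided trials with reaction times")
  ecdf(d)
}
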