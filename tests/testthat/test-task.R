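test_that("first-trial means respect the horizon-dependent uniform bounds", {
  set.seed(101)
  cfg <- task_config()
  m1_h1 <- replicate(2000, sample_episode(1, cfg)$M1)
  expect_true(all(m1_h1 >= 0.4 & m1_h1 <= 0.6))
  m1_h0 <- replicate(10000, sample_episode(0, cfg)$M1)
  expect_true(all(m1_h0 >= 0.1 & m1_h0 <= 0.9))
  # uniform on the stated bounds
  ks <- suppressWarnings(stats::ks.test(m1_h0, "punif", 0.1, 0.9))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate mean bounds are rejected at configuration time", {
  expect_error(task_config(G_by_horizon = c("0" = 0, "1" = 0.3, "2" = 0.5)),
               "degenerate")
})

test_that("the consequence rule shifts the next pair's mean by +/- G", {
  set.seed(102)
  cfg <- task_config()
  st <- sample_episode(1, cfg, delta = 0.2)
  st$M_t <- 0.5
  up <- next_trial_stimuli(st, "small")
  expect_equal(c(up$s_small, up$s_big), c(0.7, 0.9))
  dn <- next_trial_stimuli(st, "big")
  expect_equal(c(dn$s_small, dn$s_big), c(0.1, 0.3))
  # stimuli stay in [0, 1] for any generated episode and any choice path
  for (i in 1:50) {
    e <- sample_episode(2, cfg)
    for (ch in list(c("small", "small"), c("small", "big"),
                    c("big", "small"), c("big", "big"))) {
      s <- e
      vals <- c(s$M_t - s$delta / 2, s$M_t + s$delta / 2)
      for (c1 in ch) {
        p <- next_trial_stimuli(s, c1)
        s <- attr(p, "state")
        vals <- c(vals, p$s_small, p$s_big)
      }
      expect_true(all(vals >= 0 & vals <= 1))
    }
  }
  # advancing past the last trial is a state error
  done <- advance_episode(advance_episode(st, "small"), "big")
  expect_error(advance_episode(done, "big"), "finished")
  expect_error(trial_stimuli(done), "finished")
})

test_that("horizon-1 episodes admit exactly the four printed outcomes", {
  enum <- enumerate_episode_outcomes(1, M = 0.5, delta = 0.2, G = 0.3)
  M <- 0.5; d <- 0.2; G <- 0.3
  expect_equal(attr(enum, "distinct"),
               c(2 * M + G, 2 * M + G - d, 2 * M - G + d, 2 * M - G))
  expect_equal(max(enum$total), 1.3)
  expect_equal(min(enum$total), 0.7)
  expect_equal(nrow(enum), 4L)
  # degenerate symmetry: all sequences tie
  enum0 <- enumerate_episode_outcomes(1, 0.5, delta = 0, G = 0)
  expect_length(attr(enum0, "distinct"), 1L)
})

test_that("always choosing big never attains the episode maximum", {
  set.seed(103)
  cfg <- task_config()
  for (h in c(1, 2)) {
    for (i in 1:25) {
      e <- sample_episode(h, cfg)
      enum <- enumerate_episode_outcomes(h, e$M1, e$delta, e$G)
      all_big <- enum$total[enum$sequence ==
                              paste(rep("big", h + 1), collapse = ",")]
      expect_lt(all_big, max(enum$total))
    }
  }
})

test_that("the default session reproduces the reference layout", {
  cfg <- task_config(seed = 7)
  plan <- build_session(cfg)
  expect_equal(nrow(plan$blocks), 6L)
  eps <- tapply(plan$blocks$n_episodes, plan$blocks$horizon, sum)
  expect_equal(as.vector(eps), c(100L, 100L, 100L))
  expect_equal(sort(plan$blocks$n_trials[plan$blocks$horizon == 2]),
               c(90L, 105L, 105L))
  # difficulty constant within episode, drawn from the five levels
  expect_setequal(unique(plan$trials$delta), c(0.01, 0.05, 0.1, 0.15, 0.2))
  per_ep <- tapply(plan$trials$delta,
                   plan$trials$block * 1e7 + plan$trials$episode,
                   function(x) length(unique(x)))
  expect_true(all(per_ep == 1L))
})

test_that("session plans replay bit-for-bit from their seed", {
  p1 <- build_session(task_config(seed = 42))
  p2 <- build_session(task_config(seed = 42))
  expect_identical(p1, p2)
  p3 <- build_session(task_config(seed = 43))
  expect_false(identical(p1$trials, p3$trials))
})

test_that("episodes_per_horizon scales the plan", {
  plan <- build_session(task_config(episodes_per_horizon = 10, seed = 1))
  expect_equal(as.vector(tapply(plan$blocks$n_episodes, plan$blocks$horizon,
                                sum)),
               c(10L, 10L, 10L))
})

test_that("blocks must divide into whole episodes", {
  expect_error(task_config(block_layout =
                             data.frame(horizon = 1, n_trials = 101)),
               "whole episodes")
})

test_that("horizon_order override is honored", {
  cfg <- task_config(horizon_order = c(2, 0, 1), seed = 5)
  plan <- build_session(cfg)
  expect_equal(unique(plan$blocks$horizon), c(2L, 0L, 1L))
})

test_that("trial schedules export with stimuli known only for lead trials", {
  plan <- build_session(task_config(episodes_per_horizon = 4, seed = 2))
  df <- as.data.frame(plan)
  expect_named(df, c("block", "horizon", "episode", "trial_in_episode",
                     "s_left", "s_right", "shown_first", "delta", "M"))
  lead <- df$trial_in_episode == 1
  expect_false(anyNA(df$s_left[lead]))
  expect_true(all(is.na(df$M[!lead])))
  expect_equal(abs(df$s_left - df$s_right)[lead], df$delta[lead])
})

test_that("session plans survive a JSON round trip", {
  plan <- build_session(task_config(episodes_per_horizon = 4, seed = 9))
  path <- tempfile(fileext = ".json")
  write_session_json(plan, path)
  back <- read_session_json(path)
  expect_equal(back$trials$M1, plan$trials$M1)
  expect_equal(back$trials$side_of_big, plan$trials$side_of_big)
  expect_equal(back$blocks, plan$blocks, ignore_attr = TRUE)
})
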