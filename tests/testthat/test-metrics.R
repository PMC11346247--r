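test_that("episode performance matches the outcome formulas", {
  G <- 0.3
  log <- synthetic_log(1, G, delta = 0.2, M1 = 0.5,
                       choices = list(c("small", "big"),   # optimal
                                      c("big", "small"),   # anti-optimal
                                      c("big", "big"),
                                      c("small", "small")))
  pf <- episode_performance(log)$PF
  expect_equal(pf[1], 1)
  expect_equal(pf[2], 0)
  expect_equal(pf[3], 0.2 / (2 * G))   # delta / (2 G) = 1/3
  expect_equal(pf[4], 1 - 0.2 / (2 * G))
})

test_that("vectorized performance agrees with the enumeration oracle", {
  set.seed(61)
  ag <- test_agent(k = 0.8)
  log <- simulate_block(2, 20, ag)
  perf <- episode_performance(log)
  for (i in sample(nrow(perf), 8)) {
    e <- log[log$episode == perf$episode[i], ]
    enum <- enumerate_episode_outcomes(e$horizon[1], e$M[1], e$delta[1],
                                       e$gain[1])
    achieved <- sum(ifelse(is.na(e$chosen_value), 0, e$chosen_value))
    pf <- (achieved - min(enum$total)) / diff(range(enum$total))
    expect_equal(perf$PF[i], min(1, max(0, pf)), tolerance = 1e-10)
  }
})

test_that("the optimal choice is big on last trials and small before", {
  h0 <- synthetic_log(0, 0, 0.1, 0.5, list("big", "small"))
  expect_equal(optimal_choice_indicator(h0), c(1L, 0L))
  h2 <- synthetic_log(2, 0.19, 0.1, 0.5,
                      list(c("small", "big", "big")))
  expect_equal(optimal_choice_indicator(h2), c(1L, 0L, 1L))
  h1 <- synthetic_log(1, 0.3, 0.1, 0.5, list(c("small", "big")))
  expect_equal(optimal_choice_indicator(h1), c(1L, 1L))
  # lapsed trials yield NA
  nd <- synthetic_log(1, 0.3, 0.1, 0.5, list(c(NA, "big")))
  expect_equal(optimal_choice_indicator(nd), c(NA_integer_, 1L))
})

test_that("visual discrimination counts hardest-trial hits only", {
  ch <- c(rep_episodes("big", 50), rep_episodes("small", 25),
          rep_episodes("big", 25))
  log <- synthetic_log(0, 0, delta = rep(c(0.01, 0.2), 50), M1 = 0.5,
                       choices = ch)
  # last 80 episodes are 21..100; hardest are the odd episodes
  hard_last80 <- seq(21, 99, by = 2)
  expected <- mean(hard_last80 <= 50 | hard_last80 > 75)
  expect_equal(visual_discrimination(log), expected)
  expect_warning(vd <- visual_discrimination(log[log$horizon == 1, ]),
                 "no horizon-0")
  expect_true(is.na(vd))
})

test_that("learning time implements the window-plus-tail criterion", {
  opt <- c("small", "big")
  bad <- c("big", "big")
  mk <- function(pattern) synthetic_log(1, 0.3, 0.1, 0.5, pattern)
  # 11 non-optimal episodes then optimal to the end: learned at 12
  la <- learning_time(mk(c(rep_episodes(bad, 11), rep_episodes(opt, 39))))
  expect_equal(la$t_L, 12L)
  expect_true(la$learned)
  # optimal from the start
  expect_equal(learning_time(mk(rep_episodes(opt, 50)))$t_L, 1L)
  # never optimal
  la_no <- learning_time(mk(rep_episodes(bad, 50)))
  expect_false(la_no$learned)
  expect_true(is.na(la_no$t_L))
  # 9 of 10 suffices: one lapse inside the window does not delay learning
  ch <- c(rep_episodes(bad, 5), rep_episodes(opt, 3), rep_episodes(bad, 1),
          rep_episodes(opt, 41))
  expect_equal(learning_time(mk(ch))$t_L, 6L)
  # but a weak tail does: 75% of the remaining episodes must be optimal
  ch2 <- c(rep_episodes(opt, 10), rep_episodes(bad, 40))
  expect_false(learning_time(mk(ch2))$learned)
})

test_that("hardest episodes are excluded from the learning criterion", {
  opt <- c("small", "big")
  bad <- c("big", "big")
  # every episode optimal except hardest ones, which all fail:
  # perceptual lapses must not mask strategy knowledge
  deltas <- rep(c(0.1, 0.01), 25)
  ch <- rep(list(opt, bad), 25)
  log <- synthetic_log(1, 0.3, delta = deltas, M1 = 0.5, choices = ch)
  la <- learning_time(log)
  expect_true(la$learned)
  expect_equal(la$t_L, 1L)
})

test_that("learning time is stable under appending optimal episodes and
           monotone under prepending non-optimal ones", {
  opt <- c("small", "big")
  bad <- c("big", "big")
  base <- c(rep_episodes(bad, 7), rep_episodes(opt, 30))
  mk <- function(p) synthetic_log(1, 0.3, 0.1, 0.5, p)
  t0 <- learning_time(mk(base))$t_L
  expect_equal(learning_time(mk(c(base, rep_episodes(opt, 20))))$t_L, t0)
  expect_equal(learning_time(mk(c(rep_episodes(bad, 5), base)))$t_L,
               t0 + 5L)
})

test_that("learning groups split learned sessions at quantile cut points", {
  g <- learning_groups(c(2, 5, 9, 30, NA, 70))
  expect_equal(as.character(g),
               c("fast", "fast", "medium", "medium", "NL", "slow"))
  expect_equal(as.character(learning_groups(c(1, NA))), c("fast", "NL"))
})

test_that("RT summaries aggregate decided trials and track shifts", {
  log <- synthetic_log(1, 0.3, 0.1, 0.5,
                       rep_episodes(c("small", "big"), 10),
                       rt = 400)
  s <- rt_summaries(log)
  expect_equal(s$mean_rt, rep(400, nrow(s)))
  expect_equal(sum(s$n), 20)
  shifted <- log
  shifted$rt <- shifted$rt - 100
  expect_equal(rt_summaries(shifted)$mean_rt, s$mean_rt - 100)
  # identical input, identical output: metrics are pure functions
  expect_identical(rt_summaries(log), rt_summaries(log))
  f <- rt_ecdf(log)
  expect_equal(f(399), 0)
  expect_equal(f(400), 1)
})
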