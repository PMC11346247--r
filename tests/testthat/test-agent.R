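test_that("closed-loop simulation is deterministic under a fixed seed", {
  ag <- test_agent()
  set.seed(51)
  l1 <- simulate_block(1, 10, ag)
  set.seed(51)
  l2 <- simulate_block(1, 10, ag)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  plan <- build_session(task_config(episodes_per_horizon = 5, seed = 3))
  set.seed(52)
  b1 <- run_block(plan, 1, ag)
  set.seed(52)
  b2 <- run_block(plan, 1, ag)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
})

test_that("logged records are internally consistent", {
  set.seed(53)
  ag <- test_agent(rt_shift = -100)
  log <- simulate_block(2, 15, ag)
  d <- log[!log$no_decision, ]
  # choice class agrees with the chosen value
  bigger <- pmax(d$s_left, d$s_right)
  expect_equal(d$choice_class == "big", d$chosen_value == bigger)
  # reported RT is the decision time plus the anticipation shift
  expect_equal(d$rt, d$decision_time + ag$rt_shift)
  # chosen side holds the chosen value
  expect_equal(d$chosen_value,
               ifelse(d$chosen_side == "left", d$s_left, d$s_right))
})

test_that("the logged mean chain replays through the task-layer rule", {
  set.seed(54)
  ag <- test_agent()
  log <- simulate_block(2, 12, ag)
  for (e in unique(log$episode)) {
    ep <- log[log$episode == e, ]
    M <- ep$M[1]
    for (te in seq_len(nrow(ep) - 1)) {
      ch <- ep$choice_class[te]
      if (!is.na(ch)) M <- M + if (ch == "small") ep$gain[1] else -ep$gain[1]
      expect_equal(ep$M[te + 1], M)
    }
    expect_equal(ep$s_left + ep$s_right, 2 * ep$M)
    expect_equal(abs(ep$s_left - ep$s_right), rep(ep$delta[1], nrow(ep)))
  }
})

test_that("a frozen always-big agent earns the known suboptimal PF", {
  # k = 0 and phi0 = 1 lock the intention at "big"; without neural noise
  # every discrimination succeeds, so each horizon-1 episode realizes the
  # (big, big) outcome whose PF is delta / (2 G)
  set.seed(55)
  ag <- test_agent(k = 0, sigma = 0, sigma_psi = 0, phi0 = 1)
  # keep every drive inside the network's winner-take-all operating range
  # (input near the sigmoid midpoint), even for the low-mean second trials
  # that follow a "big" first choice, so every race finishes
  ag$rescale <- structure(list(alpha = 0.002, beta = 0.033),
                          class = "rescale_params")
  log <- simulate_block(1, 12, ag)
  expect_true(all(log$choice_class == "big"))
  perf <- episode_performance(log)
  expect_equal(perf$PF, perf$delta / (2 * 0.3), tolerance = 1e-9)
})

test_that("no-decision trials leave the strategy and mean chain untouched", {
  # beta = 0 gives equal negative drives: the race never crosses threshold
  set.seed(56)
  ag <- test_agent(k = 1, sigma = 0.001, beta = 0)
  log <- simulate_block(1, 5, ag)
  expect_true(all(log$no_decision))
  expect_true(all(is.na(log$rt)))
  pp <- attr(log, "phi_path")[[1]]
  expect_true(all(pp == 0.5))
  expect_equal(log$M[log$trial_in_episode == 2],
               log$M[log$trial_in_episode == 1])
  expect_equal(episode_performance(log)$PF, rep(0, 5))
})

test_that("sessions run block by block with per-block strategy reset", {
  set.seed(57)
  plan <- build_session(task_config(episodes_per_horizon = 4, seed = 8))
  ag <- test_agent(k = 1)
  log <- run_session(plan, ag)
  expect_equal(unique(log$block), plan$blocks$block)
  expect_equal(nrow(log), sum(plan$blocks$n_trials))
  paths <- attr(log, "phi_path")
  expect_length(paths, nrow(plan$blocks))
  for (p in paths) expect_true(all(p[1, ] == 0.5))
  # session episode indices are consecutive across blocks
  expect_equal(sort(unique(log$session_episode)),
               seq_len(sum(plan$blocks$n_episodes)))
})

test_that("parameter sweeps tabulate the requested grid", {
  set.seed(58)
  out <- sweep_parameter_space(list(k = c(0.2, 1.5)), base = test_agent(),
                               n_episodes = 15, reps = 3)
  expect_equal(nrow(out), 2L)
  expect_true(all(c("mean_rt", "sd_rt", "mean_t_l", "frac_learned",
                    "mean_pf") %in% names(out)))
  expect_true(all(is.finite(out$mean_rt)))
})

test_that("behavioral logs survive a CSV round trip", {
  set.seed(59)
  log <- simulate_block(1, 6, test_agent())
  path <- tempfile(fileext = ".csv")
  write_log(log, path)
  back <- read_log(path)
  expect_equal(as.data.frame(back), as.data.frame(log)[names(back)],
               tolerance = 1e-12)
  # schema validation
  broken <- as.data.frame(log)
  broken$choice_class <- NULL
  path2 <- tempfile(fileext = ".csv")
  write.csv(broken, path2, row.names = FALSE)
  expect_error(read_log(path2), "missing required columns")
})
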