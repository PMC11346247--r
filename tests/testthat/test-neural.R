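test_that("the transfer function matches its closed form", {
  p <- neural_params()
  expect_equal(transfer(p$theta, p), 0.02)
  expect_equal(transfer(p$theta + p$k_sig, p),
               0.04 * exp(1) / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(transfer(10, p), p$f_max, tolerance = 1e-6)
  expect_equal(transfer(-10, p), 0, tolerance = 1e-6)
  x <- seq(-0.05, 0.1, by = 0.001)
  expect_true(all(diff(transfer(x, p)) > 0))
})

test_that("parameter validation rejects unusable settings", {
  expect_error(neural_params(dt = 40), "smaller than tau")
  expect_error(neural_params(delta_thr = 0.05), "below f_max")
  expect_error(neural_params(tau = -1), "outside")
})

test_that("noiseless integration matches a dense-step reference", {
  p <- neural_params(sigma = 0, dt = 0.5)
  res <- simulate_trial(stimulus_drive(0.0227, 0.0203), 1, p)
  expect_equal(res$winner, "left")
  ref <- oracle_mf_crossing(0.0227, 0.0203, p, dt = 0.05)
  expect_equal(ref$winner, "left")
  # order-one convergence: the dt = 0.5 crossing sits within a few ms of
  # the dt = 0.05 reference, and dt = 0.1 sits closer still
  expect_lt(abs(res$decision_time - ref$time), 15)
  p2 <- neural_params(sigma = 0, dt = 0.1)
  res2 <- simulate_trial(stimulus_drive(0.0227, 0.0203), 1, p2)
  expect_lt(abs(res2$decision_time - ref$time),
            abs(res$decision_time - ref$time))
})

test_that("exact symmetry yields no decision", {
  p <- neural_params(sigma = 0)
  res <- simulate_trial(stimulus_drive(0.02, 0.02), 1, p)
  expect_equal(res$winner, "none")
  expect_true(is.na(res$decision_time))
})

test_that("firing rates stay within [0, f_max] along the trajectory", {
  set.seed(21)
  p <- neural_params(sigma = 0.003)
  res <- simulate_trial(stimulus_drive(0.0227, 0.0203), 1, p,
                        keep_trace = TRUE)
  tol <- 5 * p$sigma * sqrt(p$dt) / p$tau + 1e-6
  expect_true(all(res$trace$r_L > -0.002 & res$trace$r_L < p$f_max + 0.002))
  expect_true(all(res$trace$r_R > -0.002 & res$trace$r_R < p$f_max + 0.002))
})

test_that("clamping the intention at 'small' reverses the race", {
  set.seed(22)
  p <- neural_params(sigma = 0.003)
  winners <- replicate(300, simulate_trial(stimulus_drive(0.0227, 0.0203),
                                           0, p)$winner)
  frac_right <- mean(winners == "right")
  # with the drives swapped the weaker-stimulus side must win the majority
  expect_gt(frac_right, 0.6)
})

test_that("visual discrimination is perfect without noise and at chance at
           zero difference", {
  set.seed(23)
  p0 <- neural_params(sigma = 0)
  rp <- rescale_params(beta = 0.06)
  expect_equal(estimate_vd(0.2, p0, rp, n_runs = 30), 1,
               ignore_attr = TRUE)
  p <- neural_params(sigma = 0.004)
  vd0 <- estimate_vd(0, p, rp, n_runs = 400)
  expect_gt(vd0, 0.4)
  expect_lt(vd0, 0.6)
})

test_that("discrimination improves with the stimulus difference", {
  set.seed(24)
  p <- neural_params(sigma = 0.006)
  rp <- rescale_params(beta = 0.05)
  vd <- vapply(c(0.01, 0.05, 0.2), function(d)
    as.numeric(estimate_vd(d, p, rp, n_runs = 400)), numeric(1))
  expect_true(all(diff(vd) > -0.05))   # non-decreasing up to MC noise
  expect_gt(vd[3], vd[1])
})
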