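test_that("the KS distance matches ECDF enumeration and ks.test", {
  expect_equal(ksd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ksd(1:3, 11:13), 1)
  expect_equal(ksd(c(1, 2, 3), c(1, 2, 4)), 1 / 3)
  expect_error(ksd(numeric(0), 1:3), "non-empty")
  set.seed(71)
  a <- rnorm(40)
  b <- rnorm(60, 0.5)
  expect_equal(ksd(a, b),
               unname(suppressWarnings(stats::ks.test(a, b))$statistic))
})

test_that("the threshold follows the printed line in tau", {
  expect_equal(fitting_line_delta(80), 0.02816)
  expect_equal(fitting_line_delta(25), 2.57e-4 * 25 + 0.0076)
})

test_that("initial bias rescales the early big-choice frequency", {
  opt <- c("small", "big")
  # larger stimulus chosen at every position of the first 3 episodes
  all_big <- synthetic_log(1, 0.3, 0.1, 0.5, rep_episodes(c("big", "big"), 5))
  expect_equal(round(estimate_initial_bias(all_big), 2), c(0.67, 0.67))
  # never chosen
  none <- synthetic_log(1, 0.3, 0.1, 0.5,
                        rep_episodes(c("small", "small"), 5))
  expect_equal(estimate_initial_bias(none), c(1, 1) / 3)
  # with 3 episodes the estimate can only take four values
  mixed <- synthetic_log(1, 0.3, 0.1, 0.5,
                         list(c("big", "small"), c("big", "big"),
                              c("small", "small"), opt, opt))
  expect_true(all(round(estimate_initial_bias(mixed), 3) %in%
                    round(c(1/3, 4/9, 5/9, 2/3), 3)))
  expect_error(estimate_initial_bias(synthetic_log(1, 0.3, 0.1, 0.5,
                                                   rep_episodes(opt, 2))),
               "at least 3 decided trials")
  # an alternative rescaling can be plugged in
  expect_equal(estimate_initial_bias(all_big,
                                     rescale_f = function(f) (1 + f) / 4),
               c(0.5, 0.5))
})

test_that("perceptual fit recovers a generating grid cell", {
  set.seed(72)
  tau_true <- 67
  beta_true <- 0.057
  truth <- agent_params(
    neural = neural_params(tau = tau_true, sigma = 0.001,
                           delta_thr = fitting_line_delta(tau_true)),
    learning = learning_params(k = 0),
    rescale = rescale_params(beta = beta_true))
  log <- simulate_block(0, 100, truth, fixed_psi = 1)
  fit <- fit_neural(log, tau_grid = c(43, 55, 67, 79, 91),
                    beta_grid = c(0.035, 0.046, 0.057, 0.068),
                    n_trials = 100, n_vd = 150)
  expect_lte(abs(fit$tau - tau_true), 12)       # within one grid step
  expect_lte(abs(fit$beta - beta_true), 0.0111)
  # the composite error always dominates its KSD part
  expect_true(all(fit$surface$m_hat >= fit$surface$ksd - 1e-12))
  expect_true(is.finite(fit$m_hat))
})

test_that("a non-learner's log drives the learning-rate fit toward zero", {
  set.seed(73)
  truth <- test_agent(k = 0, sigma_psi = 0.6, sigma = 0.001, tau = 60,
                      delta_thr = fitting_line_delta(60))
  log <- simulate_block(1, 30, truth)
  lf <- fit_learning_rate(log, tau = 60, beta = 0.05, phi0 = c(0.5, 0.5),
                          k_grid = c(0, 0.5, 1.5, 2.5), reps = 6)
  expect_lte(lf$k, 0.5)
  expect_equal(lf$t_L_obs, 31)   # never learned, imputed past the block
})

test_that("the sequential fit is modular and scores its own goodness", {
  set.seed(74)
  truth <- test_agent(k = 1.5, sigma_psi = 0.6, sigma = 0.001, tau = 55,
                      delta_thr = fitting_line_delta(55), beta = 0.06)
  h0 <- simulate_block(0, 60, truth, block = 1)
  h1 <- simulate_block(1, 25, truth, block = 2)
  log <- rbind(as.data.frame(h0), as.data.frame(h1))
  class(log) <- c("conseq_log", "data.frame")
  fit <- fit_model(log, behavior_block = 2,
                   tau_grid = c(40, 55, 70, 85),
                   beta_grid = c(0.04, 0.06, 0.08), n_vd = 100,
                   k_grid = c(0, 0.75, 1.5, 2.25), reps = 5, gf_reps = 5)
  # steps 2 and 3 never alter the step-1 estimates
  expect_identical(fit$tau, fit$neural_fit$tau)
  expect_identical(fit$beta, fit$neural_fit$beta)
  expect_identical(fit$rt_shift, fit$neural_fit$rt_shift)
  expect_length(fit$phi0, 2L)
  expect_true(all(fit$phi0 >= 1/3 & fit$phi0 <= 2/3))
  expect_true(fit$k %in% c(0, 0.75, 1.5, 2.25))
  expect_true(all(fit$gf >= 0 & fit$gf <= 1))
  expect_named(fit$gf, c("RT", "PF_i", "t_L"))
})
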