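test_that("parameter container validates its fields", {
  expect_error(tm_params(0, 50, 200, 20), "U0")
  expect_error(tm_params(1.2, 50, 200, 20), "U0")
  expect_error(tm_params(0.1, -1, 200, 20), "positive")
  expect_error(tm_params(0.1, 50, 200, 20, N_cal = -2), "N_cal")
  expect_silent(tm_params(0.5, 50, 200, 20, N_cal = 15))
})

test_that("full recovery between widely spaced stimuli gives constant p = U0", {
  pars <- tm_params(0.1, tau_d = 50, tau_f = 200, dt = 1e6 * 200)
  st <- tm_release_probabilities(pars, 8)
  expect_equal(st$p_seq, rep(0.1, 8), tolerance = 1e-9)
  expect_equal(st$X_seq, rep(1, 8), tolerance = 1e-9)
})

test_that("vanishing facilitation time constant removes facilitation", {
  pars <- tm_params(0.1, tau_d = 50, tau_f = 1e-6, dt = 20)
  st <- tm_release_probabilities(pars, 6)
  expect_equal(st$U_seq, rep(0.1, 6), tolerance = 1e-9)
})

test_that("one hand-iterated step reproduces the recursion", {
  U0 <- 0.1; tau_f <- 200; tau_d <- 50; dt <- 20
  st <- tm_release_probabilities(tm_params(U0, tau_d, tau_f, dt), 2)
  ef <- exp(-dt / tau_f); ed <- exp(-dt / tau_d)
  U2 <- U0 * ef + U0 * (1 - U0 * ef)
  X2 <- 1 - (1 - 1 * (1 - U0)) * ed
  expect_equal(st$p_seq[1], 0.1)
  expect_equal(st$U_seq[2], U2)
  expect_equal(st$X_seq[2], X2)
  expect_equal(st$p_seq[2], U2 * X2)
  expect_gt(st$p_seq[2] / st$p_seq[1], 1) # facilitation
})

test_that("state variables stay in (0, 1] for random parameter draws", {
  for (s in 1:20) {
    pars <- withr::with_seed(s, tm_params(
      U0 = runif(1, 0.01, 1), tau_d = runif(1, 1, 1000),
      tau_f = runif(1, 1, 1000), dt = runif(1, 5, 100)
    ))
    st <- tm_release_probabilities(pars, 12)
    expect_true(all(st$U_seq > 0 & st$U_seq <= 1))
    expect_true(all(st$X_seq > 0 & st$X_seq <= 1))
    expect_equal(st$p_seq, st$U_seq * st$X_seq)
  }
})

test_that("low-utilization slow-facilitation trains have rising utilization", {
  pars <- tm_params(0.05, tau_d = 50, tau_f = 500, dt = 20)
  st <- tm_release_probabilities(pars, 10)
  expect_true(all(diff(st$U_seq) > 0))
})

test_that("the alternative printed recursion inverts recovery with interval", {
  pars_short <- tm_params(0.5, tau_d = 50, tau_f = 200, dt = 1)
  pars_long <- tm_params(0.5, tau_d = 50, tau_f = 200, dt = 5000)
  alt_short <- tm_release_probabilities(pars_short, 2, recursion = "alternative")
  alt_long <- tm_release_probabilities(pars_long, 2, recursion = "alternative")
  std_long <- tm_release_probabilities(pars_long, 2, recursion = "standard")
  # standard: full recovery at long intervals; alternative: none
  expect_equal(std_long$X_seq[2], 1, tolerance = 1e-9)
  expect_equal(alt_long$X_seq[2], 0.5, tolerance = 1e-3)
  expect_gt(alt_short$X_seq[2], alt_long$X_seq[2])
})

test_that("predicted means scale linearly in q and N_cal", {
  pars <- tm_params(0.1, 50, 200, dt = 1e9, N_cal = 20)
  mu <- tm_predicted_means(pars, 10, 6)
  expect_equal(mu, rep(20, 6), tolerance = 1e-6) # q N U0 = 10 * 20 * 0.1
  expect_equal(tm_predicted_means(pars, 20, 6), 2 * mu, tolerance = 1e-9)
})

test_that("noise-free calibration round-trips the generative parameters", {
  pars <- tm_params(0.1, tau_d = 50, tau_f = 200, dt = 20, N_cal = 20)
  mu <- tm_predicted_means(pars, 10, 10)
  cal <- calibrate_tm(mu, q_hat = 10, dt = 20, n_starts = 10, seed = 3)
  rms_rel <- sqrt(mean((cal$fitted - mu)^2)) / mean(mu)
  expect_lt(rms_rel, 0.001)
  expect_lt(abs(cal$params$N_cal - 20) / 20, 0.10)
  expect_false(cal$flat_trajectory)
  expect_true(cal$converged)
})

test_that("a constant trajectory is fit with near-zero residual and flagged", {
  cal <- calibrate_tm(rep(20, 8), q_hat = 10, dt = 20, n_starts = 8, seed = 1)
  expect_lt(cal$sse, 1e-4)
  expect_true(cal$flat_trajectory)
})

test_that("multistart dominates a single-start fit on noisy trajectories", {
  pars <- tm_params(0.1, tau_d = 50, tau_f = 200, dt = 20, N_cal = 20)
  mu <- tm_predicted_means(pars, 10, 10)
  mu_noisy <- withr::with_seed(4, mu * (1 + rnorm(10, 0, 0.05)))
  multi <- calibrate_tm(mu_noisy, 10, dt = 20, n_starts = 20, seed = 8)
  single <- calibrate_tm(mu_noisy, 10, dt = 20, n_starts = 1, seed = 8)
  expect_lte(multi$sse, single$sse + 1e-9)
})

test_that("calibration validates its inputs", {
  expect_error(calibrate_tm(c(10, 20, 30), 10, 20), "4 stimuli")
  expect_error(calibrate_tm(c(10, 20, 30, 40), -1, 20), "positive")
  expect_error(calibrate_tm(c(10, -20, 30, 40), 10, 20), "positive")
})

test_that("tidy/glance/json expose the calibrated state", {
  pars <- tm_params(0.2, 80, 300, dt = 20, N_cal = 15)
  mu <- tm_predicted_means(pars, 8, 8)
  cal <- calibrate_tm(mu, 8, dt = 20, n_starts = 6, seed = 2)
  d <- tidy(cal)
  expect_equal(nrow(d), 8)
  expect_equal(d$p_cal, cal$state$p_seq)
  g <- glance(cal)
  expect_true(g$sse < 1e-6)
  js <- jsonlite::fromJSON(write_calibration_json(cal))
  expect_equal(js$N_cal, cal$params$N_cal)
  expect_length(js$p_cal, 8)
})
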