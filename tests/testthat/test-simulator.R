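test_that("ground truth validates its configuration", {
  expect_error(ground_truth(q_bar = 10, N = 20, sigma_eta = 1), "exactly one")
  expect_error(ground_truth(q_bar = 10, N = 20, p = c(0.5), tm = tm_params(0.1, 50, 200, 20)),
               "exactly one")
  expect_error(ground_truth(q_bar = -1, N = 20, p = 0.5), "q_bar")
  expect_error(ground_truth(q_bar = 10, N = 20, p = c(0.2, 1.5)), "0, 1")
  expect_error(ground_truth(q_bar = 10, N = 2.5, p = 0.5), "integer")
  tm <- tm_params(0.1, 50, 200, 20)
  expect_error(ground_truth(q_bar = 10, N = 20, tm = tm), "n_stimuli")
  tr <- ground_truth(q_bar = 10, N = 20, tm = tm, n_stimuli = 6)
  expect_length(tr$p, 6)
})

test_that("deterministic saturated release produces exactly q_bar * N", {
  truth <- ground_truth(q_bar = 10, sigma_q = 0, N = 20, p = c(1, 1, 1),
                        sigma_eta = 0, n_sweeps = 5, seed = 1)
  sm <- simulate_sweeps(truth)
  expect_true(all(as_sweep_values(sm) == 200))
})

test_that("the same seed reproduces bit-identical sweep matrices", {
  truth <- truth_flat5(sigma_q = 2, n_sweeps = 50, seed = 77)
  expect_identical(simulate_sweeps(truth), simulate_sweeps(truth))
  het <- ground_truth(q_bar = 10, sigma_q = 0, N = 20, p = c(0.1, 0.2, 0.3, 0.4),
                      sigma_eta = 1, n_sweeps = 30, het_sigma_p_site = 0.05, seed = 5)
  expect_identical(simulate_heterogeneous(het), simulate_heterogeneous(het))
})

test_that("analytic population moments match the closed forms", {
  truth <- ground_truth(q_bar = 10, sigma_q = 2, N = 20, p = c(0.1, 0.15),
                        sigma_eta = 2)
  am <- analytic_moments(truth)
  expect_equal(am$mu, c(20, 30))
  expect_equal(am$var[1], 207.2) # 104*20*0.09 + 4*400*0.01 + 4
  expect_equal(am$cov[1, 2], 24) # 4 * 400 * 0.1 * 0.15
  clean <- ground_truth(q_bar = 10, sigma_q = 0, N = 20, p = c(0.1, 0.15),
                        sigma_eta = 2)
  amc <- analytic_moments(clean)
  expect_equal(amc$cov[1, 2], 0)
})

test_that("Monte Carlo moments converge to the analytic oracle", {
  for (s in 1:4) {
    truth <- random_truth(s)
    truth$n_sweeps <- 20000L
    sm <- simulate_sweeps(truth)
    m <- epsc_moments(sm, truth$sigma_eta^2)
    am <- analytic_moments(truth)
    se_mu <- sqrt(am$var / truth$n_sweeps)
    expect_true(all(abs(m$mu - am$mu) < 4 * se_mu))
    # SE of the sample variance from the empirical fourth moment
    a <- as_sweep_values(sm)
    m4 <- colMeans(sweep(a, 2, colMeans(a))^4)
    se_var <- sqrt((m4 - m$var^2) / truth$n_sweeps)
    expect_true(all(abs(m$var - am$var) < 4 * se_var))
  }
})

test_that("cross-stimulus covariance scales with the product of means", {
  truth <- ground_truth(q_bar = 10, sigma_q = 3, N = 25,
                        p = c(0.1, 0.2, 0.4, 0.6), sigma_eta = 0)
  am <- analytic_moments(truth)
  pairs <- utils::combn(4, 2)
  ratio <- am$cov[t(pairs)] / (am$mu[pairs[1, ]] * am$mu[pairs[2, ]])
  expect_equal(ratio, rep(0.09, 6), tolerance = 1e-12) # sigma_q^2 / q_bar^2
})

test_that("degenerate heterogeneity reproduces the homogeneous moments", {
  het <- ground_truth(q_bar = 10, sigma_q = 0, N = 20, p = c(0.2, 0.4, 0.6),
                      sigma_eta = 0, n_sweeps = 10000, seed = 11)
  hom <- analytic_moments(het)
  m <- epsc_moments(simulate_heterogeneous(het), 0)
  se_mu <- sqrt(hom$var / het$n_sweeps)
  expect_true(all(abs(m$mu - hom$mu) < 4 * se_mu))
  expect_true(all(abs(m$var - hom$var) / hom$var < 0.1))
})

test_that("zero-truncation bias stays small over the supported CV range", {
  # closed form: the rejection-truncated mean is q + sigma*phi(q/sigma)/Phi(q/sigma),
  # i.e. at most sigma*phi(2)/Phi(2) = 2.8% of q at CV 0.5
  for (cv in c(0.1, 0.3, 0.5)) {
    x <- withr::with_seed(1, quantalmoments:::rtrunc_normal(2e5, 10, cv * 10))
    shift <- cv * 10 * dnorm(1 / cv) / pnorm(1 / cv)
    expect_lt(abs(mean(x) - 10) / 10, shift / 10 + 0.005)
    expect_lt(shift / 10, 0.03)
    expect_true(all(x >= 0))
  }
})

test_that("default scenarios encode facilitating and depressing trains", {
  stf <- scenario_stf()
  std <- scenario_std()
  expect_equal(stf$n_stimuli, 10)
  expect_equal(stf$p[1], 0.1, tolerance = 1e-9)
  expect_gt(stf$p[5], stf$p[1]) # facilitation
  expect_lt(std$p[5], std$p[1]) # depression
  expect_true(all(abs(stf$q_bar * stf$N * stf$p[1] - 20) < 1e-6))
})

test_that("truth JSON round-trips through the scenario config format", {
  tmp <- withr::local_tempfile(fileext = ".json")
  truth <- scenario_stf(seed = 42)
  write_truth_json(truth, tmp)
  back <- read_truth_json(tmp)
  expect_equal(back$p, truth$p, tolerance = 1e-12)
  expect_equal(back$seed, truth$seed)
  expect_identical(simulate_sweeps(back), simulate_sweeps(truth))
})
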