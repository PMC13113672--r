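test_that("tuple enumeration yields all ordered pairwise-distinct quadruples", {
  expect_equal(nrow(release_tuples(3)), 0)
  t4 <- release_tuples(4)
  expect_equal(nrow(t4), 24) # 4 * 3 * 2 * 1
  expect_equal(nrow(release_tuples(10)), 5040) # 10 * 9 * 8 * 7
  distinct <- apply(as.matrix(t4), 1, function(r) length(unique(r)) == 4)
  expect_true(all(distinct))
})

test_that("quantal size from a tuple matches hand-derived population values", {
  clean <- ground_truth(q_bar = 10, sigma_q = 0, N = 20,
                        p = c(0.1, 0.15, 0.2, 0.3), sigma_eta = 0)
  am <- analytic_moments(clean)
  # mu = (20, 30, 40, 60); F(1,2) = 180, F(3,4) = 320
  expect_equal(q_from_tuple(am, 1, 2, 3, 4, r_hat = 0), 10)
  # antisymmetry: swapping the two pairs flips both signs
  expect_equal(q_from_tuple(am, 3, 4, 1, 2, r_hat = 0), 10)

  vq <- ground_truth(q_bar = 10, sigma_q = 2, N = 20,
                     p = c(0.1, 0.15, 0.2, 0.3), sigma_eta = 0)
  amv <- analytic_moments(vq)
  expect_equal(q_from_tuple(amv, 1, 2, 3, 4, r_hat = 0.04), 10)
})

test_that("degenerate tuples are refused", {
  am <- analytic_moments(truth_flat5())
  expect_error(q_from_tuple(am, 1, 1, 3, 4), "distinct")
  same_mu <- moment_set(c(20, 30, 20, 60), diag(c(1, 1, 1, 1)))
  expect_error(q_from_tuple(same_mu, 1, 2, 3, 4), "degenerate")
})

test_that("pool size from a pair matches population values for both branches", {
  clean <- ground_truth(q_bar = 10, sigma_q = 0, N = 20,
                        p = c(0.1, 0.15, 0.2, 0.3), sigma_eta = 0)
  res <- N_from_pair(analytic_moments(clean), 1, 2, q_hat = 10)
  expect_true(res$valid)
  expect_equal(res$N, 20) # 400 / (200 - 180)

  vq <- ground_truth(q_bar = 10, sigma_q = 2, N = 20,
                     p = c(0.1, 0.15, 0.2, 0.3), sigma_eta = 0)
  res2 <- N_from_pair(analytic_moments(vq), 1, 2, q_hat = 10, r_hat = 0.04)
  expect_equal(res2$N, 20) # 400 / (200 - 187.2 / 1.04)

  # an underestimated q forces a negative denominator: non-physical signal
  res3 <- N_from_pair(analytic_moments(clean), 1, 2, q_hat = 5)
  expect_false(res3$valid)
  expect_true(is.na(res3$N))
})

test_that("release probabilities divide out q and N, flagged when impossible", {
  am <- analytic_moments(truth_flat5())
  tab <- p_sequence(am, 10, 20)
  expect_equal(tab$p_hat, c(0.1, 0.15, 0.2, 0.3, 0.35))
  expect_false(any(tab$out_of_range))
  # mu_i = q N gives p = 1 at the saturation bound
  sat <- moment_set(c(200, 100), diag(2))
  expect_equal(p_sequence(sat, 10, 20)$p_hat[1], 1)
  expect_false(p_sequence(sat, 10, 20)$out_of_range[1])
  # mu_i > q N is flagged, not clipped
  over <- moment_set(c(250, 100), diag(2))
  tab2 <- p_sequence(over, 10, 20)
  expect_gt(tab2$p_hat[1], 1)
  expect_true(tab2$out_of_range[1])
})

test_that("q aggregation removes negatives and extremes, then averages", {
  agg <- quantalmoments:::aggregate_q(c(10, 10.2, -5))
  expect_equal(agg$q_hat, 10.1)
  expect_equal(agg$n_rejected, 1)
  # a symmetric blow-up tail around a tight cluster is trimmed both sides
  cand <- withr::with_seed(1, c(rnorm(100, 10, 0.1), 1e6, -1e6))
  agg2 <- quantalmoments:::aggregate_q(cand)
  expect_lt(abs(agg2$q_hat - 10), 0.2)
})

test_that("N aggregation takes the maximum of 3-sigma inliers", {
  agg <- quantalmoments:::aggregate_N(c(18, 19, 20))
  expect_equal(agg$N_hat, 20)
  expect_equal(agg$n_rejected, 0)
  vals <- withr::with_seed(2, c(rnorm(100, 20, 0.5), 1e6))
  agg2 <- quantalmoments:::aggregate_N(vals)
  expect_equal(agg2$N_hat, max(vals[vals < 1e5]))
  expect_gte(agg2$n_rejected, 1)
  # non-positive candidates count as rejections, never as estimates
  agg3 <- quantalmoments:::aggregate_N(c(-3, NA, 20))
  expect_equal(agg3$N_hat, 20)
  expect_equal(agg3$n_rejected, 2)
})

test_that("the estimator chain is exact on population moments", {
  # the central correctness property of the elimination algebra
  p5 <- c(0.1, 0.15, 0.2, 0.3, 0.35)
  clean <- ground_truth(q_bar = 10, sigma_q = 0, N = 20, p = p5, sigma_eta = 2)
  fit <- quantal_estimate_moments(analytic_moments(clean), branch = "fast")
  expect_equal(fit$q_hat, 10, tolerance = 1e-10)
  expect_equal(fit$N_hat, 20, tolerance = 1e-10)
  expect_equal(fit$p_hat, p5, tolerance = 1e-10)

  vq <- ground_truth(q_bar = 10, sigma_q = 2, N = 20, p = p5, sigma_eta = 2)
  fitv <- quantal_estimate_moments(analytic_moments(vq), branch = "detailed")
  expect_equal(fitv$R_hat, 0.04, tolerance = 1e-12)
  expect_equal(fitv$q_hat, 10, tolerance = 1e-10)
  expect_equal(fitv$N_hat, 20, tolerance = 1e-10)
  expect_equal(fitv$p_hat, p5, tolerance = 1e-10)

  # and for randomized parameter sets
  for (s in 1:5) {
    truth <- random_truth(s)
    fit_r <- quantal_estimate_moments(analytic_moments(truth), branch = "detailed")
    expect_equal(fit_r$q_hat, truth$q_bar, tolerance = 1e-8)
    expect_equal(fit_r$N_hat, truth$N, tolerance = 1e-8)
    expect_equal(fit_r$p_hat, truth$p, tolerance = 1e-8)
  }
})

test_that("q candidates are invariant under (i,j,k,l) -> (k,l,i,j) relabeling", {
  am <- analytic_moments(random_truth(7))
  tuples <- release_tuples(am$n_stimuli)
  pick <- withr::with_seed(7, sample(nrow(tuples), 20))
  for (r in pick) {
    t1 <- tuples[r, ]
    q1 <- q_from_tuple(am, t1$i, t1$j, t1$k, t1$l, r_hat = 0.01)
    q2 <- q_from_tuple(am, t1$k, t1$l, t1$i, t1$j, r_hat = 0.01)
    expect_equal(q1, q2, tolerance = 1e-12)
  }
})

test_that("short trains are refused with a 4-stimulus message", {
  truth3 <- ground_truth(q_bar = 10, sigma_q = 0, N = 20,
                         p = c(0.1, 0.2, 0.3), sigma_eta = 0, n_sweeps = 20)
  expect_error(quantal_estimate(simulate_sweeps(truth3), 0), "at least 4")
})

test_that("simulated data at large T recovers the quantal size within 5%", {
  truth <- truth_flat5(sigma_q = 0, sigma_eta = 2, n_sweeps = 2000, seed = 3)
  fit <- quantal_estimate(simulate_sweeps(truth), 4, branch = "fast")
  expect_lt(abs(fit$q_hat - 10) / 10, 0.05)
})

test_that("fast and detailed branches agree when quantal variability is absent", {
  truth <- truth_flat5(sigma_q = 0, sigma_eta = 2, n_sweeps = 2000, seed = 5)
  sm <- simulate_sweeps(truth)
  f1 <- suppressWarnings(quantal_estimate(sm, 4, branch = "fast"))
  f2 <- suppressWarnings(quantal_estimate(sm, 4, branch = "detailed"))
  expect_lt(abs(f1$q_hat - f2$q_hat), 0.5)
})

test_that("estimation is deterministic given the input", {
  truth <- truth_flat5(sigma_q = 2, n_sweeps = 50, seed = 9)
  sm <- simulate_sweeps(truth)
  f1 <- suppressWarnings(quantal_estimate(sm, 4))
  f2 <- suppressWarnings(quantal_estimate(sm, 4))
  expect_identical(glance(f1), glance(f2))
})

test_that("pool-size estimates show no order-of-magnitude inflation on clean data", {
  Ns <- sapply(1:10, function(s) {
    truth <- truth_flat5(sigma_q = 0, sigma_eta = 0, n_sweeps = 2000, seed = s)
    quantal_estimate(simulate_sweeps(truth), 0, branch = "fast")$N_hat
  })
  expect_gt(median(Ns), 0.9 * 20)
  expect_lt(median(Ns), 1.3 * 20)
})

test_that("tidy and glance summarise a fit consistently", {
  truth <- truth_flat5(sigma_q = 2, n_sweeps = 200, seed = 2)
  fit <- suppressWarnings(quantal_estimate(simulate_sweeps(truth), 4))
  g <- glance(fit)
  expect_equal(g$n_stimuli, 5)
  expect_equal(g$n_sweeps, 200)
  d <- tidy(fit)
  expect_equal(nrow(d), 5)
  expect_equal(d$p_hat, fit$p_hat)
  js <- jsonlite::fromJSON(write_estimate_json(fit))
  expect_equal(js$q_hat, fit$q_hat)
  expect_equal(js$K, 5)
})
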