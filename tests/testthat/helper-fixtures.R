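# Shared fixtures: canonical ground truths used across the suite.

truth_flat5 <- function(sigma_q = 0, sigma_eta = 2, n_sweeps = 20, seed = 1L) {
  ground_truth(
    q_bar = 10, sigma_q = sigma_q, N = 20,
    p = c(0.1, 0.15, 0.2, 0.3, 0.35),
    sigma_eta = sigma_eta, n_sweeps = n_sweeps, seed = seed
  )
}

# Bare numeric matrix view of a sweep_matrix tibble.
as_sweep_values <- function(sm) quantalmoments:::as_amplitude_matrix(sm)

# Brute-force double-loop sample covariance (divisor T - 1), the
# independent oracle for the moments module.
brute_cov <- function(a) {
  Tn <- nrow(a); K <- ncol(a)
  mu <- colMeans(a)
  out <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    s <- 0
    for (t in seq_len(Tn)) s <- s + (a[t, i] - mu[i]) * (a[t, j] - mu[j])
    out[i, j] <- s / (Tn - 1)
  }
  out
}

# Random homogeneous ground truth for property-style suites.
random_truth <- function(seed) {
  withr::with_seed(seed, {
    K <- sample(4:10, 1)
    q_bar <- runif(1, 5, 20)
    # CV capped at 0.3 so the untruncated analytic moments are exact to
    # well inside Monte Carlo error (truncation shifts the mean by <0.1%)
    ground_truth(
      q_bar = q_bar,
      sigma_q = runif(1, 0, 0.3) * q_bar,
      N = sample(5:50, 1),
      p = runif(K, 0.05, 0.9),
      sigma_eta = runif(1, 0, 5),
      n_sweeps = 50,
      seed = seed
    )
  })
}
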