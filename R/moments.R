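#' First- and second-order moments of an EPSC sweep matrix
#'
#' Computes the per-stimulus sample means, the full K x K cross-stimulus
#' sample covariance (divisor T - 1), and stores the baseline noise variance
#' `sigma_eta2` alongside. These low-order statistics are the complete input
#' of the moment-based estimators: the mean carries q*N*p_i, the variance
#' adds binomial and quantal-variability terms, and the cross-stimulus
#' covariance isolates the sweep-level quantal fluctuation shared across
#' stimuli.
#'
#' @param data A [sweep_matrix()] or coercible data frame / matrix
#'   (sweeps x stimuli, pA).
#' @param sigma_eta2 Baseline noise variance (pA^2), measured from a
#'   pre-stimulus window (see [estimate_noise_variance()]) or supplied.
#'   It is stored, never re-estimated from the amplitudes.
#' @return An object of class `epsc_moments`: a list with `mu` (length-K
#'   means, pA), `var` (length-K variances, pA^2), `cov` (K x K covariance,
#'   pA^2), `sigma_eta2`, `n_sweeps`, `n_stimuli`.
#' @examples
#' m <- epsc_moments(matrix(c(2, 4, 4, 8), 2, byrow = TRUE), sigma_eta2 = 0)
#' m$mu # 3 6
#' @export
epsc_moments <- function(data, sigma_eta2 = 0) {
  a <- as_amplitude_matrix(data)
  if (nrow(a) < 2L) rlang::abort("At least 2 sweeps are required to compute sample covariance.")
  if (!all(is.finite(a))) rlang::abort("All amplitudes must be finite.")
  if (!is.numeric(sigma_eta2) || length(sigma_eta2) != 1L ||
      !is.finite(sigma_eta2) || sigma_eta2 < 0) {
    rlang::abort("`sigma_eta2` must be a single finite non-negative number (pA^2).")
  }
  cv <- stats::cov(a)
  structure(
    list(
      mu = colMeans(a),
      var = diag(cv),
      cov = cv,
      sigma_eta2 = sigma_eta2,
      n_sweeps = nrow(a),
      n_stimuli = ncol(a)
    ),
    class = "epsc_moments"
  )
}

#' Bundle pre-computed population moments
#'
#' Builds an `epsc_moments` object directly from known mean vector and
#' covariance matrix (e.g. the analytic population moments of
#' [analytic_moments()]), so the estimator chain can be exercised on exact
#' inputs.
#'
#' @param mu Length-K mean vector (pA).
#' @param cov K x K covariance matrix (pA^2).
#' @param sigma_eta2 Noise variance (pA^2).
#' @param n_sweeps Nominal sweep count to record (default `Inf` for
#'   population moments).
#' @return An `epsc_moments` object.
#' @export
moment_set <- function(mu, cov, sigma_eta2 = 0, n_sweeps = Inf) {
  mu <- as.numeric(mu)
  cov <- as.matrix(cov)
  stopifnot(length(mu) == nrow(cov), nrow(cov) == ncol(cov))
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    rlang::abort("`cov` must be symmetric.")
  }
  structure(
    list(
      mu = mu, var = diag(cov), cov = cov,
      sigma_eta2 = sigma_eta2, n_sweeps = n_sweeps, n_stimuli = length(mu)
    ),
    class = "epsc_moments"
  )
}

#' @export
print.epsc_moments <- function(x, ...) {
  cat(sprintf(
    "<epsc_moments> K = %d stimuli, T = %s sweeps, sigma_eta2 = %g pA^2\n",
    x$n_stimuli, format(x$n_sweeps), x$sigma_eta2
  ))
  cat("mu (pA): ", paste(signif(x$mu, 4), collapse = " "), "\n")
  invisible(x)
}

#' @method tidy epsc_moments
#' @export
tidy.epsc_moments <- function(x, ...) {
  tibble::tibble(
    stimulus = seq_len(x$n_stimuli),
    mean = x$mu,
    variance = x$var,
    sd = sqrt(x$var)
  )
}

#' Composite noise-free observable F(i, j)
#'
#' The linear combination
#' `F(i,j) = Var(A_i) - (mu_i / mu_j) * Cov(A_i, A_j) - sigma_eta2`
#' of observable moments. Under the generative model its population value is
#' `E[q_sweep^2] * N * p_i * (1 - p_i)`: the covariance term exactly cancels
#' the quadratic `sigma_q^2 N^2 p_i^2` contribution of sweep-level quantal
#' fluctuation, and the measured noise variance removes the additive noise
#' floor, leaving only the first-order binomial term.
#'
#' @param moments An [epsc_moments()] object.
#' @param i,j Distinct 1-based stimulus indices; `mu[j]` must be non-zero.
#' @return The composite value in pA^2.
#' @export
composite_F <- function(moments, i, j) {
  k <- moments$n_stimuli
  if (i == j) rlang::abort("`i` and `j` must be distinct stimulus indices.")
  if (i < 1 || j < 1 || i > k || j > k) rlang::abort("Stimulus indices out of range.")
  if (moments$mu[j] == 0) rlang::abort("`mu[j]` is zero; F(i, j) is undefined for this pair.")
  moments$var[i] - (moments$mu[i] / moments$mu[j]) * moments$cov[i, j] - moments$sigma_eta2
}

# Full K x K matrix of F(i, j) values (NA on the diagonal); vectorised form
# used by the estimators.
composite_F_matrix <- function(moments) {
  mu <- moments$mu
  if (any(mu == 0)) rlang::abort("All per-stimulus means must be non-zero.")
  # element [i, j] = var[i] - (mu_i / mu_j) * cov[i, j] - sigma_eta2;
  # var recycles down columns so row i carries var[i]
  f <- moments$var - outer(mu, mu, "/") * moments$cov - moments$sigma_eta2
  diag(f) <- NA_real_
  f
}

#' Normalized quantal variability ratio
#'
#' Estimates `R = sigma_q^2 / q_bar^2`, the squared coefficient of variation
#' of the sweep-level quantal size, as the average of
#' `Cov(A_i, A_j) / (mu_i * mu_j)` over all unordered stimulus pairs
#' `i < j`. Under the generative model every pairwise ratio has population
#' value `sigma_q^2 / q_bar^2`, so the average is a robust, fully observable
#' estimate. The result is clamped below at zero: sampling noise can push
#' individual ratios negative, but the target is a variance ratio. A warning
#' is raised when more than 25% of the pairwise ratios are negative, a sign
#' that the covariance signal is dominated by noise.
#'
#' @param moments An [epsc_moments()] object with K >= 2 and all means
#'   non-zero.
#' @return A single non-negative number.
#' @export
quantal_cv_ratio <- function(moments) {
  k <- moments$n_stimuli
  if (k < 2) rlang::abort("At least 2 stimuli are required to estimate the quantal variability ratio.")
  if (any(moments$mu == 0)) rlang::abort("All per-stimulus means must be non-zero.")
  pairs <- utils::combn(k, 2)
  ratios <- moments$cov[t(pairs)] / (moments$mu[pairs[1, ]] * moments$mu[pairs[2, ]])
  if (mean(ratios < 0) > 0.25) {
    rlang::warn(sprintf(
      "%.0f%% of pairwise covariance ratios are negative; the quantal variability estimate may be noise-dominated.",
      100 * mean(ratios < 0)
    ))
  }
  max(mean(ratios), 0)
}
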