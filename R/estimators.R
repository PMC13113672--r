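#' Enumerate admissible stimulus index tuples
#'
#' The closed-form quantal-size estimator combines the composite observables
#' F(i, j) and F(k, l) from two stimulus pairs. A tuple (i, j, k, l) is
#' admissible when all four indices are pairwise distinct, which is why at
#' least four stimuli are required: paired-pulse and three-stimulus
#' protocols cannot support the estimator.
#'
#' @param n_stimuli Number of stimuli K in the train.
#' @return A tibble with integer columns `i`, `j`, `k`, `l`, one row per
#'   ordered tuple of pairwise-distinct indices; zero rows when K < 4.
#' @examples
#' nrow(release_tuples(4)) # 24
#' @export
release_tuples <- function(n_stimuli) {
  if (n_stimuli < 4) {
    return(tibble::tibble(i = integer(), j = integer(), k = integer(), l = integer()))
  }
  g <- tidyr::expand_grid(
    i = seq_len(n_stimuli), j = seq_len(n_stimuli),
    k = seq_len(n_stimuli), l = seq_len(n_stimuli)
  )
  dplyr::filter(
    g,
    .data$i != .data$j, .data$i != .data$k, .data$i != .data$l,
    .data$j != .data$k, .data$j != .data$l, .data$k != .data$l
  )
}

#' Closed-form quantal size from one index tuple
#'
#' Evaluates the variability-corrected estimator
#' `q = (mu_k^2 F(i,j) - mu_i^2 F(k,l)) / (mu_k mu_i (1 + R) (mu_k - mu_i))`.
#' With `r_hat = 0` this reduces to the fast-branch approximation that
#' assumes negligible sweep-level quantal variability. On population
#' moments the expression returns the generative quantal mean exactly, for
#' any admissible tuple.
#'
#' @param moments An [epsc_moments()] object.
#' @param i,j,k,l Pairwise-distinct 1-based stimulus indices.
#' @param r_hat Normalized quantal variability ratio (>= 0), from
#'   [quantal_cv_ratio()] or 0 for the fast branch.
#' @param tol Relative tolerance below which `|mu_k - mu_i|` is considered
#'   degenerate (division blow-up); such tuples raise an error here and are
#'   skipped during aggregation.
#' @return Quantal size estimate in pA.
#' @export
q_from_tuple <- function(moments, i, j, k, l, r_hat = 0, tol = 1e-6) {
  idx <- c(i, j, k, l)
  if (anyDuplicated(idx) || any(idx < 1) || any(idx > moments$n_stimuli)) {
    rlang::abort("Tuple indices must be pairwise distinct and within 1..K.")
  }
  mu <- moments$mu
  if (mu[i] == 0 || mu[k] == 0) rlang::abort("Zero mean at index i or k; estimator undefined.")
  if (abs(mu[k] - mu[i]) < tol * max(abs(mu))) {
    rlang::abort("Near-degenerate tuple: |mu_k - mu_i| below tolerance.")
  }
  fij <- composite_F(moments, i, j)
  fkl <- composite_F(moments, k, l)
  (mu[k]^2 * fij - mu[i]^2 * fkl) / (mu[k] * mu[i] * (1 + r_hat) * (mu[k] - mu[i]))
}

#' Pool size from one stimulus pair
#'
#' Evaluates `N = mu_i^2 / (mu_i q - F(i,j) / (1 + R))`. A non-positive
#' denominator signals a non-physical candidate (typically noise-driven)
#' and is reported as `NA` with `valid = FALSE` rather than returned as a
#' number.
#'
#' @inheritParams q_from_tuple
#' @param q_hat Quantal size (pA), typically the aggregated estimate.
#' @return A list with `N` (estimate or `NA`) and `valid` (logical).
#' @export
N_from_pair <- function(moments, i, j, q_hat, r_hat = 0) {
  if (i == j) rlang::abort("`i` and `j` must be distinct.")
  if (q_hat <= 0) rlang::abort("`q_hat` must be positive.")
  mu <- moments$mu
  denom <- mu[i] * q_hat - composite_F(moments, i, j) / (1 + r_hat)
  if (!is.finite(denom) || denom <= 0) {
    return(list(N = NA_real_, valid = FALSE))
  }
  list(N = mu[i]^2 / denom, valid = TRUE)
}

#' Release probability sequence from aggregated q and N
#'
#' `p_i = mu_i / (q N)`. Values outside `[0, 1]` are flagged, never
#' clipped, so downstream calibration sees the raw estimate.
#'
#' @param moments An [epsc_moments()] object.
#' @param q_hat,N_hat Positive quantal size (pA) and pool size.
#' @return A tibble with columns `stimulus`, `p_hat`, `out_of_range`.
#' @export
p_sequence <- function(moments, q_hat, N_hat) {
  if (q_hat <= 0 || N_hat <= 0) rlang::abort("`q_hat` and `N_hat` must be positive.")
  p <- moments$mu / (q_hat * N_hat)
  tibble::tibble(
    stimulus = seq_along(p),
    p_hat = p,
    out_of_range = p < 0 | p > 1
  )
}

# --- aggregation ------------------------------------------------------------

# Negative, non-finite and extreme q candidates are noise-induced outliers
# and removed before averaging. Extremes are identified with a two-sided
# robust 3-sigma band (median +/- 3 * scaled MAD): noise-dominated index
# combinations produce a symmetric heavy tail of blow-ups around the
# central cluster, so a mean/SD-based trim would not converge. The band is
# degenerate (keeps exact ties only) when all candidates agree, as on
# population moments.
aggregate_q <- function(q_candidates) {
  finite <- q_candidates[is.finite(q_candidates)]
  n_total <- length(q_candidates)
  if (length(finite) == 0) {
    rlang::abort(sprintf(
      "Quantal size estimation failed: all %d candidates rejected.", n_total
    ))
  }
  m <- stats::median(finite)
  s <- stats::mad(finite)
  kept <- finite[abs(finite - m) <= 3 * s & finite > 0]
  if (length(kept) == 0) {
    rlang::abort(sprintf(
      "Quantal size estimation failed: all %d candidates rejected (non-positive or extreme).",
      n_total
    ))
  }
  list(
    q_hat = mean(kept),
    q_sd = stats::sd(kept),
    n_rejected = n_total - length(kept),
    kept = kept
  )
}

# Finite positive N candidates, then a 3-sigma trim about the center of
# their empirical distribution (median +/- 3 * scaled MAD -- robust, since
# near-zero denominators give the candidate set a heavy upper tail), then
# the maximum of the survivors: covariance-based candidates tend to
# underestimate the effective pool, so the maximal stable value is taken.
aggregate_N <- function(N_candidates) {
  ok <- is.finite(N_candidates) & N_candidates > 0
  n_rej <- sum(!ok)
  vals <- N_candidates[ok]
  if (length(vals) == 0) {
    return(list(N_hat = NA_real_, n_rejected = n_rej, kept = numeric()))
  }
  if (length(vals) > 1) {
    s <- stats::mad(vals)
    if (is.finite(s) && s > 0) {
      inlier <- abs(vals - stats::median(vals)) <= 3 * s
      n_rej <- n_rej + sum(!inlier)
      vals <- vals[inlier]
    }
  }
  list(N_hat = max(vals), n_rejected = n_rej, kept = vals)
}

#' Moment-based estimation of q, N and the release probability sequence
#'
#' Runs the full closed-form estimation chain on a sweep matrix: moments,
#' optional quantal-variability ratio, quantal-size candidates over all
#' admissible index tuples, aggregation, pool-size candidates over all
#' ordered stimulus pairs, outlier rejection, and the release-probability
#' sequence. The `"fast"` branch assumes negligible sweep-level quantal
#' variability (R := 0); the `"detailed"` branch estimates R from the
#' cross-stimulus covariance and corrects both q and N by the factor
#' `(1 + R)`.
#'
#' @param data A [sweep_matrix()] or coercible data (sweeps x stimuli, pA).
#' @param sigma_eta2 Baseline noise variance (pA^2).
#' @param branch `"detailed"` (default) or `"fast"`.
#' @param tol Relative tolerance for exactly degenerate tuples; see
#'   [q_from_tuple()].
#' @param sep_se Admissibility multiplier for noise-dominated tuples: a
#'   tuple is rejected when `|mu_k - mu_i|` is below `sep_se` standard
#'   errors of the sample mean difference (default 4). Has no effect on
#'   population moments, where the standard error is zero.
#' @return An object of class `quantal_fit`; see [tidy.quantal_fit()] and
#'   [glance.quantal_fit()].
#' @examples
#' truth <- ground_truth(q_bar = 10, sigma_q = 0, N = 20,
#'                       p = c(0.1, 0.15, 0.2, 0.3, 0.35),
#'                       sigma_eta = 2, n_sweeps = 500, seed = 1)
#' fit <- quantal_estimate(simulate_sweeps(truth), sigma_eta2 = 4)
#' glance(fit)
#' @export
quantal_estimate <- function(data, sigma_eta2 = 0,
                             branch = c("detailed", "fast"), tol = 1e-6,
                             sep_se = 4) {
  branch <- match.arg(branch)
  a <- as_amplitude_matrix(data)
  if (ncol(a) < 4) {
    rlang::abort(sprintf(
      "Train too short: %d stimuli; at least 4 are required to form an admissible index tuple.",
      ncol(a)
    ))
  }
  moments <- epsc_moments(a, sigma_eta2)
  quantal_estimate_moments(moments, branch = branch, tol = tol, sep_se = sep_se)
}

#' Estimation chain operating on a pre-computed moment set
#'
#' Identical to [quantal_estimate()] but starting from an
#' [epsc_moments()] / [moment_set()] object, so exact population moments
#' can be pushed through the estimator algebra directly.
#'
#' @inheritParams quantal_estimate
#' @param moments An [epsc_moments()] object with K >= 4.
#' @return A `quantal_fit` object.
#' @export
quantal_estimate_moments <- function(moments, branch = c("detailed", "fast"),
                                     tol = 1e-6, sep_se = 4) {
  branch <- match.arg(branch)
  K <- moments$n_stimuli
  if (K < 4) {
    rlang::abort("Train too short: at least 4 stimuli are required.")
  }
  mu <- moments$mu
  if (any(mu == 0)) rlang::abort("All per-stimulus means must be non-zero.")

  r_hat <- if (branch == "detailed") quantal_cv_ratio(moments) else 0

  fmat <- composite_F_matrix(moments)
  tuples <- release_tuples(K)
  mu_i <- mu[tuples$i]
  mu_k <- mu[tuples$k]
  # A tuple is noise-dominated when the separation |mu_k - mu_i| in its
  # denominator is not resolved by the data: the sampling SE of the mean
  # difference is sqrt((var_k + var_i - 2 cov_ik) / T). Such tuples yield
  # reciprocal blow-ups and are rejected (on population moments, T = Inf,
  # the SE is zero and only exact degeneracy is excluded).
  se_diff <- sqrt(pmax(
    moments$var[tuples$k] + moments$var[tuples$i] -
      2 * moments$cov[cbind(tuples$k, tuples$i)], 0
  ) / moments$n_sweeps)
  degenerate <- abs(mu_k - mu_i) < pmax(tol * max(abs(mu)), sep_se * se_diff)
  fij <- fmat[cbind(tuples$i, tuples$j)]
  fkl <- fmat[cbind(tuples$k, tuples$l)]
  q_cand <- ifelse(
    degenerate, NA_real_,
    (mu_k^2 * fij - mu_i^2 * fkl) / (mu_k * mu_i * (1 + r_hat) * (mu_k - mu_i))
  )
  q_candidates <- dplyr::mutate(tuples, q = q_cand, degenerate = degenerate)
  q_agg <- aggregate_q(q_cand)

  # N candidates over all ordered pairs i != j, using the aggregated q
  pairs <- dplyr::filter(
    tidyr::expand_grid(i = seq_len(K), j = seq_len(K)),
    .data$i != .data$j
  )
  denom <- mu[pairs$i] * q_agg$q_hat - fmat[cbind(pairs$i, pairs$j)] / (1 + r_hat)
  N_cand <- ifelse(is.finite(denom) & denom > 0, mu[pairs$i]^2 / denom, NA_real_)
  N_candidates <- dplyr::mutate(pairs, N = N_cand)
  N_agg <- aggregate_N(N_cand)

  p_tab <- if (is.finite(N_agg$N_hat)) {
    p_sequence(moments, q_agg$q_hat, N_agg$N_hat)
  } else {
    tibble::tibble(stimulus = integer(), p_hat = numeric(), out_of_range = logical())
  }

  structure(
    list(
      q_hat = q_agg$q_hat,
      q_sd = q_agg$q_sd,
      N_hat = N_agg$N_hat,
      p_hat = p_tab$p_hat,
      p_out_of_range = p_tab$out_of_range,
      R_hat = r_hat,
      branch = branch,
      n_rejected_q = q_agg$n_rejected,
      n_rejected_N = N_agg$n_rejected,
      n_candidates_q = nrow(q_candidates),
      n_candidates_N = nrow(N_candidates),
      q_candidates = q_candidates,
      N_candidates = N_candidates,
      moments = moments
    ),
    class = "quantal_fit"
  )
}

#' @export
print.quantal_fit <- function(x, ...) {
  cat(sprintf(
    "<quantal_fit> branch = %s\n  q_hat = %.4g pA (SD %.3g, %d/%d candidates kept)\n  N_hat = %s (%d candidates rejected)\n  R_hat = %.4g\n",
    x$branch, x$q_hat, x$q_sd,
    x$n_candidates_q - x$n_rejected_q, x$n_candidates_q,
    if (is.finite(x$N_hat)) sprintf("%.4g", x$N_hat) else "unavailable",
    x$n_rejected_N, x$R_hat
  ))
  if (length(x$p_hat)) {
    cat("  p_hat: ", paste(signif(x$p_hat, 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' Tidy a moment-based quantal fit
#'
#' @param x A `quantal_fit` from [quantal_estimate()].
#' @param ... Unused.
#' @return Per-stimulus tibble with `stimulus`, `mean_pA`, `p_hat`,
#'   `out_of_range`.
#' @method tidy quantal_fit
#' @export
tidy.quantal_fit <- function(x, ...) {
  tibble::tibble(
    stimulus = seq_len(x$moments$n_stimuli),
    mean_pA = x$moments$mu,
    p_hat = if (length(x$p_hat)) x$p_hat else NA_real_,
    out_of_range = if (length(x$p_hat)) x$p_out_of_range else NA
  )
}

#' One-row summary of a moment-based quantal fit
#'
#' @inheritParams tidy.quantal_fit
#' @return A one-row tibble: `q_hat`, `q_sd`, `N_hat`, `R_hat`, `branch`,
#'   rejection counts, `n_stimuli`, `n_sweeps`.
#' @method glance quantal_fit
#' @export
glance.quantal_fit <- function(x, ...) {
  tibble::tibble(
    q_hat = x$q_hat, q_sd = x$q_sd, N_hat = x$N_hat, R_hat = x$R_hat,
    branch = x$branch,
    n_rejected_q = x$n_rejected_q, n_rejected_N = x$n_rejected_N,
    n_stimuli = x$moments$n_stimuli, n_sweeps = x$moments$n_sweeps
  )
}

#' Serialize an estimate to the JSON result schema
#'
#' @param x A `quantal_fit`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or a JSON string.
#' @export
write_estimate_json <- function(x, path = NULL) {
  out <- list(
    q_hat = x$q_hat, q_sd = x$q_sd, N_hat = x$N_hat,
    p_hat = x$p_hat, R_hat = x$R_hat, branch = x$branch,
    n_rejected_q = x$n_rejected_q, n_rejected_N = x$n_rejected_N,
    K = x$moments$n_stimuli, T = x$moments$n_sweeps
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null"))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
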