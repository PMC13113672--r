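#' Bias, RMSE and SD of a set of estimates
#'
#' Standard recovery metrics: `bias = mean(est) - truth`,
#' `RMSE = sqrt(mean((est - truth)^2))`, and the sample SD of the
#' estimates. For a vector-valued parameter (the release probability
#' sequence) pass a replicates x indices matrix and a truth vector; metrics
#' are computed per index and averaged.
#'
#' @param estimates Numeric vector (one estimate per replicate) or matrix
#'   (replicates x stimulus indices).
#' @param truth Scalar truth, or length-K vector for matrix input.
#' @return A one-row tibble with `bias`, `rmse`, `sd`, `n`.
#' @examples
#' compute_bias_rmse(c(9, 11), 10) # bias 0, rmse 1, sd sqrt(2)
#' @export
compute_bias_rmse <- function(estimates, truth) {
  if (is.matrix(estimates)) {
    keep <- stats::complete.cases(estimates)
    m <- estimates[keep, , drop = FALSE]
    if (nrow(m) == 0) rlang::abort("No finite estimates supplied.")
    per_idx <- purrr::map(seq_len(ncol(m)), function(j) {
      compute_bias_rmse(m[, j], truth[j])
    })
    tab <- dplyr::bind_rows(per_idx)
    return(tibble::tibble(
      bias = mean(tab$bias), rmse = mean(tab$rmse),
      sd = mean(tab$sd), n = nrow(m)
    ))
  }
  est <- estimates[is.finite(estimates)]
  if (length(est) == 0) rlang::abort("No finite estimates supplied.")
  tibble::tibble(
    bias = mean(est) - truth,
    rmse = sqrt(mean((est - truth)^2)),
    sd = if (length(est) > 1) stats::sd(est) else 0,
    n = length(est)
  )
}

# Replicate seeds derived deterministically from the master seed, kept
# within 32-bit integer range.
replicate_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Simulate one cell under `truth` and estimate with the requested methods.
# Never aborts: per-replicate errors are recorded as failures.
run_one_cell <- function(truth, methods, branch, heterogeneous = FALSE) {
  sm <- if (heterogeneous) simulate_heterogeneous(truth) else simulate_sweeps(truth)
  s2 <- truth$sigma_eta^2
  purrr::map(methods, function(m) {
    res <- tryCatch(
      {
        if (m == "me") {
          fit <- suppressWarnings(quantal_estimate(sm, sigma_eta2 = s2, branch = branch))
          list(q = fit$q_hat, N = fit$N_hat,
               p = if (length(fit$p_hat)) fit$p_hat else rep(NA_real_, truth$n_stimuli),
               reject_N = fit$n_rejected_N / fit$n_candidates_N,
               mu = fit$moments$mu)
        } else {
          fit <- vm_estimate(epsc_moments(sm, s2))
          list(q = fit$q_vm, N = fit$N_vm, p = fit$p_vm, reject_N = 0,
               mu = fit$mu)
        }
      },
      error = function(e) list(q = NA_real_, N = NA_real_,
                               p = rep(NA_real_, truth$n_stimuli),
                               reject_N = NA_real_, mu = NULL)
    )
    tibble::tibble(
      method = m, q = res$q, N = res$N, p = list(res$p),
      reject_N = res$reject_N, mu = list(res$mu)
    )
  }) |> dplyr::bind_rows()
}

# Score a condition's replicate estimates into report rows.
score_condition <- function(reps, truth, condition, label) {
  purrr::map(unique(reps$method), function(m) {
    sub <- dplyr::filter(reps, .data$method == m)
    q_row <- tryCatch(compute_bias_rmse(sub$q, truth$q_bar), error = function(e) NULL)
    N_row <- tryCatch(compute_bias_rmse(sub$N, truth$N), error = function(e) NULL)
    p_mat <- do.call(rbind, sub$p)
    p_row <- tryCatch(compute_bias_rmse(p_mat, truth$p), error = function(e) NULL)
    empty <- tibble::tibble(bias = NA_real_, rmse = NA_real_, sd = NA_real_, n = 0L)
    rows <- dplyr::bind_rows(
      (q_row %||% empty),
      (N_row %||% empty),
      (p_row %||% empty)
    )
    tibble::tibble(
      condition = condition, condition_label = label,
      estimator = toupper(m),
      parameter = c("q", "N", "p"),
      bias = rows$bias, rmse = rows$rmse, sd = rows$sd,
      n_replicates = nrow(sub),
      n_failures = c(sum(!is.finite(sub$q)), sum(!is.finite(sub$N)),
                     sum(!vapply(sub$p, function(v) all(is.finite(v)), logical(1)))),
      reject_rate_N = mean(sub$reject_N, na.rm = TRUE)
    )
  }) |> dplyr::bind_rows()
}

# Shared driver for the sensitivity sweeps: `truth_fn(value, seed)` builds
# the per-replicate ground truth for one condition value. The same
# replicate seeds are reused across condition values (common random
# numbers), so across-condition trends are paired comparisons rather than
# independent Monte Carlo draws.
run_sweep <- function(values, label, truth_fn, n_replicates, seed,
                      methods = "me", branch = "detailed",
                      heterogeneous = FALSE) {
  seeds <- replicate_seeds(seed, n_replicates)
  out <- purrr::map(values, function(v) {
    reps <- purrr::map(seq_len(n_replicates), function(r) {
      truth <- truth_fn(v, seeds[r])
      run_one_cell(truth, methods, branch,
                   heterogeneous = heterogeneous)
    }) |> dplyr::bind_rows()
    score_condition(reps, truth_fn(v, 1L), v, label)
  }) |> dplyr::bind_rows()
  attr(out, "seed") <- seed
  class(out) <- c("recovery_report", class(out))
  out
}

#' Sensitivity of parameter recovery to measurement noise
#'
#' Simulates replicate cells at increasing noise levels, scaled relative to
#' the mean first-stimulus EPSC amplitude of the scenario (the quantity the
#' recordings anchor at 10-50 pA), and scores bias / RMSE / SD of the
#' recovered q, N and release probabilities.
#' Per-replicate estimation errors are recorded as failures and never abort
#' the sweep; everything is deterministic given `seed`.
#'
#' @param scenario A [ground_truth()] template (e.g. [scenario_stf()]);
#'   its `sigma_eta` is overridden per condition.
#' @param noise_fractions Noise SD as a fraction of the mean first-stimulus
#'   EPSC amplitude (default `c(0, 0.1, 0.2, 0.3, 0.5)`).
#' @param n_replicates Simulated cells per condition (default 200).
#' @param seed Master seed.
#' @param methods Character subset of `c("me", "vm")`.
#' @param branch Estimation branch for the ME method.
#' @return A `recovery_report` tibble: one row per condition x estimator x
#'   parameter with `bias`, `rmse`, `sd`, failure counts and the mean
#'   fraction of rejected pool-size candidates.
#' @export
run_noise_sweep <- function(scenario, noise_fractions = c(0, 0.1, 0.2, 0.3, 0.5),
                            n_replicates = 200, seed = 1L,
                            methods = "me", branch = "detailed") {
  mean_epsc <- scenario$q_bar * scenario$N * scenario$p[1]
  truth_fn <- function(frac, s) {
    ground_truth(
      q_bar = scenario$q_bar, sigma_q = scenario$sigma_q, N = scenario$N,
      p = scenario$p, sigma_eta = frac * mean_epsc,
      n_sweeps = scenario$n_sweeps, frequency_hz = scenario$frequency_hz,
      seed = s
    )
  }
  run_sweep(noise_fractions, "noise_fraction", truth_fn, n_replicates, seed,
            methods = methods, branch = branch)
}

#' Sensitivity to sweep-level quantal variability
#'
#' Varies the quantal coefficient of variation `sigma_q / q_bar` over
#' `cv_values` (the supported range is 0 to 0.5) and scores recovery with
#' the detailed branch (or the branch requested).
#'
#' @inheritParams run_noise_sweep
#' @param cv_values Quantal CV values in `[0, 0.5]`.
#' @return A `recovery_report` tibble.
#' @export
run_quantal_variability_sweep <- function(scenario, cv_values = c(0, 0.2, 0.4),
                                          n_replicates = 200, seed = 1L,
                                          methods = "me", branch = "detailed") {
  truth_fn <- function(cv, s) {
    ground_truth(
      q_bar = scenario$q_bar, sigma_q = cv * scenario$q_bar, N = scenario$N,
      p = scenario$p, sigma_eta = scenario$sigma_eta,
      n_sweeps = scenario$n_sweeps, frequency_hz = scenario$frequency_hz,
      seed = s
    )
  }
  run_sweep(cv_values, "quantal_cv", truth_fn, n_replicates, seed,
            methods = methods, branch = branch)
}

#' Sensitivity to the number of sweeps
#'
#' Varies the sweep count T at fixed truth; moment sampling error shrinks
#' as 1/sqrt(T), so the SD of the recovered q should fall accordingly and
#' the pool-size outlier rate should drop.
#'
#' @inheritParams run_noise_sweep
#' @param T_values Sweep counts to test.
#' @return A `recovery_report` tibble.
#' @export
run_sweep_count_sweep <- function(scenario, T_values = c(20, 80, 320),
                                  n_replicates = 200, seed = 1L,
                                  methods = "me", branch = "detailed") {
  truth_fn <- function(Tn, s) {
    ground_truth(
      q_bar = scenario$q_bar, sigma_q = scenario$sigma_q, N = scenario$N,
      p = scenario$p, sigma_eta = scenario$sigma_eta,
      n_sweeps = Tn, frequency_hz = scenario$frequency_hz, seed = s
    )
  }
  run_sweep(T_values, "n_sweeps", truth_fn, n_replicates, seed,
            methods = methods, branch = branch)
}

#' Moment-based vs variance-mean method comparison
#'
#' Runs both estimators on replicate cells simulated under a facilitating
#' (STF) and a depressing (STD) scenario and reports Table-style
#' bias / RMSE / SD for q, N and p in each regime.
#'
#' @param stf_scenario,std_scenario [ground_truth()] templates; defaults
#'   [scenario_stf()] / [scenario_std()].
#' @inheritParams run_noise_sweep
#' @return A `recovery_report` tibble with conditions `"STF"` and `"STD"`.
#' @export
run_method_comparison <- function(stf_scenario = scenario_stf(),
                                  std_scenario = scenario_std(),
                                  n_replicates = 200, seed = 1L,
                                  branch = "detailed") {
  scenarios <- list(STF = stf_scenario, STD = std_scenario)
  out <- purrr::imap(scenarios, function(sc, nm) {
    truth_fn <- function(v, s) {
      ground_truth(
        q_bar = sc$q_bar, sigma_q = sc$sigma_q, N = sc$N, p = sc$p,
        sigma_eta = sc$sigma_eta, n_sweeps = sc$n_sweeps,
        frequency_hz = sc$frequency_hz, seed = s
      )
    }
    rep <- run_sweep(nm, "regime", truth_fn, n_replicates,
                     seed + match(nm, names(scenarios)),
                     methods = c("me", "vm"), branch = branch)
    rep
  }) |> dplyr::bind_rows()
  attr(out, "seed") <- seed
  class(out) <- unique(c("recovery_report", class(out)))
  out
}

#' Calibration dispersion study
#'
#' Simulates facilitating cells, estimates (q, N) by moments, then
#' calibrates the pool size against each cell's mean trajectory with the
#' T-M model. Returns per-cell uncalibrated and calibrated pool sizes plus
#' the calibrated release sequence, to quantify the dispersion reduction
#' the calibration provides.
#'
#' @param scenario A facilitating [ground_truth()] template. The default
#'   uses 80 sweeps per cell: pool-size-related quantities need longer
#'   recordings than the quantal size (which stabilizes by 20-30 sweeps),
#'   so calibration studies follow the >= 80 sweep recommendation.
#' @param n_cells Number of simulated cells.
#' @param seed Master seed.
#' @param n_starts Multistart count passed to [calibrate_tm()].
#' @return A tibble with one row per cell: `q_hat`, `N_me`, `N_cal`,
#'   `p_cal` (list column), `sse`.
#' @export
run_calibration_study <- function(scenario = scenario_stf(n_sweeps = 80),
                                  n_cells = 100, seed = 1L, n_starts = 10) {
  seeds <- replicate_seeds(seed, n_cells)
  dt <- if (!is.null(scenario$tm)) scenario$tm$dt else 1000 / scenario$frequency_hz
  purrr::map(seq_len(n_cells), function(i) {
    truth <- ground_truth(
      q_bar = scenario$q_bar, sigma_q = scenario$sigma_q, N = scenario$N,
      p = scenario$p, sigma_eta = scenario$sigma_eta,
      n_sweeps = scenario$n_sweeps, frequency_hz = scenario$frequency_hz,
      seed = seeds[i]
    )
    sm <- simulate_sweeps(truth)
    out <- tryCatch(
      {
        fit <- suppressWarnings(quantal_estimate(sm, sigma_eta2 = truth$sigma_eta^2))
        cal <- calibrate_tm(fit$moments$mu, fit$q_hat, dt = dt,
                            n_starts = n_starts, seed = seeds[i])
        tibble::tibble(
          cell = i, q_hat = fit$q_hat, N_me = fit$N_hat,
          N_cal = cal$params$N_cal, p_cal = list(cal$state$p_seq),
          sse = cal$sse
        )
      },
      error = function(e) tibble::tibble(
        cell = i, q_hat = NA_real_, N_me = NA_real_, N_cal = NA_real_,
        p_cal = list(rep(NA_real_, scenario$n_stimuli)), sse = NA_real_
      )
    )
    out
  }) |> dplyr::bind_rows()
}

#' Recovery under release-site heterogeneity
#'
#' Simulates cells with site-to-site variability in quantal size and/or
#' release probability and scores the resulting estimation biases. The
#' conditions mirror the heterogeneity study settings: site SDs
#' `sigma_q_site = 2` pA and `sigma_p_site = 0.05`.
#'
#' @param scenario A [ground_truth()] template.
#' @param conditions Character subset of
#'   `c("ideal", "q_site", "p_site", "both")`.
#' @param sigma_q_site,sigma_p_site Site-level SDs applied in the
#'   heterogeneous conditions.
#' @inheritParams run_noise_sweep
#' @return A `recovery_report` tibble, one condition per heterogeneity
#'   setting.
#' @export
run_heterogeneity_sweep <- function(scenario = scenario_stf(n_sweeps = 200),
                                    conditions = c("ideal", "q_site", "p_site", "both"),
                                    sigma_q_site = 2, sigma_p_site = 0.05,
                                    n_replicates = 100, seed = 1L,
                                    branch = "detailed") {
  truth_fn <- function(cond, s) {
    ground_truth(
      q_bar = scenario$q_bar, sigma_q = 0, N = scenario$N, p = scenario$p,
      sigma_eta = scenario$sigma_eta, n_sweeps = scenario$n_sweeps,
      het_sigma_q_site = if (cond %in% c("q_site", "both")) sigma_q_site else 0,
      het_sigma_p_site = if (cond %in% c("p_site", "both")) sigma_p_site else 0,
      frequency_hz = scenario$frequency_hz, seed = s
    )
  }
  run_sweep(conditions, "heterogeneity", truth_fn, n_replicates, seed,
            methods = "me", branch = branch, heterogeneous = TRUE)
}
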