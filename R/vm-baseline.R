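#' Classical variance-mean (VM) quantal analysis baseline
#'
#' Fits the noise-corrected parabola of the stationary binomial model,
#' `Var(A_i) - sigma_eta^2 = q mu_i - mu_i^2 / N`, by unweighted least
#' squares over the stimulus indices, treating each stimulus position as
#' one (mean, variance) condition. The quantal size is the linear
#' coefficient and the pool size the negative reciprocal of the quadratic
#' coefficient. The method deliberately ignores cross-stimulus covariance:
#' structured sweep-level fluctuation therefore leaks into the variance
#' term and biases the fit under facilitation with quantal variability,
#' which is precisely the deficiency the moment-based estimators address.
#'
#' @param moments An [epsc_moments()] object with K >= 2 stimuli and at
#'   least 2 distinct means.
#' @return An object of class `vm_fit` with `q_vm` (pA), `N_vm` (or `NA`
#'   with `non_physical = TRUE` when the quadratic coefficient is
#'   non-negative), `p_vm` (length-K), and `fit_residual` (residual sum of
#'   squares, pA^4 scale).
#' @examples
#' truth <- ground_truth(q_bar = 10, sigma_q = 0, N = 20,
#'                       p = c(0.1, 0.15, 0.2, 0.3, 0.35), sigma_eta = 2)
#' vm_estimate(analytic_moments(truth)) # exact: q = 10, N = 20
#' @export
vm_estimate <- function(moments) {
  stopifnot(inherits(moments, "epsc_moments"))
  mu <- moments$mu
  if (length(unique(mu)) < 2) {
    rlang::abort("VM fit needs at least 2 distinct per-stimulus means.")
  }
  y <- moments$var - moments$sigma_eta2
  fit <- stats::lm(y ~ 0 + mu + I(mu^2))
  b <- unname(stats::coef(fit))
  q_vm <- b[1]
  non_physical <- !is.finite(b[2]) || b[2] >= 0
  N_vm <- if (non_physical) NA_real_ else -1 / b[2]
  p_vm <- if (non_physical || q_vm <= 0) rep(NA_real_, length(mu)) else mu / (q_vm * N_vm)
  structure(
    list(
      q_vm = q_vm, N_vm = N_vm, p_vm = p_vm,
      fit_residual = sum(stats::residuals(fit)^2),
      non_physical = non_physical,
      mu = mu, corrected_var = y
    ),
    class = "vm_fit"
  )
}

#' @export
print.vm_fit <- function(x, ...) {
  cat(sprintf(
    "<vm_fit> q_vm = %.4g pA, N_vm = %s, residual = %.3g%s\n",
    x$q_vm,
    if (is.finite(x$N_vm)) sprintf("%.4g", x$N_vm) else "unavailable",
    x$fit_residual,
    if (x$non_physical) " [non-physical quadratic coefficient]" else ""
  ))
  invisible(x)
}

#' Tidy / summarize a VM baseline fit
#'
#' @param x A `vm_fit` from [vm_estimate()].
#' @param ... Unused.
#' @return `tidy()`: per-stimulus tibble of mean, noise-corrected variance
#'   and `p_vm`. `glance()`: one-row summary.
#' @method tidy vm_fit
#' @export
tidy.vm_fit <- function(x, ...) {
  tibble::tibble(
    stimulus = seq_along(x$mu),
    mean = x$mu,
    corrected_var = x$corrected_var,
    p_vm = x$p_vm
  )
}

#' @rdname tidy.vm_fit
#' @method glance vm_fit
#' @export
glance.vm_fit <- function(x, ...) {
  tibble::tibble(
    q_vm = x$q_vm, N_vm = x$N_vm,
    fit_residual = x$fit_residual, non_physical = x$non_physical,
    method = "VM"
  )
}
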