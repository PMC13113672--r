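#' Raw current trace container
#'
#' Holds voltage-clamp current traces from which EPSC peak amplitudes are
#' extracted: one row per sweep, one column per time sample (pA), plus the
#' sampling rate and stimulus onset times.
#'
#' @param traces S x M numeric matrix (sweeps x samples, pA).
#' @param sampling_rate_hz Sampling rate > 0 (recordings are typically
#'   acquired at 20 kHz).
#' @param stimulus_onsets_ms Strictly increasing onset times (ms) within
#'   the trace duration.
#' @param sign_convention `"inward-negative"` (EPSCs at -70 mV are inward,
#'   negative-going; default) or `"magnitude"` (already positive).
#' @return A list of class `raw_traces`.
#' @export
raw_traces <- function(traces, sampling_rate_hz, stimulus_onsets_ms,
                       sign_convention = c("inward-negative", "magnitude")) {
  sign_convention <- match.arg(sign_convention)
  traces <- as.matrix(traces)
  if (sampling_rate_hz <= 0) rlang::abort("`sampling_rate_hz` must be positive.")
  if (any(diff(stimulus_onsets_ms) <= 0)) {
    rlang::abort("`stimulus_onsets_ms` must be strictly increasing.")
  }
  dur_ms <- (ncol(traces) - 1) * 1000 / sampling_rate_hz
  if (min(stimulus_onsets_ms) < 0 || max(stimulus_onsets_ms) > dur_ms) {
    rlang::abort("Stimulus onsets must lie within the trace duration.")
  }
  structure(
    list(
      traces = traces,
      sampling_rate_hz = sampling_rate_hz,
      stimulus_onsets_ms = as.numeric(stimulus_onsets_ms),
      sign_convention = sign_convention
    ),
    class = "raw_traces"
  )
}

#' @export
print.raw_traces <- function(x, ...) {
  cat(sprintf(
    "<raw_traces> %d sweeps x %d samples @ %g kHz, %d stimuli, %s convention\n",
    nrow(x$traces), ncol(x$traces), x$sampling_rate_hz / 1000,
    length(x$stimulus_onsets_ms), x$sign_convention
  ))
  invisible(x)
}

#' Read raw traces from CSV + JSON metadata
#'
#' CSV rows are sweeps, columns are time samples (no header); the metadata
#' JSON carries `sampling_rate_hz`, `stimulus_onsets_ms` and
#' `sign_convention`.
#'
#' @param path Trace CSV path.
#' @param metadata Metadata JSON path (default `<path>.json`).
#' @return A [raw_traces()] object.
#' @export
read_trace_csv <- function(path, metadata = paste0(path, ".json")) {
  m <- as.matrix(readr::read_csv(path, col_names = FALSE,
                                 show_col_types = FALSE, progress = FALSE))
  meta <- jsonlite::read_json(metadata, simplifyVector = TRUE)
  raw_traces(m, sampling_rate_hz = meta$sampling_rate_hz,
             stimulus_onsets_ms = meta$stimulus_onsets_ms,
             sign_convention = meta$sign_convention %||% "inward-negative")
}

#' Sliding-window median filter with zero-padded edges
#'
#' Running median used to smooth raw traces before peak detection. Edges
#' are handled by zero-padding, mirroring the default behaviour of the
#' classic one-dimensional median filter routine; `window = 1` is the
#' identity.
#'
#' @param trace Numeric vector (one sweep's samples).
#' @param window Odd positive window length, at most the trace length.
#' @return Filtered numeric vector of the same length.
#' @examples
#' median_filter_trace(c(0, 100, 0), 3) # 0 0 0
#' @export
median_filter_trace <- function(trace, window) {
  n <- length(trace)
  if (window < 1 || window %% 2 == 0) rlang::abort("`window` must be odd and positive.")
  if (window > n) rlang::abort("`window` exceeds the trace length.")
  if (window == 1) return(trace)
  h <- (window - 1) / 2
  padded <- c(rep(0, h), trace, rep(0, h))
  out <- stats::runmed(padded, window, endrule = "keep")
  out[(h + 1):(h + n)]
}

#' Baseline noise variance from the pre-stimulus window
#'
#' The noise variance `sigma_eta^2` entering the composite observable is
#' measured from the resting baseline preceding the stimulus train: the
#' per-sweep sample variance of the samples inside `baseline_window`,
#' averaged over sweeps.
#'
#' @param traces A [raw_traces()] object.
#' @param baseline_window Length-2 numeric `(t0, t1)` in ms; must end at or
#'   before the first stimulus onset and contain at least 2 samples.
#' @return Noise variance in pA^2.
#' @export
estimate_noise_variance <- function(traces, baseline_window) {
  stopifnot(inherits(traces, "raw_traces"))
  t0 <- baseline_window[1]; t1 <- baseline_window[2]
  if (t1 > traces$stimulus_onsets_ms[1]) {
    rlang::abort("`baseline_window` must precede the first stimulus onset.")
  }
  dt_ms <- 1000 / traces$sampling_rate_hz
  idx <- which(seq(0, by = dt_ms, length.out = ncol(traces$traces)) >= t0 &
                 seq(0, by = dt_ms, length.out = ncol(traces$traces)) <= t1)
  if (length(idx) < 2) rlang::abort("`baseline_window` must contain at least 2 samples.")
  mean(apply(traces$traces[, idx, drop = FALSE], 1, stats::var))
}

#' Extract EPSC peak amplitudes from raw traces
#'
#' Reproduces the standard peak-extraction procedure: traces are
#' sign-normalized to positive EPSC magnitude, median-filtered, and for
#' each stimulus the amplitude is the maximum within the inter-stimulus
#' window (starting `blank_ms` after the onset, to skip the stimulus
#' artifact) minus the pre-train baseline level (the mean over the
#' baseline window). The final window extends one inter-stimulus interval
#' past the last onset.
#'
#' @param traces A [raw_traces()] object with K >= 1 onsets.
#' @param filter_window Odd median-filter window in samples (default 5).
#' @param blank_ms Post-onset artifact blanking in ms (default 2).
#' @param baseline_window Length-2 `(t0, t1)` ms for the baseline level;
#'   defaults to the whole pre-train segment `(0, first onset)`.
#' @return A [sweep_matrix()] (sweeps x stimuli, pA).
#' @export
extract_epsc_peaks <- function(traces, filter_window = 5, blank_ms = 2,
                               baseline_window = NULL) {
  stopifnot(inherits(traces, "raw_traces"))
  onsets <- traces$stimulus_onsets_ms
  K <- length(onsets)
  dt_ms <- 1000 / traces$sampling_rate_hz
  t_ms <- seq(0, by = dt_ms, length.out = ncol(traces$traces))
  if (is.null(baseline_window)) baseline_window <- c(0, onsets[1])
  if (baseline_window[2] > onsets[1]) {
    rlang::abort("`baseline_window` must precede the first stimulus onset.")
  }
  base_idx <- which(t_ms >= baseline_window[1] & t_ms <= baseline_window[2])
  if (length(base_idx) < 1) rlang::abort("Empty baseline window.")

  isi <- if (K > 1) diff(onsets) else 2 * blank_ms
  win_end <- c(onsets[-1], onsets[K] + mean(isi))

  m <- traces$traces
  if (traces$sign_convention == "inward-negative") m <- -m

  amps <- matrix(NA_real_, nrow(m), K)
  for (s in seq_len(nrow(m))) {
    tr <- median_filter_trace(m[s, ], filter_window)
    baseline <- mean(tr[base_idx])
    for (i in seq_len(K)) {
      idx <- which(t_ms >= onsets[i] + blank_ms & t_ms <= win_end[i])
      if (length(idx) == 0) rlang::abort("Empty peak window; check onsets and blanking.")
      amps[s, i] <- max(tr[idx]) - baseline
    }
  }
  freq <- if (K > 1) 1000 / mean(diff(onsets)) else NULL
  sweep_matrix(amps, frequency_hz = freq)
}
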