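#' Construct a sweep matrix of EPSC peak amplitudes
#'
#' The canonical input of the moment-based estimators: a T x K table of EPSC
#' peak amplitudes (pA), one row per sweep (repetition of the stimulus train)
#' and one column per stimulus position. Amplitudes follow a magnitude
#' convention: positive values denote EPSC size, with inward (negative)
#' currents sign-flipped at ingestion.
#'
#' @param data A data frame or matrix of amplitudes, sweeps in rows and
#'   stimuli in columns. Data-frame columns named `stim_1 ... stim_K` are
#'   used in index order; otherwise all numeric columns are taken as given.
#' @param frequency_hz Optional stimulation frequency (Hz); the
#'   inter-stimulus interval in ms is derived as `1000 / frequency_hz`.
#' @return A tibble of class `sweep_matrix` with columns `stim_1 ... stim_K`
#'   and attributes `frequency_hz` and `isi_ms`.
#' @examples
#' sweep_matrix(matrix(c(2, 4, 4, 8), nrow = 2, byrow = TRUE))
#' @export
sweep_matrix <- function(data, frequency_hz = NULL) {
  m <- as_amplitude_matrix(data)
  if (nrow(m) < 2L) {
    rlang::abort("A sweep matrix needs at least 2 sweeps (sample covariance requires T >= 2).")
  }
  if (!all(is.finite(m))) {
    rlang::abort("All EPSC amplitudes must be finite.")
  }
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- paste0("stim_", seq_len(ncol(m)))
  attr(out, "frequency_hz") <- frequency_hz
  attr(out, "isi_ms") <- if (is.null(frequency_hz)) NULL else 1000 / frequency_hz
  class(out) <- c("sweep_matrix", class(out))
  out
}

# Coerce data frame / matrix input to a bare numeric matrix, honouring
# stim_* column naming when present.
as_amplitude_matrix <- function(data) {
  if (inherits(data, "sweep_matrix")) {
    data <- as.data.frame(unclass(data), check.names = FALSE)
  }
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    return(unname(data))
  }
  if (is.data.frame(data)) {
    stim_cols <- grep("^stim_[0-9]+$", names(data), value = TRUE)
    if (length(stim_cols) > 0) {
      ord <- order(as.integer(sub("^stim_", "", stim_cols)))
      data <- data[stim_cols[ord]]
    } else {
      data <- data[vapply(data, is.numeric, logical(1))]
    }
    if (ncol(data) == 0) rlang::abort("No numeric amplitude columns found.")
    return(unname(as.matrix(data)))
  }
  rlang::abort("`data` must be a data frame or numeric matrix of amplitudes.")
}

#' @export
print.sweep_matrix <- function(x, ...) {
  f <- attr(x, "frequency_hz")
  cat(sprintf(
    "<sweep_matrix> %d sweeps x %d stimuli%s\n",
    nrow(x), ncol(x),
    if (is.null(f)) "" else sprintf(" @ %g Hz (ISI %g ms)", f, 1000 / f)
  ))
  NextMethod()
}

#' Read / write the sweep-matrix CSV interchange format
#'
#' One row per sweep, one column per stimulus with header `stim_1 ... stim_K`,
#' values in pA. An optional JSON sidecar carries `frequency_hz` and
#' `sigma_eta2` (baseline noise variance, pA^2).
#'
#' @param path Path to the CSV file.
#' @param sidecar Path to the JSON sidecar; defaults to `<path>.json` when
#'   that file exists.
#' @return `read_sweep_csv()`: a [sweep_matrix()] with attribute
#'   `sigma_eta2` when the sidecar provides it. `write_sweep_csv()`: `path`,
#'   invisibly.
#' @export
read_sweep_csv <- function(path, sidecar = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(sidecar)) {
    candidate <- paste0(path, ".json")
    if (file.exists(candidate)) sidecar <- candidate
  }
  meta <- if (!is.null(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  sm <- sweep_matrix(df, frequency_hz = meta$frequency_hz)
  if (!is.null(meta$sigma_eta2)) attr(sm, "sigma_eta2") <- meta$sigma_eta2
  sm
}

#' @rdname read_sweep_csv
#' @param x A [sweep_matrix()] (or coercible data).
#' @param sigma_eta2 Optional noise variance to record in the sidecar.
#' @export
write_sweep_csv <- function(x, path, sidecar = NULL, sigma_eta2 = NULL) {
  sm <- if (inherits(x, "sweep_matrix")) x else sweep_matrix(x)
  readr::write_csv(tibble::as_tibble(unclass(sm)[seq_along(sm)]), path, progress = FALSE)
  meta <- list()
  if (!is.null(attr(sm, "frequency_hz"))) meta$frequency_hz <- attr(sm, "frequency_hz")
  if (!is.null(sigma_eta2)) meta$sigma_eta2 <- sigma_eta2
  if (length(meta) > 0) {
    if (is.null(sidecar)) sidecar <- paste0(path, ".json")
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
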