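#' Uniformly sampled physiological waveform
#'
#' A waveform is a tibble with columns `time_s` and `value` plus a sampling
#' rate and a units label. It is the universal carrier for arterial blood
#' pressure (mmHg), cerebral blood flow velocity (cm/s), cerebral blood flow
#' (ml/s) and intracranial pressure (mmHg) traces throughout the package.
#'
#' @param value numeric vector of samples.
#' @param fs sampling rate in samples per second.
#' @param t0 time of the first sample in seconds.
#' @param units units label, e.g. `"mmHg"`, `"cm/s"`, `"ml/s"`.
#' @return A tibble of class `nicp_wave` with columns `time_s`, `value` and
#'   attributes `fs` and `units`.
#' @examples
#' w <- waveform(90 + sin(2 * pi * seq(0, 5, by = 0.01)), fs = 100, units = "mmHg")
#' wave_fs(w)
#' @export
waveform <- function(value, fs, t0 = 0, units = "") {
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop_input("`fs` must be a single positive number.")
  }
  value <- as.numeric(value)
  if (length(value) < 2) stop_input("A waveform needs at least 2 samples.")
  if (!all(is.finite(value))) stop_input("Waveform samples must all be finite.")
  out <- tibble(time_s = t0 + (seq_along(value) - 1) / fs, value = value)
  structure(out,
    fs = fs, units = units,
    class = c("nicp_wave", class(out))
  )
}

#' @rdname waveform
#' @param x a `nicp_wave`, or any data frame with `time_s` and `value`
#'   columns on a uniform time grid (the rate is then inferred).
#' @export
as_waveform <- function(x, units = NULL) {
  if (inherits(x, "nicp_wave")) {
    if (!is.null(units)) attr(x, "units") <- units
    return(x)
  }
  if (!is.data.frame(x) || !all(c("time_s", "value") %in% names(x))) {
    stop_input("Expected a data frame with columns `time_s` and `value`.")
  }
  fs <- infer_fs(x$time_s)
  waveform(x$value, fs = fs, t0 = x$time_s[1], units = units %||% "")
}

#' @rdname waveform
#' @export
wave_fs <- function(x) attr(x, "fs") %||% infer_fs(x$time_s)

#' @rdname waveform
#' @export
wave_units <- function(x) attr(x, "units") %||% ""

wave_t0 <- function(x) x$time_s[1]

# Sampling rate from a time vector; errors if spacing deviates by > 1%.
infer_fs <- function(time_s, tol = 0.01) {
  if (length(time_s) < 2) stop_input("Need at least 2 time points to infer a rate.")
  dt <- diff(time_s)
  dt0 <- median(dt)
  if (dt0 <= 0) stop_input("Time column must be strictly increasing.")
  bad <- which(abs(dt - dt0) > tol * dt0)
  if (length(bad) > 0) {
    stop_input(sprintf(
      "Non-uniform sampling: interval after row %d is %.6g s (expected %.6g s).",
      bad[1], dt[bad[1]], dt0
    ))
  }
  1 / dt0
}

check_same_grid <- function(a, b, what = c("signals")) {
  fa <- wave_fs(a); fb <- wave_fs(b)
  if (abs(fa - fb) > 1e-6 * fa || nrow(a) != nrow(b) ||
      abs(wave_t0(a) - wave_t0(b)) > 0.5 / fa) {
    stop_input(sprintf("The %s must share one uniform time grid.", what[1]))
  }
  invisible(fa)
}

#' @export
print.nicp_wave <- function(x, ...) {
  cat(sprintf(
    "<waveform: %d samples @ %g Hz, %.3g s%s>\n",
    nrow(x), wave_fs(x), nrow(x) / wave_fs(x),
    if (nzchar(wave_units(x))) paste0(", ", wave_units(x)) else ""
  ))
  NextMethod()
}

#' Read or write a waveform as two-column CSV
#'
#' The canonical interchange format is a plain CSV with header
#' `time_s,value`; the sampling rate is inferred from the time column, which
#' must be uniform to within 1%.
#'
#' @param path file path.
#' @param units units label attached to the waveform on read.
#' @return `read_waveform()` returns a [waveform()]; `write_waveform()`
#'   returns `path` invisibly.
#' @export
read_waveform <- function(path, units = "") {
  if (!file.exists(path)) stop_input(sprintf("File not found: %s", path))
  df <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      time_s = readr::col_double(), value = readr::col_double()
    )),
    error = function(e) stop_input(sprintf("Cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (!all(c("time_s", "value") %in% names(df)) || nrow(df) == 0) {
    stop_input(sprintf("%s must have header `time_s,value` and at least one row.", path))
  }
  as_waveform(df, units = units)
}

#' @rdname read_waveform
#' @param x a waveform (or data frame with `time_s`, `value`).
#' @export
write_waveform <- function(x, path) {
  if (!is.data.frame(x) || !all(c("time_s", "value") %in% names(x)) || nrow(x) == 0) {
    stop_input("`x` must be a non-empty waveform with columns `time_s` and `value`.")
  }
  readr::write_csv(tibble(time_s = x$time_s, value = x$value), path)
  invisible(path)
}
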