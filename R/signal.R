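#' Time-domain ECG signal
#'
#' Lightweight container for a finite, single-channel sample vector with its
#' sampling rate.  All transforms and denoisers in the package consume and
#' return `ecg_signal` objects.
#'
#' @param samples Numeric vector of at least two finite samples (amplitude,
#'   arbitrary units, typically mV).
#' @param fs Sampling rate in Hz (positive scalar).
#' @return An object of class `ecg_signal`: a list with elements `samples`
#'   and `fs`.
#' @examples
#' s <- ecg_signal(sin(2 * pi * 5 * seq(0, 1, length.out = 360)), fs = 360)
#' duration(s)
#' @export
ecg_signal <- function(samples, fs) {
  if (!is.numeric(samples))
    stop_invalid_input("`samples` must be numeric")
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop_invalid_input("a signal needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop_invalid_input("`samples` contains non-finite values")
  if (!is_scalar_num(fs) || fs <= 0)
    stop_invalid_input("`fs` must be a positive scalar (Hz)")
  structure(list(samples = samples, fs = as.numeric(fs)),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.3f s), range [%.4g, %.4g]\n",
              length(x$samples), x$fs, duration(x),
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' Signal duration in seconds
#' @param x An `ecg_signal`.
#' @return Duration `length(samples) / fs` in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "ecg_signal"))
  length(x$samples) / x$fs
}

as_ecg_signal <- function(x, fs) {
  if (inherits(x, "ecg_signal")) x else ecg_signal(x, fs)
}
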