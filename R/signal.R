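#' Sampled one-dimensional signal
#'
#' The universal input container: a real-valued sample vector with its
#' sampling frequency.
#'
#' @param samples Numeric vector, length >= 2, all finite.
#' @param fs Sampling frequency in Hz (> 0).
#' @return An object of class `signal_record` with fields `samples` and `fs`.
#' @examples
#' s <- signal_record(sin(2 * pi * 5 * (0:999) / 100), fs = 100)
#' @export
signal_record <- function(samples, fs) {
  if (!is.numeric(samples) || length(samples) < 2L)
    fc_domain_error("`samples` must be a numeric vector of length >= 2")
  if (!all(is.finite(samples)))
    fc_domain_error("all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    fc_domain_error("`fs` must be a single positive number (Hz)")
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs)),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("signal_record: %d samples at %g Hz (%.4g s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.signal_record <- function(x) length(x$samples)
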