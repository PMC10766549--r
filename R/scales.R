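#' Exponentially discretized scale axis
#'
#' Build `m` wavelet scales whose mapped physical frequencies divide
#' `[f0, f1]` evenly on a logarithmic (base-2) scale. Scales are a geometric
#' progression `a_x = a_1 * 2^((x-1) * delta_a)`; the scale mapped to a
#' frequency f is `a = fs * (sigma / (2*pi)) / f`, the standard Morlet
#' center-frequency convention. The smallest scale (mapped to `f1`) must be at
#' least `a_min = 2`, the reference scale of the precomputed mother-wavelet
#' table that daughter wavelets are downsampled from.
#'
#' @param f0 Lowest analyzed frequency (Hz, > 0).
#' @param f1 Highest analyzed frequency (Hz, `f0 <= f1 <= fs/2`).
#' @param m Number of scales (>= 1).
#' @param fs Sampling frequency (Hz).
#' @param wavelet A [morlet()] wavelet.
#' @return An object of class `scale_set`: `scales` (ascending), `delta_a`
#'   (log2 step of the progression), `m`, `frequencies` (Hz, descending,
#'   `frequencies[i] = fs * sigma/(2*pi) / scales[i]`), plus the `fs`, `sigma`,
#'   `f0`, `f1` it was built for.
#' @examples
#' sc <- generate_scales(1, 32, 300, fs = 500, wavelet = morlet(6))
#' range(sc$frequencies)  # 1 .. 32
#' @export
generate_scales <- function(f0, f1, m, fs, wavelet) {
  stopifnot(inherits(wavelet, "morlet_wavelet"))
  if (!is.numeric(f0) || !is.numeric(f1) || f0 <= 0 || f1 < f0)
    fc_domain_error("need 0 < f0 <= f1")
  if (f1 > fs / 2)
    fc_domain_error(sprintf("f1 = %g Hz is above the Nyquist frequency %g Hz", f1, fs / 2))
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    fc_domain_error("`m` must be a positive integer count")
  if (m > 1 && f0 == f1)
    fc_domain_error("f0 == f1 requires m = 1")
  fc <- wavelet$center_frequency
  a_min <- fs * fc / f1   # smallest scale, highest frequency
  a_max <- fs * fc / f0
  if (a_min < 2)
    fc_domain_error(sprintf(
      "scale mapped to f1 = %g Hz is %.4g < a_min = 2; lower f1 to at most %.6g Hz",
      f1, a_min, fs * fc / 2))
  m <- as.integer(m)
  if (m == 1L) {
    scales <- a_min
    delta_a <- 0
  } else {
    delta_a <- log2(a_max / a_min) / (m - 1)
    scales <- a_min * 2^((seq_len(m) - 1) * delta_a)
  }
  structure(
    list(
      scales = scales,
      delta_a = delta_a,
      m = m,
      frequencies = fs * fc / scales,
      fs = as.numeric(fs),
      sigma = wavelet$sigma,
      f0 = as.numeric(f0),
      f1 = as.numeric(f1)
    ),
    class = "scale_set"
  )
}

#' @export
print.scale_set <- function(x, ...) {
  cat(sprintf(
    "scale_set: %d scales in [%.6g, %.6g] (delta_a = %.6g), frequencies %.6g..%.6g Hz at fs = %g Hz, sigma = %g\n",
    x$m, min(x$scales), max(x$scales), x$delta_a,
    max(x$frequencies), min(x$frequencies), x$fs, x$sigma))
  invisible(x)
}
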