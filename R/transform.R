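#' Zero-padded forward FFT of a signal
#'
#' Extends the signal with zeros to the next power of two `K >= N` and returns
#' its discrete Fourier transform. Padding to a power of two keeps every
#' inverse transform in the scale loop on the same fast grid; the original
#' length is recorded so the padded tail can be dropped after inversion.
#'
#' @param signal A [signal_record()].
#' @return An object of class `spectrum_record`: `coefficients` (complex,
#'   length `K`), `original_length` (`N`), `padded_length` (`K`).
#' @export
forward_fft_padded <- function(signal) {
  stopifnot(inherits(signal, "signal_record"))
  n <- length(signal$samples)
  k <- next_power_of_two(n)
  x <- c(signal$samples, numeric(k - n))
  structure(
    list(coefficients = stats::fft(x), original_length = n, padded_length = k),
    class = "spectrum_record"
  )
}

#' Fourier-domain mother wavelet lookup table
#'
#' Samples the analytic Fourier-domain Morlet once, at the reference scale
#' `a0 = 2`, over the full padded frequency grid: `values[q] =
#' morlet_fourier_value(2 * xi_q)` with `xi_q = 2*pi*q/K` the dimensionless
#' angular frequency of FFT bin `q`. Every daughter wavelet at scale
#' `a >= 2` is later read from this table by accessing every `(a/2)`-th value,
#' so the costly Gaussian evaluations happen exactly once per transform.
#'
#' Because the table argument tops out at `2 * xi_(K-1)` (just under `4*pi`),
#' the Gaussian peak and support fit inside the table only for
#' `sigma` up to about 6.5; [fcwt_transform()] enforces this.
#'
#' @param padded_length Table length `K`, a power of two >= 8.
#' @param wavelet A [morlet()] wavelet.
#' @return An object of class `mother_table`: `values` (real, length `K`),
#'   `padded_length`, `sigma`.
#' @export
precompute_mother_table <- function(padded_length, wavelet) {
  stopifnot(inherits(wavelet, "morlet_wavelet"))
  if (length(padded_length) != 1L || !is_power_of_two(padded_length) || padded_length < 8)
    fc_domain_error("`padded_length` must be a power of two >= 8")
  k <- as.integer(padded_length)
  xi <- 2 * pi * (0:(k - 1L)) / k
  structure(
    list(values = morlet_fourier_value(2 * xi, wavelet),
         padded_length = k, sigma = wavelet$sigma),
    class = "mother_table"
  )
}

# Largest sigma whose Gaussian support [sigma - w, sigma + w] fits in the
# table's argument range [0, 4*pi) with truncation below `tol`.
sigma_table_ok <- function(sigma, tol = 1e-6) {
  exp(-((4 * pi - sigma)^2) / 2) < tol
}

#' Spectrum times one downsampled daughter wavelet
#'
#' The scale-dependent inner step of the fast transform, exposed for testing
#' and single-scale use: multiplies the padded signal spectrum by the daughter
#' wavelet at scale `a`, where the daughter is read from the mother table by
#' the downsampling lookup at fractional index `(a/2) * k`, resolved by linear
#' interpolation between the two neighbouring table entries (indices past the
#' table end read as zero). Integer indices — every even-integer scale, and
#' `a = 2` in particular — reproduce table entries identically; fractional
#' indices stay within the interpolation error of the Gaussian, quadratic in
#' the table's bin width. Only the non-negative-frequency half is populated;
#' the negative-frequency half is zero (analytic wavelet). [fcwt_transform()]
#' performs the same computation for all scales in one fused compiled pass.
#'
#' @param spectrum A [forward_fft_padded()] result.
#' @param table A [precompute_mother_table()] table of the same padded length.
#' @param a Scale factor (>= 2).
#' @return Complex vector of length `K`.
#' @export
daughter_product <- function(spectrum, table, a) {
  stopifnot(inherits(spectrum, "spectrum_record"), inherits(table, "mother_table"))
  if (a < 2) fc_domain_error("scale `a` must be >= 2 (the mother table reference scale)")
  k <- spectrum$padded_length
  if (table$padded_length != k)
    fc_domain_error("spectrum and mother table padded lengths differ")
  half <- k %/% 2L
  bins <- 0:half
  pos <- (a / 2) * bins
  i0 <- floor(pos)
  frac <- pos - i0
  lo <- ifelse(i0 < k, table$values[pmin(i0, k - 1L) + 1L], 0)
  hi <- ifelse(i0 + 1 < k, table$values[pmin(i0 + 1, k - 1L) + 1L], 0)
  w <- lo + frac * (hi - lo)
  out <- complex(k)
  out[bins + 1L] <- spectrum$coefficients[bins + 1L] * w
  out
}

new_tf_matrix <- function(values, scale_set, fs) {
  structure(list(values = values, scale_set = scale_set, fs = fs),
            class = "tf_matrix")
}

#' @export
print.tf_matrix <- function(x, ...) {
  cat(sprintf("tf_matrix: %d scales x %d samples (fs = %g Hz, sigma = %g)\n",
              nrow(x$values), ncol(x$values), x$fs, x$scale_set$sigma))
  invisible(x)
}

#' @export
dim.tf_matrix <- function(x) dim(x$values)

check_transform_args <- function(signal, scale_set, wavelet) {
  stopifnot(inherits(signal, "signal_record"),
            inherits(scale_set, "scale_set"),
            inherits(wavelet, "morlet_wavelet"))
  if (!isTRUE(all.equal(scale_set$fs, signal$fs)))
    fc_domain_error("scale_set was generated for a different sampling frequency")
  if (!isTRUE(all.equal(scale_set$sigma, wavelet$sigma)))
    fc_domain_error("scale_set was generated for a different sigma")
}

# Inverse-FFT a K x m coefficient matrix column-wise, truncate the padded tail
# and return the m x N time-frequency matrix.
invert_coefs <- function(coefs, n, scale_set, fs) {
  k <- nrow(coefs)
  w <- stats::mvfft(coefs, inverse = TRUE) / k
  new_tf_matrix(t(w[seq_len(n), , drop = FALSE]), scale_set, fs)
}

#' Fast continuous wavelet transform (downsampled-lookup algorithm)
#'
#' Computes the CWT by splitting the work into scale-independent and
#' scale-dependent parts. Scale-independent (done once): the zero-padded FFT
#' of the signal and the Fourier-domain mother wavelet table at reference
#' scale `a0 = 2`. Scale-dependent (done per scale, fused in compiled code):
#' read the daughter wavelet from the table by downsampling lookup, multiply
#' it into the spectrum, and inverse-FFT the product back to the time domain.
#' Row `i` of the result is the complex wavelet coefficient series at
#' `scale_set$scales[i]`; the padded tail is dropped so the matrix is
#' `m x N`.
#'
#' Boundary policy is unbiased zero extension: the signal is treated as zero
#' outside its support and no mirroring or continuation is applied, so edge
#' coefficients carry the usual cone-of-influence attenuation. Callers wanting
#' a different boundary treatment can extend the signal themselves first.
#'
#' @param signal A [signal_record()].
#' @param scale_set A [generate_scales()] axis built for the same `fs` and
#'   wavelet.
#' @param wavelet The [morlet()] wavelet the scale set was built with.
#' @return A `tf_matrix`: complex `m x N` matrix `values`, plus the scale set
#'   and sampling frequency.
#' @seealso [reference_cwt()] for the dense per-scale evaluation this
#'   algorithm approximates, [naive_time_cwt()] for the direct-convolution
#'   oracle.
#' @export
fcwt_transform <- function(signal, scale_set, wavelet) {
  check_transform_args(signal, scale_set, wavelet)
  if (!sigma_table_ok(wavelet$sigma))
    fc_domain_error(paste0(
      "sigma = ", wavelet$sigma, " is too large for the length-K a0 = 2 mother table ",
      "(Gaussian support exceeds its argument range [0, 4*pi)); use reference_cwt()"))
  spectrum <- forward_fft_padded(signal)
  table <- precompute_mother_table(spectrum$padded_length, wavelet)
  coefs <- fcwt_fill_coefs(spectrum$coefficients, table$values, scale_set$scales)
  invert_coefs(coefs, spectrum$original_length, scale_set, signal$fs)
}

#' Dense Fourier-domain reference CWT
#'
#' Same contract as [fcwt_transform()], but every daughter wavelet is
#' evaluated densely from the analytic Fourier-domain Morlet at its own scale
#' (no lookup table, no index rounding). This is the ground truth the lookup
#' path is validated against: the two differ only by the rounding of the
#' fractional lookup index, bounded by the Gaussian's smoothness.
#'
#' @inheritParams fcwt_transform
#' @return A `tf_matrix`, as [fcwt_transform()].
#' @export
reference_cwt <- function(signal, scale_set, wavelet) {
  check_transform_args(signal, scale_set, wavelet)
  spectrum <- forward_fft_padded(signal)
  k <- spectrum$padded_length
  half <- k %/% 2L
  xi <- 2 * pi * (0:half) / k
  m <- scale_set$m
  coefs <- matrix(0 + 0i, nrow = k, ncol = m)
  spec_half <- spectrum$coefficients[1:(half + 1L)]
  for (s in seq_len(m)) {
    psi <- morlet_fourier_value(scale_set$scales[s] * xi, wavelet)
    coefs[1:(half + 1L), s] <- spec_half * psi
  }
  invert_coefs(coefs, spectrum$original_length, scale_set, signal$fs)
}

#' Direct time-domain convolution oracle
#'
#' Computes `W[a, b] = |a|^-1 * sum_n f[n] * conj(psi)((n - b) / a)` by
#' explicit summation with the time-domain analytic Morlet, zero extension
#' outside the signal support. Quadratic in the signal length by construction;
#' it exists purely as an independent oracle for the Fourier-domain paths and
#' is capped at `N <= 4096`.
#'
#' @inheritParams fcwt_transform
#' @param support Kernel half-width in units of the Gaussian envelope standard
#'   deviation (`a` samples at scale `a`); the kernel is truncated where the
#'   envelope has decayed to `exp(-support^2/2)`.
#' @return A `tf_matrix`, as [fcwt_transform()].
#' @export
naive_time_cwt <- function(signal, scale_set, wavelet, support = 8) {
  check_transform_args(signal, scale_set, wavelet)
  n <- length(signal$samples)
  if (n > 4096) fc_size_error("naive_time_cwt is an O(N^2) oracle; N must be <= 4096")
  x <- signal$samples
  m <- scale_set$m
  values <- matrix(0 + 0i, nrow = m, ncol = n)
  for (s in seq_len(m)) {
    a <- scale_set$scales[s]
    l <- ceiling(support * a)
    kern <- Conj(morlet_time_value((-l:l) / a, wavelet))  # conj(psi)(u) at u = (n-b)/a
    for (b in seq_len(n)) {
      n_lo <- max(1L, b - l)
      n_hi <- min(n, b + l)
      offs <- (n_lo:n_hi) - b
      values[s, b] <- sum(x[n_lo:n_hi] * kern[offs + l + 1L]) / a
    }
  }
  new_tf_matrix(values, scale_set, signal$fs)
}
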