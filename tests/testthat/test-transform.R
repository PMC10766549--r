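# The three transform routes: fast lookup, dense reference, direct-convolution
# oracle, and their agreement.

test_that("padded FFT round-trips and handles degenerate spectra", {
  # all-zero signal: linearity
  z <- forward_fft_padded(signal_record(numeric(100) + 0, fs = 10))
  expect_identical(z$padded_length, 128L)
  expect_true(all(z$coefficients == 0))

  # constant signal on an exact power-of-two grid: DC-only spectrum
  s <- forward_fft_padded(signal_record(rep(3, 64), fs = 10))
  expect_identical(s$padded_length, 64L)
  expect_equal(s$coefficients[1], 3 * 64 + 0i)
  expect_equal(max(abs(s$coefficients[-1])), 0)

  # random signal: inverse FFT truncated to N reproduces the input
  set.seed(7)
  x <- rnorm(300)
  sp <- forward_fft_padded(signal_record(x, fs = 100))
  back <- Re(stats::fft(sp$coefficients, inverse = TRUE)) / sp$padded_length
  expect_equal(back[1:300], x, tolerance = 1e-9)
})

test_that("daughter product matches explicit downsampling of the mother table", {
  w <- morlet(6)
  set.seed(11)
  sig <- signal_record(rnorm(256), fs = 100)
  sp <- forward_fft_padded(sig)
  k <- sp$padded_length
  tab <- precompute_mother_table(k, w)
  half <- k %/% 2L

  # a = 2: identity lookup, element k equals spectrum[k] * table[k]
  d2 <- daughter_product(sp, tab, 2)
  expect_equal(d2[1:(half + 1)],
               sp$coefficients[1:(half + 1)] * tab$values[1:(half + 1)])
  expect_true(all(d2[(half + 2):k] == 0))

  # a = 4: every 2nd table value; bins with 2k >= K read zero
  d4 <- daughter_product(sp, tab, 4)
  idx <- 2 * (0:half)
  expected <- ifelse(idx < k, tab$values[pmin(idx, k - 1) + 1], 0)
  expect_equal(d4[1:(half + 1)], sp$coefficients[1:(half + 1)] * expected)

  # zero spectrum is absorbing
  zsp <- forward_fft_padded(signal_record(numeric(256), fs = 100))
  expect_true(all(daughter_product(zsp, tab, 3.7) == 0))

  expect_error(daughter_product(sp, tab, 1.5), class = "fastcwt_domain_error")
})

test_that("fast and reference transforms agree to 1e-3 and interpolation stays tight", {
  w <- morlet(6)
  set.seed(23)
  sig <- signal_record(rnorm(1024), fs = 256)   # K = 1024
  sc <- generate_scales(4, 64, 48, 256, w)
  tf_fast <- fcwt_transform(sig, sc, w)
  tf_ref <- reference_cwt(sig, sc, w)
  expect_identical(dim(tf_fast$values), c(48L, 1024L))
  dev <- max(abs(tf_fast$values - tf_ref$values)) / max(abs(tf_ref$values))
  expect_lt(dev, 1e-3)
})

test_that("all three routes agree at interior samples for random signals", {
  w <- morlet(6)
  for (cfg in list(list(n = 256, seed = 1), list(n = 512, seed = 2))) {
    sig <- make_noise_signal(cfg$n, fs = 128, seed = cfg$seed)
    sc <- generate_scales(8, 32, 16, 128, w)
    tf_fast <- fcwt_transform(sig, sc, w)
    tf_ref <- reference_cwt(sig, sc, w)
    tf_naive <- naive_time_cwt(sig, sc, w)
    cols <- interior_columns(cfg$n, sc)
    ref_max <- max(abs(tf_ref$values))
    expect_lt(max(abs(tf_fast$values - tf_ref$values)) / ref_max, 1e-3)
    expect_lt(max(abs(tf_fast$values[, cols] - tf_naive$values[, cols])) / ref_max, 1e-3)
    expect_lt(max(abs(tf_ref$values[, cols] - tf_naive$values[, cols])) / ref_max, 1e-3)
  }
})

test_that("zero signals produce exactly zero coefficients (boundary policy)", {
  w <- morlet(6)
  sig <- signal_record(numeric(400), fs = 100)
  sc <- generate_scales(2, 20, 10, 100, w)
  expect_true(all(fcwt_transform(sig, sc, w)$values == 0))
  expect_true(all(reference_cwt(sig, sc, w)$values == 0))
  expect_true(all(naive_time_cwt(sig, sc, w)$values == 0))
})

test_that("transforms are linear", {
  w <- morlet(6)
  fs <- 128
  sc <- generate_scales(8, 32, 12, fs, w)
  set.seed(31)
  x <- rnorm(256)
  y <- rnorm(256)
  al <- 2.5
  be <- -1.25
  for (transform in list(fcwt_transform, reference_cwt)) {
    wx <- transform(signal_record(x, fs), sc, w)$values
    wy <- transform(signal_record(y, fs), sc, w)$values
    wxy <- transform(signal_record(al * x + be * y, fs), sc, w)$values
    expect_equal(wxy, al * wx + be * wy, tolerance = 1e-9)
  }
})

test_that("shifting the input shifts the coefficients (time covariance)", {
  w <- morlet(6)
  fs <- 128
  n <- 512
  sc <- generate_scales(8, 32, 12, fs, w)
  # compactly supported burst well inside the record
  t <- (0:(n - 1)) / fs
  burst <- exp(-((t - 1.5)^2) / 0.02) * cos(2 * pi * 16 * t)
  s <- 40L
  shifted <- c(numeric(s), burst[1:(n - s)])
  w0 <- fcwt_transform(signal_record(burst, fs), sc, w)$values
  w1 <- fcwt_transform(signal_record(shifted, fs), sc, w)$values
  cols <- interior_columns(n - s, sc)
  dev <- max(abs(w1[, cols + s] - w0[, cols])) / max(abs(w0))
  expect_lt(dev, 1e-6)
})

test_that("manual zero padding and automatic padding give identical results", {
  w <- morlet(6)
  fs <- 128
  n <- 300
  set.seed(41)
  x <- rnorm(n)
  sc <- generate_scales(8, 32, 8, fs, w)
  auto <- fcwt_transform(signal_record(x, fs), sc, w)$values
  manual <- fcwt_transform(signal_record(c(x, numeric(512 - n)), fs), sc, w)$values
  expect_equal(manual[, 1:n], auto, tolerance = 1e-9)
})

test_that("a tone at a row's center frequency gives flat unit-calibrated magnitude", {
  w <- morlet(6)
  fs <- 500
  n <- 2048
  freq <- 20
  sc1 <- generate_scales(freq, freq, 1, fs, w)
  t <- (0:(n - 1)) / fs
  # analytic-signal calibration: W(cos) + i W(sin) = W(exp(i 2 pi f t)),
  # which must have unit magnitude at the matching row
  wc <- fcwt_transform(signal_record(cos(2 * pi * freq * t), fs), sc1, w)$values
  ws <- fcwt_transform(signal_record(sin(2 * pi * freq * t), fs), sc1, w)$values
  mag <- abs(wc + 1i * ws)
  mid <- (n %/% 4):(3 * n %/% 4)
  expect_equal(mean(mag[1, mid]), 1, tolerance = 1e-3)
  # real cosine alone carries half the analytic amplitude
  expect_equal(mean(abs(wc[1, mid])), 0.5, tolerance = 1e-3)

  # over a full grid the magnitude is flat in time and maximal at the nearest row
  sc <- generate_scales(5, 100, 60, fs, w)
  tfm <- fcwt_transform(signal_record(cos(2 * pi * freq * t), fs), sc, w)
  prof <- abs(tfm$values[, mid])
  cv <- apply(prof, 1, stats::sd) / apply(prof, 1, mean)
  peak_row <- which.max(rowMeans(prof))
  expect_lt(cv[peak_row], 0.01)
  expect_equal(peak_row, which.min(abs(sc$frequencies - freq)))
})

test_that("impulse response of the oracle is the scaled conjugate wavelet", {
  w <- morlet(6)
  fs <- 100
  n <- 256
  n0 <- 128L
  x <- numeric(n)
  x[n0] <- 1
  a <- 5
  f_a <- fs * w$center_frequency / a
  sc <- generate_scales(f_a, f_a, 1, fs, w)
  tfm <- naive_time_cwt(signal_record(x, fs), sc, w)
  b <- seq_len(n)
  expected <- Conj(fastcwt:::morlet_time_value((n0 - b) / a, w)) / a
  expect_equal(as.vector(tfm$values[1, ]), expected, tolerance = 1e-12)
})

test_that("size and sigma guards fire", {
  w <- morlet(6)
  sc <- generate_scales(8, 32, 4, 128, w)
  expect_error(naive_time_cwt(make_noise_signal(5000, 128, 1), sc, w),
               class = "fastcwt_size_error")
  w_big <- morlet(8)
  sc_big <- generate_scales(8, 32, 4, 128, w_big)
  expect_error(fcwt_transform(make_noise_signal(256, 128, 1), sc_big, w_big),
               class = "fastcwt_domain_error")
  # reference path has no table and accepts the same sigma
  expect_silent(reference_cwt(make_noise_signal(256, 128, 1), sc_big, w_big))
})
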