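# Shared fixtures: small deterministic signals and a brute-force ridge oracle.

make_tone <- function(freq, fs, n, phase = 0) {
  signal_record(cos(2 * pi * freq * (0:(n - 1)) / fs + phase), fs)
}

make_noise_signal <- function(n, fs, seed) {
  set.seed(seed)
  signal_record(stats::rnorm(n), fs)
}

# Exhaustive best path over all row sequences: the oracle for the ridge DP.
brute_force_ridge <- function(power, penalty) {
  m <- nrow(power)
  n <- ncol(power)
  grid <- do.call(expand.grid, rep(list(seq_len(m)), n))
  best_score <- -Inf
  best_path <- NULL
  for (i in seq_len(nrow(grid))) {
    path <- as.integer(grid[i, ])
    score <- sum(power[cbind(path, seq_len(n))]) -
      penalty * sum(diff(path)^2)
    if (score > best_score + 1e-12) {
      best_score <- score
      best_path <- path
    }
  }
  list(path = best_path, score = best_score)
}

# Interior columns at least `widths` envelope widths away from both edges for
# the largest scale in the set.
interior_columns <- function(n, scale_set, widths = 6) {
  margin <- ceiling(widths * max(scale_set$scales))
  stopifnot(2 * margin < n)
  (margin + 1):(n - margin)
}
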