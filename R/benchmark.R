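# Wall-clock benchmark harness and the real-time analysis ratio.

#' Real-time analysis ratio
#'
#' `RAR = t_computation / t_signal`: the fraction of the signal's own duration
#' an algorithm needs to analyze it. `RAR > 1` means the method cannot keep up
#' with the signal in real time; values well below 1 leave headroom for the
#' rest of a processing pipeline.
#'
#' @param t_computation Computation wall-clock time (s, > 0).
#' @param t_signal Signal duration (s, > 0).
#' @return The ratio (dimensionless).
#' @examples
#' rar(1, 10)   # 0.1: ten times faster than real time
#' @export
rar <- function(t_computation, t_signal) {
  if (!is.numeric(t_computation) || !is.numeric(t_signal) ||
      any(t_computation <= 0) || any(t_signal <= 0))
    fc_domain_error("both durations must be positive")
  t_computation / t_signal
}

#' Retained-run mask after 3-s.d. outlier trimming
#'
#' Flags runs deviating more than three standard deviations from the mean,
#' with each run compared against the mean and s.d. of the *remaining* runs
#' (a jackknifed z-score). The leave-one-out form prevents an extreme run
#' from masking itself by inflating the spread it is judged against — at
#' small n a gross outlier can otherwise never reach 3 s.d. of the full set —
#' and coincides with the plain rule for large, well-behaved samples. Applied
#' once; an already-trimmed set is left unchanged.
#'
#' @param durations Numeric vector of per-run durations.
#' @return Logical vector: `TRUE` for retained runs.
#' @export
trim_outliers <- function(durations) {
  if (!is.numeric(durations) || length(durations) < 1L)
    fc_domain_error("`durations` must be a non-empty numeric vector")
  n <- length(durations)
  if (n < 3L) return(rep(TRUE, n))
  s_tot <- sum(durations)
  ss_tot <- sum(durations^2)
  mean_loo <- (s_tot - durations) / (n - 1)
  var_loo <- pmax(0, (ss_tot - durations^2 - (n - 1) * mean_loo^2) / (n - 2))
  abs(durations - mean_loo) <= 3 * sqrt(var_loo)
}

#' Timing record from per-run durations
#'
#' Assemble trimmed summary statistics and the real-time analysis ratio from
#' already-measured per-run durations. [timing_harness()] produces these by
#' measurement; constructing one directly is useful for testing the trimming
#' arithmetic on known durations.
#'
#' @param durations Per-run wall-clock durations (s).
#' @param t_signal Duration of the analyzed signal (s).
#' @param label Method label.
#' @return An object of class `timing_record`: `label`, `durations`,
#'   `retained` (logical mask), `mean`, `sd`, `min`, `max` (over retained
#'   runs) and `rar` (retained mean over `t_signal`).
#' @export
timing_record <- function(durations, t_signal, label = "method") {
  retained <- trim_outliers(durations)
  kept <- durations[retained]
  structure(
    list(label = label, durations = durations, retained = retained,
         t_signal = t_signal,
         mean = mean(kept), sd = stats::sd(kept),
         min = min(kept), max = max(kept),
         # sub-resolution timings can average to zero; RAR is undefined there
         rar = if (mean(kept) > 0) rar(mean(kept), t_signal) else NA_real_),
    class = "timing_record")
}

#' @export
print.timing_record <- function(x, ...) {
  cat(sprintf("%s: n = %d (%d retained), mean %.4g s, sd %.3g s, range [%.4g, %.4g] s, RAR %.4g%s\n",
              x$label, length(x$durations), sum(x$retained), x$mean,
              x$sd, x$min, x$max, x$rar,
              if (x$rar > 1) " (not real time)" else ""))
  invisible(x)
}

#' Time a method over repeated runs
#'
#' Runs `fn()` `n_runs` times on identical input after `warmup` untimed
#' warm-up calls (excluding one-off setup such as FFT planning from the
#' measurement), records wall-clock time per run, trims 3-s.d. outliers once,
#' and reports summary statistics and the real-time analysis ratio.
#'
#' @param fn Zero-argument function performing the computation.
#' @param t_signal Duration of the analyzed signal (s), for the RAR.
#' @param n_runs Number of timed runs (>= 3).
#' @param warmup Number of untimed warm-up runs.
#' @param label Method label for reporting.
#' @return A [timing_record()].
#' @export
timing_harness <- function(fn, t_signal, n_runs = 10L, warmup = 1L, label = "method") {
  if (n_runs < 3) fc_domain_error("`n_runs` must be >= 3")
  for (i in seq_len(warmup)) fn()
  durations <- vapply(seq_len(n_runs), function(i) {
    t0 <- proc.time()[["elapsed"]]
    fn()
    proc.time()[["elapsed"]] - t0
  }, numeric(1))
  timing_record(durations, t_signal, label)
}
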