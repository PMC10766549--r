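# Synthetic three-wavepacket validation signal and calibrated noise injection.
#
# Layout at any valid fs (durations in seconds):
#   WP1 (5) | gap (0.5) | WP2 (5) | gap (0.5) | WP3 (10)  -> 21.0 s total.
# WP1: three sinusoidally frequency-modulated sines sweeping 100-110, 20-22
#      and 5-6 Hz with a 1 Hz modulation period.
# WP2: two simultaneous linear chirps, 5 -> 50 Hz up and 100 -> 50 Hz down.
# WP3: three constant tones at 2, 1 and 0.5 Hz.
# Each packet is the unit-amplitude sum of its components multiplied by a
# Gaussian window (sd = T/8, edge amplitude exp(-8) of peak) to avoid
# discontinuities at the packet boundaries. Component phases are the exact
# cumulative integral of their instantaneous frequency, so there are no phase
# jumps and the ground-truth track is recoverable from the generated phase.

packet_specs <- function() {
  list(
    list(kind = "fm_sine_triplet", duration = 5,
         components = list(c(lo = 100, hi = 110), c(lo = 20, hi = 22), c(lo = 5, hi = 6)),
         fm_rate = 1),
    list(kind = "linear_chirp_pair", duration = 5,
         components = list(c(from = 5, to = 50), c(from = 100, to = 50))),
    list(kind = "low_freq_triplet", duration = 10,
         components = list(c(f = 2), c(f = 1), c(f = 0.5)))
  )
}

# Instantaneous frequency (Hz) and exact phase (radians) of one component at
# packet-local times t.
component_law <- function(kind, comp, fm_rate, t, dur) {
  switch(kind,
    fm_sine_triplet = {
      lo <- comp[["lo"]]; hi <- comp[["hi"]]
      freq <- lo + (hi - lo) * (1 + sin(2 * pi * fm_rate * t)) / 2
      # integral of freq: lo*t + (hi-lo)*(t/2 + (1 - cos(2*pi*r*t)) / (4*pi*r))
      phase <- 2 * pi * (lo * t + (hi - lo) *
                           (t / 2 + (1 - cos(2 * pi * fm_rate * t)) / (4 * pi * fm_rate)))
      list(freq = freq, phase = phase)
    },
    linear_chirp_pair = {
      f0 <- comp[["from"]]; f1 <- comp[["to"]]
      k <- (f1 - f0) / dur
      freq <- f0 + k * t
      phase <- 2 * pi * (f0 * t + k * t^2 / 2)
      list(freq = freq, phase = phase)
    },
    low_freq_triplet = {
      f <- comp[["f"]]
      list(freq = rep(f, length(t)), phase = 2 * pi * f * t)
    },
    fc_domain_error("unknown wavepacket kind")
  )
}

#' Generate the clean three-wavepacket validation signal
#'
#' Builds the 21.0-second synthetic signal used to validate time-frequency
#' methods: three Gaussian-windowed wavepackets (sinusoidally
#' frequency-modulated sine triplet, crossing linear chirp pair, low-frequency
#' tone triplet) separated by 0.5-s silent gaps, together with the
#' ground-truth instantaneous-frequency track of every component.
#'
#' @param fs Sampling frequency in Hz; must resolve the 110 Hz maximum
#'   instantaneous frequency with margin (>= 250). Default 500.
#' @return A list with elements `signal` (a [signal_record()], `round(21*fs)`
#'   samples) and `truth`, an object of class `ground_truth_tracks` holding
#'   `tracks` (data.frame: `sample`, `time`, `packet`, `component`,
#'   `freq_hz`, defined only inside each packet's span) and `boundaries`
#'   (data.frame: `packet`, `start`, `end`, 1-based inclusive sample indices).
#' @examples
#' d <- generate_clean_dataset(fs = 500)
#' length(d$signal)                 # 10500
#' subset(d$truth$boundaries, packet == 3)
#' @export
generate_clean_dataset <- function(fs = 500) {
  if (!is.numeric(fs) || length(fs) != 1L || fs < 250)
    fc_domain_error("fs must be >= 250 Hz to resolve the 110 Hz component")
  specs <- packet_specs()
  durations <- c(specs[[1]]$duration, 0.5, specs[[2]]$duration, 0.5, specs[[3]]$duration)
  edges <- round(cumsum(c(0, durations)) * fs)   # segment sample edges
  n_total <- edges[length(edges)]
  x <- numeric(n_total)
  tracks <- vector("list", 3L)
  bounds <- data.frame(packet = 1:3, start = NA_integer_, end = NA_integer_)
  seg_for_packet <- c(1L, 3L, 5L)

  for (p in 1:3) {
    seg <- seg_for_packet[p]
    start <- edges[seg] + 1L
    end <- edges[seg + 1L]
    idx <- start:end
    t_loc <- (idx - start) / fs
    dur <- specs[[p]]$duration
    window <- exp(-((t_loc - dur / 2)^2) / (2 * (dur / 8)^2))
    packet <- numeric(length(idx))
    comp_tracks <- vector("list", length(specs[[p]]$components))
    for (ci in seq_along(specs[[p]]$components)) {
      law <- component_law(specs[[p]]$kind, specs[[p]]$components[[ci]],
                           specs[[p]]$fm_rate, t_loc, dur)
      packet <- packet + sin(law$phase)
      comp_tracks[[ci]] <- data.frame(
        sample = idx, time = (idx - 1L) / fs, packet = p, component = ci,
        freq_hz = law$freq)
    }
    x[idx] <- packet * window
    tracks[[p]] <- do.call(rbind, comp_tracks)
    bounds$start[p] <- start
    bounds$end[p] <- end
  }

  truth <- structure(
    list(tracks = do.call(rbind, tracks), boundaries = bounds, fs = fs),
    class = "ground_truth_tracks")
  list(signal = signal_record(x, fs), truth = truth)
}

#' @export
print.ground_truth_tracks <- function(x, ...) {
  cat(sprintf("ground_truth_tracks: %d packets, %d track samples at fs = %g Hz\n",
              nrow(x$boundaries), nrow(x$tracks), x$fs))
  invisible(x)
}

#' Add white Gaussian noise at an exact signal-to-noise ratio
#'
#' Adds zero-mean white Gaussian noise scaled so the whole-signal
#' average-power SNR, `10*log10(P_signal / P_noise)`, equals `snr_db`
#' exactly: the raw Gaussian draw is rescaled to the target power, so the
#' realized SNR does not fluctuate with the draw. Deterministic given `seed`;
#' the caller's RNG state is left untouched.
#'
#' @param signal A [signal_record()] with nonzero power.
#' @param snr_db Target SNR in dB (0 means equal signal and noise power).
#' @param seed Optional integer seed for the noise draw.
#' @return A [signal_record()] of the noisy signal.
#' @export
add_white_noise <- function(signal, snr_db, seed = NULL) {
  stopifnot(inherits(signal, "signal_record"))
  if (!is.numeric(snr_db) || length(snr_db) != 1L || !is.finite(snr_db))
    fc_domain_error("`snr_db` must be a single finite number")
  p_sig <- mean(signal$samples^2)
  if (p_sig <= 0) fc_domain_error("signal has zero power; SNR is undefined")
  n <- length(signal$samples)
  raw <- with_seed(seed, stats::rnorm(n))
  p_target <- p_sig / 10^(snr_db / 10)
  noise <- raw * sqrt(p_target / mean(raw^2))
  signal_record(signal$samples + noise, signal$fs)
}

#' Measured average-power SNR between a clean and a noisy signal
#'
#' @param clean,noisy [signal_record()]s of equal length; the noise is taken
#'   to be their difference.
#' @return SNR in dB.
#' @export
measure_snr_db <- function(clean, noisy) {
  stopifnot(inherits(clean, "signal_record"), inherits(noisy, "signal_record"))
  if (length(clean) != length(noisy))
    fc_domain_error("signals differ in length")
  noise <- noisy$samples - clean$samples
  10 * log10(mean(clean$samples^2) / mean(noise^2))
}
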