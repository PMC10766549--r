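# Readers and writers: one-column delimited text signals, minimal RIFF/WAVE
# (PCM16 and IEEE float32), and the binary coefficient-matrix dump.

#' Read a sampled signal from text or WAV
#'
#' Text format: one sample per line; lines starting with `#` are comments, and
#' a `# fs=<Hz>` comment supplies the sampling rate. WAV files carry their own
#' rate; the first channel is used. If no rate is available from the file, the
#' `fs` argument is required.
#'
#' @param path File path.
#' @param fs Sampling rate override/fallback (Hz).
#' @param format `"auto"` (by extension), `"text"` or `"wav"`.
#' @return A [signal_record()].
#' @export
read_signal <- function(path, fs = NULL, format = c("auto", "text", "wav")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "text"
  if (format == "wav") {
    wav <- read_wav(path)
    return(signal_record(wav$samples, if (is.null(fs)) wav$fs else fs))
  }
  lines <- readLines(path)
  header <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  fs_line <- regmatches(header, regexpr("fs\\s*=\\s*[0-9.eE+-]+", header))
  if (is.null(fs) && length(fs_line) > 0)
    fs <- as.numeric(sub("fs\\s*=\\s*", "", fs_line[[1]]))
  if (is.null(fs) || !is.finite(fs))
    fc_stop("no sampling rate: file has no '# fs=' header and `fs` was not given",
            "fastcwt_missing_rate_error")
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples))
    fc_format_error(sprintf("non-numeric sample line: '%s'",
                            body[which(is.na(samples))[1]]))
  signal_record(samples, fs)
}

#' Write a signal as one-column text with an `# fs=` header
#'
#' @param signal A [signal_record()].
#' @param path Output path.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "signal_record"))
  writeLines(c(sprintf("# fs=%.17g", signal$fs),
               sprintf("%.17g", signal$samples)), path)
  invisible(path)
}

#' Read a WAV file (first channel)
#'
#' Minimal RIFF/WAVE reader supporting 16-bit PCM and 32-bit IEEE float
#' subformats. PCM samples are scaled to `[-1, 1)`.
#'
#' @param path File path.
#' @return List with `samples` (numeric) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) fc_format_error("not a RIFF file")
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    fc_format_error("not a WAVE file")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(body[5:8]) * 256^(0:3)),
        bits = sum(as.integer(body[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    fc_format_error("WAV file missing fmt or data chunk")
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    vals <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                    signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    vals <- readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else {
    fc_format_error(sprintf("unsupported WAV subformat (format %d, %d bits)",
                            fmt$audio_format, fmt$bits))
  }
  if (fmt$n_channels > 1L)
    vals <- vals[seq(1L, length(vals), by = fmt$n_channels)]
  list(samples = vals, fs = fmt$sample_rate)
}

#' Write a WAV file
#'
#' Minimal RIFF/WAVE writer: mono, 32-bit IEEE float (lossless for
#' single-precision data) or 16-bit PCM.
#'
#' @param signal A [signal_record()].
#' @param path Output path.
#' @param bits 32 (IEEE float, default) or 16 (PCM; samples must lie in
#'   `[-1, 1]`).
#' @export
write_wav <- function(signal, path, bits = 32L) {
  stopifnot(inherits(signal, "signal_record"))
  if (!bits %in% c(16L, 32L)) fc_domain_error("`bits` must be 16 or 32")
  n <- length(signal$samples)
  bytes_per <- bits / 8L
  data_size <- n * bytes_per
  fmt_code <- if (bits == 32L) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(fmt_code, 1L), con, 2, endian = "little")            # format, channels
  writeBin(as.integer(round(signal$fs)), con, 4, endian = "little")
  writeBin(as.integer(round(signal$fs)) * as.integer(bytes_per), con, 4, endian = "little")
  writeBin(c(as.integer(bytes_per), as.integer(bits)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 32L) {
    writeBin(signal$samples, con, 4, endian = "little")
  } else {
    if (any(abs(signal$samples) > 1))
      fc_domain_error("16-bit PCM requires samples in [-1, 1]")
    writeBin(as.integer(pmin(32767, round(signal$samples * 32768))), con, 2,
             endian = "little")
  }
  invisible(path)
}

matrix_magic <- "FCWTMTX1"

#' Write a wavelet coefficient matrix to a binary dump
#'
#' Layout: an 8-byte magic, an integer header (`m`, `N`, precision flag), a
#' double header (`fs`, `sigma`, `f0`, `f1`), then the payload of exactly
#' `2*N*M` floating values in row-major order by scale, each complex
#' coefficient stored as adjacent (real, imaginary) pairs. Double precision by
#' default; single precision halves the file at reduced accuracy. Round trips
#' are bit-exact at the stored precision.
#'
#' @param tf A `tf_matrix`.
#' @param path Output path.
#' @param precision `"double"` or `"single"`.
#' @export
write_matrix <- function(tf, path, precision = c("double", "single")) {
  stopifnot(inherits(tf, "tf_matrix"))
  precision <- match.arg(precision)
  m <- nrow(tf$values)
  n <- ncol(tf$values)
  row_major <- as.vector(t(tf$values))            # scale rows traversed in order
  payload <- as.vector(rbind(Re(row_major), Im(row_major)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(matrix_magic, con, eos = NULL)
  writeBin(as.integer(c(m, n, if (precision == "single") 1L else 0L)), con,
           4, endian = "little")
  writeBin(as.numeric(c(tf$fs, tf$scale_set$sigma, tf$scale_set$f0, tf$scale_set$f1)),
           con, 8, endian = "little")
  writeBin(payload, con, size = if (precision == "single") 4 else 8,
           endian = "little")
  invisible(path)
}

#' Read a wavelet coefficient matrix dump
#'
#' @param path File written by [write_matrix()].
#' @return A `tf_matrix` (its scale axis regenerated from the stored header).
#' @export
read_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- suppressWarnings(readChar(con, nchar(matrix_magic), useBytes = TRUE))
  if (length(magic) != 1L || !identical(magic, matrix_magic))
    fc_format_error("bad magic: not a coefficient matrix dump")
  ints <- readBin(con, "integer", 3, 4, endian = "little")
  if (length(ints) < 3) fc_format_error("truncated header")
  m <- ints[1]; n <- ints[2]; single <- ints[3] == 1L
  dbls <- readBin(con, "double", 4, 8, endian = "little")
  if (length(dbls) < 4) fc_format_error("truncated header")
  expected <- 2 * as.numeric(m) * n
  payload <- readBin(con, "double", expected, size = if (single) 4 else 8,
                     endian = "little")
  if (length(payload) != expected)
    fc_format_error(sprintf("truncated payload: expected %d values, read %d",
                            expected, length(payload)))
  re <- payload[seq(1, expected, by = 2)]
  im <- payload[seq(2, expected, by = 2)]
  values <- matrix(complex(real = re, imaginary = im), nrow = m, byrow = TRUE)
  wavelet <- morlet(dbls[2])
  scales <- generate_scales(dbls[3], dbls[4], m, dbls[1], wavelet)
  new_tf_matrix(values, scales, dbls[1])
}
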