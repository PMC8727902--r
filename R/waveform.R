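#' Mono waveform objects
#'
#' A `waveform` is the carrier of every audio stage in the package: a mono
#' amplitude sequence (dimensionless, nominal range \[-1, 1\]) together with
#' its sample rate in Hz.
#'
#' @param samples Numeric vector of amplitudes. Must be finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return An object of class `waveform` with elements `samples` and
#'   `sample_rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, length.out = 8000)), 8000)
#' duration(w)
#' @export
waveform <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate <= 0)
    stop("'sample_rate' must be a single positive number")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("waveform samples must be finite (no NA/NaN/Inf)")
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), rms %.4f>\n",
              length(x$samples), x$sample_rate, duration(x),
              if (length(x$samples)) rms(x) else 0))
  invisible(x)
}

is_waveform <- function(x) inherits(x, "waveform")

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Duration in seconds.
#' @export
duration <- function(w) {
  stopifnot(is_waveform(w))
  length(w$samples) / w$sample_rate
}

#' Root-mean-square amplitude
#'
#' The power basis of every SNR computation in the package.
#'
#' @param w A non-empty [waveform()].
#' @return `sqrt(mean(samples^2))`.
#' @examples
#' rms(waveform(rep(0.5, 100), 8000))  # 0.5
#' @export
rms <- function(w) {
  stopifnot(is_waveform(w))
  if (length(w$samples) == 0L) stop("cannot take the RMS of an empty waveform")
  sqrt(mean(w$samples^2))
}

#' Read a mono waveform from a RIFF/WAVE file
#'
#' Reads 16-bit PCM WAV. Multi-channel input is downmixed to mono by
#' averaging channels. Samples are returned as doubles in \[-1, 1\]
#' (divided by 32768).
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()] at the file's native sample rate.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "raw", sz)
      audio_format <- sum(as.integer(fmt[1:2]) * c(1L, 256L))
      if (audio_format != 1L) stop("only uncompressed PCM WAV is supported")
      n_channels  <- sum(as.integer(fmt[3:4]) * c(1L, 256L))
      sample_rate <- sum(as.integer(fmt[5:8]) * c(1, 256, 65536, 16777216))
      bits        <- sum(as.integer(fmt[15:16]) * c(1L, 256L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2L)  # skip unknown chunk (word-aligned)
      next
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1L)
    if (!is.null(data_raw) && !is.null(sample_rate)) break
  }
  if (is.null(sample_rate)) stop("malformed WAV: no fmt chunk")
  if (is.null(data_raw) || length(data_raw) == 0L)
    stop("zero-length audio in ", path)
  if (!identical(bits, 16L) && bits != 16) stop("only 16-bit PCM is supported")

  ints <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                  size = 2, signed = TRUE, endian = "little")
  if (length(ints) == 0L) stop("zero-length audio in ", path)
  if (n_channels > 1L) {
    n_frames <- length(ints) %/% n_channels
    ints <- ints[seq_len(n_frames * n_channels)]
    m <- matrix(ints, nrow = n_channels)
    ints <- colMeans(m)
  }
  waveform(ints / 32768, sample_rate)
}

#' Write a mono waveform as 16-bit PCM RIFF/WAVE
#'
#' The package commits to one WAV dialect: 16-bit little-endian PCM, one
#' channel. Samples must lie in \[-1, 1\]; apply your own headroom scaling
#' first if necessary.
#'
#' @param w A [waveform()] with samples in \[-1, 1\].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_wav()]
#' @export
write_wav <- function(w, path) {
  stopifnot(is_waveform(w))
  if (length(w$samples) == 0L) stop("refusing to write an empty waveform")
  if (max(abs(w$samples)) > 1 + 1e-12)
    stop("samples outside [-1, 1]; rescale before writing")
  # symmetric with read_wav's /32768; +1.0 clips to 32767 (one LSB)
  ints <- as.integer(pmax(pmin(round(w$samples * 32768), 32767), -32768))
  rate <- as.integer(round(w$sample_rate))
  n_bytes <- length(ints) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")       # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

# rational approximation of a ratio with bounded denominator
.rational <- function(x, max_den = 1000L) {
  # continued-fraction expansion
  h <- c(1, floor(x)); k <- c(0, 1)
  r <- x - floor(x)
  while (r > 1e-12 && k[length(k)] < max_den) {
    r <- 1 / r
    a <- floor(r)
    h <- c(h, a * h[length(h)] + h[length(h) - 1])
    k <- c(k, a * k[length(k)] + k[length(k) - 1])
    r <- r - a
  }
  i <- max(which(k <= max_den))
  c(p = h[i], q = k[i])
}

#' Band-limited resampling
#'
#' Converts a waveform to a new sample rate by rational-ratio polyphase
#' resampling: zero-stuff upsampling, a Kaiser-windowed FIR low-pass at the
#' narrower of the two Nyquist frequencies (designed with [signal::fir1()]),
#' and decimation. Content above the output Nyquist is attenuated by well
#' over 40 dB, so downsampling (e.g. 48 kHz to 8 kHz) does not alias.
#'
#' @param w A [waveform()].
#' @param target_rate Desired sample rate in Hz (> 0).
#' @return A [waveform()] at `target_rate`; duration is preserved within one
#'   sample period.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * (0:4799) / 48000), 48000)
#' resample(w, 8000)
#' @export
resample <- function(w, target_rate) {
  stopifnot(is_waveform(w))
  if (length(target_rate) != 1L || !is.finite(target_rate) || target_rate <= 0)
    stop("'target_rate' must be a single positive number")
  if (target_rate == w$sample_rate) return(w)
  pq <- .rational(target_rate / w$sample_rate, max_den = 10000L)
  p <- as.integer(pq["p"]); q <- as.integer(pq["q"])
  x <- w$samples
  n_out <- ceiling(length(x) * p / q)

  if (p > 1L) {
    up <- numeric(length(x) * p)
    up[seq(1L, length(up), by = p)] <- x * p
  } else up <- x

  ord <- 20L * max(p, q)            # transition narrow enough for >40 dB stop
  h <- signal::fir1(ord, 0.98 / max(p, q))
  y <- signal::fftfilt(h, c(up, numeric(ord)))
  y <- y[(ord %/% 2L + 1L):(ord %/% 2L + length(up))]
  y <- y[seq(1L, length(y), by = q)]
  waveform(y[seq_len(min(n_out, length(y)))], target_rate)
}
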