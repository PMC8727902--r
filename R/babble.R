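#' Single-talker clip
#'
#' A labelled source clip for babble construction: one talker's continuous
#' speech plus the talker's sex, so the combiner can enforce a sex-balanced
#' mixture.
#'
#' @param audio A [waveform()] of at least 1 s.
#' @param talker_id Opaque label.
#' @param sex `"male"` or `"female"`.
#' @return An object of class `talker_clip`.
#' @export
talker_clip <- function(audio, talker_id, sex = c("male", "female")) {
  stopifnot(is_waveform(audio))
  sex <- match.arg(sex)
  if (duration(audio) < 1) stop("talker clip must be at least 1 s long")
  structure(list(audio = audio, talker_id = as.character(talker_id), sex = sex),
            class = "talker_clip")
}

#' @export
print.talker_clip <- function(x, ...) {
  cat(sprintf("<talker_clip '%s' (%s): %.1f s @ %g Hz>\n",
              x$talker_id, x$sex, duration(x$audio), x$audio$sample_rate))
  invisible(x)
}

# frame-level silence mask: TRUE where the 10 ms frame is below threshold_db
# relative to the clip's peak amplitude
.silence_frames <- function(x, sample_rate, frame_ms, threshold_db) {
  flen <- max(1L, round(frame_ms / 1000 * sample_rate))
  n_frames <- ceiling(length(x) / flen)
  peak <- max(abs(x))
  idx <- rep(seq_len(n_frames), each = flen, length.out = length(x))
  frame_rms <- sqrt(tapply(x^2, idx, mean))
  level_db <- 20 * log10(pmax(frame_rms / peak, 1e-12))
  list(silent = as.vector(level_db < threshold_db), frame_len = flen,
       n_frames = n_frames)
}

#' Trim prolonged silences
#'
#' Detects silence on 10 ms frames (energy below `threshold_db` relative to
#' the clip's peak) and shortens every maximal silent run longer than
#' `max_silence_ms` to exactly `max_silence_ms`, keeping the leading frames.
#' Shorter pauses and speech content are untouched, so the natural pause
#' structure of the clip survives with a hard cap on pause length.
#'
#' @param w A non-empty [waveform()].
#' @param max_silence_ms Cap on any silent run, milliseconds.
#' @param threshold_db Silence threshold relative to the clip peak, dB.
#' @param frame_ms Analysis frame length, milliseconds.
#' @return A [waveform()] no longer than the input. Idempotent.
#' @export
trim_silences <- function(w, max_silence_ms = 500, threshold_db = -40,
                          frame_ms = 10) {
  stopifnot(is_waveform(w))
  x <- w$samples
  if (length(x) == 0L) stop("empty waveform")
  if (max(abs(x)) == 0) stop("entirely silent input: nothing left to trim around")

  sf <- .silence_frames(x, w$sample_rate, frame_ms, threshold_db)
  if (!any(sf$silent)) return(w)
  max_frames <- floor(max_silence_ms / frame_ms)

  runs <- rle(sf$silent)
  keep_frame <- logical(sf$n_frames)
  pos <- 1L
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]
    if (runs$values[i] && len > max_frames) {
      keep_frame[pos:(pos + max_frames - 1L)] <- TRUE  # keep the cap
    } else {
      keep_frame[pos:(pos + len - 1L)] <- TRUE
    }
    pos <- pos + len
  }
  frame_of_sample <- rep(seq_len(sf$n_frames), each = sf$frame_len,
                         length.out = length(x))
  out <- x[keep_frame[frame_of_sample]]
  waveform(out, w$sample_rate)
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)  # periodic

#' Moving-window spectral equalization
#'
#' Whitens the short-time magnitude spectrum: the signal is analysed in
#' Hann-windowed frames (`window_ms` long, hopped by `hop_ms`), each frame's
#' magnitude spectrum is flattened to its mean while phases are kept, and
#' the frames are reconstructed by overlap-add. With the default 50%
#' overlap the Hann windows sum to one, so an unmodified signal would be
#' reconstructed exactly. Output RMS is renormalized to the input RMS.
#'
#' Tonal and coloured inputs come out with a much flatter spectrum; an
#' already-white input is left essentially unchanged in spectral shape.
#'
#' @param w A [waveform()] longer than one analysis window.
#' @param window_ms Analysis window length, milliseconds.
#' @param hop_ms Hop between windows, milliseconds; must be < `window_ms`.
#' @return A [waveform()] of the same length and RMS as the input.
#' @export
equalize_spectrum <- function(w, window_ms = 50, hop_ms = 25) {
  stopifnot(is_waveform(w))
  if (!(window_ms > hop_ms && hop_ms > 0))
    stop("need window_ms > hop_ms > 0")
  n <- length(w$samples)
  win_len <- max(4L, 2L * round(window_ms / 1000 * w$sample_rate / 2))
  hop <- max(1L, round(hop_ms / 1000 * w$sample_rate))
  if (n <= win_len) stop("waveform shorter than one analysis window")

  x <- c(numeric(win_len), w$samples, numeric(2L * win_len))  # edge padding
  win <- .hann(win_len)
  starts <- seq(1L, length(x) - win_len + 1L, by = hop)
  out <- numeric(length(x))
  for (s in starts) {
    seg <- x[s:(s + win_len - 1L)] * win
    X <- stats::fft(seg)
    mag <- Mod(X)
    mbar <- mean(mag)
    if (mbar > 0) {
      flat <- mbar * exp(1i * Arg(X))
      flat[mag == 0] <- mbar      # zero bins get zero phase
      seg <- Re(stats::fft(flat, inverse = TRUE)) / win_len
    }
    out[s:(s + win_len - 1L)] <- out[s:(s + win_len - 1L)] + seg
  }
  y <- out[(win_len + 1L):(win_len + n)]
  r_in <- rms(w)
  r_out <- sqrt(mean(y^2))
  if (r_out > 0) y <- y * (r_in / r_out)
  waveform(y, w$sample_rate)
}

#' Spectral flatness of a waveform
#'
#' Ratio of the geometric to the arithmetic mean of a Welch-averaged power
#' spectrum: 1 for an ideally flat (white) spectrum, near 0 for a tone.
#' Welch averaging over `n_segments` segments tames the chi-square scatter
#' of single periodograms so the measure reflects spectral shape, not
#' estimation noise.
#'
#' @param w A [waveform()].
#' @param n_segments Number of Welch segments.
#' @return Flatness in (0, 1\].
#' @export
spectral_flatness <- function(w, n_segments = 16) {
  stopifnot(is_waveform(w))
  x <- w$samples
  seg_len <- max(8L, 2L * (length(x) %/% n_segments %/% 2L))
  if (seg_len > length(x)) seg_len <- 2L * (length(x) %/% 2L)
  starts <- seq(1L, length(x) - seg_len + 1L, by = seg_len)
  win <- .hann(seg_len)
  nb <- seg_len %/% 2L
  psd <- numeric(nb)
  for (s in starts) {
    X <- stats::fft(x[s:(s + seg_len - 1L)] * win)
    psd <- psd + Mod(X[2:(nb + 1L)])^2
  }
  psd <- psd / length(starts)
  psd <- pmax(psd, max(psd) * 1e-12)
  exp(mean(log(psd))) / mean(psd)
}

#' N-talker babble noise
#'
#' Combines single-talker clips into babble: clips are truncated to the
#' shortest common duration, summed, and renormalized to `target_rms`.
#' The mixture must contain equal numbers of male and female talkers,
#' matching the balanced 10-talker (5 male, 5 female) construction used in
#' speech-in-noise work.
#'
#' @param clips List of [talker_clip()] objects (>= 2, balanced sexes, one
#'   common sample rate).
#' @param target_rms RMS amplitude of the combined babble.
#' @return An object of class `babble_noise` with elements `audio`,
#'   `n_talkers`, `n_male`, `n_female`.
#' @export
combine_talkers <- function(clips, target_rms = 0.1) {
  if (!is.list(clips) || length(clips) < 2L)
    stop("need at least 2 talker clips")
  if (!all(vapply(clips, inherits, logical(1), "talker_clip")))
    stop("all elements must be talker_clip objects")
  sexes <- vapply(clips, `[[`, character(1), "sex")
  n_male <- sum(sexes == "male"); n_female <- sum(sexes == "female")
  if (n_male != n_female)
    stop("unbalanced composition: ", n_male, " male vs ", n_female, " female")
  rates <- vapply(clips, function(cl) cl$audio$sample_rate, numeric(1))
  if (length(unique(rates)) != 1L) stop("clips have mismatched sample rates")
  if (!(target_rms > 0)) stop("'target_rms' must be positive")

  n_min <- min(vapply(clips, function(cl) length(cl$audio$samples), integer(1)))
  mix <- rowSums(vapply(clips, function(cl) cl$audio$samples[seq_len(n_min)],
                        numeric(n_min)))
  r <- sqrt(mean(mix^2))
  if (r == 0) stop("combined clips are silent")
  mix <- mix * (target_rms / r)
  structure(list(audio = waveform(mix, rates[1]),
                 n_talkers = length(clips),
                 n_male = n_male, n_female = n_female),
            class = "babble_noise")
}

#' @export
print.babble_noise <- function(x, ...) {
  cat(sprintf("<babble_noise: %d talkers (%dM/%dF), %.1f s @ %g Hz, rms %.3f>\n",
              x$n_talkers, x$n_male, x$n_female, duration(x$audio),
              x$audio$sample_rate, rms(x$audio)))
  invisible(x)
}
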